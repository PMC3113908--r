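#' Allowed transition cells of a scheme
#'
#' Canonical (row-major) ordering of the allowed off-diagonal cells of the
#' constraint mask; all rate vectors in the package follow this order.
#'
#' @param scheme a `coding_scheme`.
#' @return tibble with columns `from`, `to`, `cell` (label `"From->To"`).
#' @export
allowed_cells <- function(scheme) {
  idx <- which(t(scheme$mask), arr.ind = TRUE) # transpose -> row-major order
  from <- scheme$states[idx[, 2]]
  to <- scheme$states[idx[, 1]]
  tibble(from = from, to = to, cell = paste0(from, "->", to))
}

#' Build a constrained rate matrix
#'
#' Off-diagonal entries are nonnegative transition rates (events per
#' branch-length unit); cells forbidden by the scheme's mask are structural
#' zeros; the diagonal is minus the row sum.
#'
#' @param scheme a `coding_scheme`.
#' @param rates either a numeric vector in [allowed_cells()] order, a named
#'   vector with `"From->To"` names (missing cells default to 0), or a full
#'   k x k matrix whose forbidden cells must be 0.
#' @return a k x k rate matrix with state dimnames and attribute `scheme`.
#' @export
rate_matrix <- function(scheme, rates) {
  states <- scheme$states
  k <- length(states)
  cells <- allowed_cells(scheme)
  Q <- matrix(0, k, k, dimnames = list(states, states))
  if (is.matrix(rates)) {
    assert_that(all(dim(rates) == k), "rate matrix has wrong dimensions")
    off <- rates
    diag(off) <- 0
    assert_that(all(off >= 0), "off-diagonal rates must be >= 0")
    if (any(off[!scheme$mask & !diag(TRUE, k)] != 0)) {
      abort("nonzero rate in a forbidden cell")
    }
    Q[] <- off
  } else if (!is.null(names(rates))) {
    bad <- setdiff(names(rates), cells$cell)
    if (length(bad) > 0) {
      abort(sprintf("unknown or forbidden cell name(s): %s",
                    paste(bad, collapse = ", ")))
    }
    assert_that(all(rates >= 0), "rates must be >= 0")
    for (nm in names(rates)) {
      i <- match(nm, cells$cell)
      Q[cells$from[i], cells$to[i]] <- rates[[nm]]
    }
  } else {
    assert_that(length(rates) == nrow(cells),
                sprintf("expected %d rates (one per allowed cell)", nrow(cells)))
    assert_that(all(rates >= 0), "rates must be >= 0")
    for (i in seq_len(nrow(cells))) {
      Q[cells$from[i], cells$to[i]] <- rates[i]
    }
  }
  diag(Q) <- -rowSums(Q)
  attr(Q, "scheme") <- scheme
  Q
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed by scaling-and-squaring (constrained Q can be defective, so
#' eigendecomposition is avoided). Forbidden single-step cells need not be 0
#' in P(t): multi-step paths are allowed, except out of absorbing states.
#'
#' @param Q rate matrix from [rate_matrix()] (or any square rate matrix).
#' @param t branch length, `t >= 0` (`t = 0` returns the identity exactly).
#' @return stochastic matrix of the same dimension.
#' @export
transition_matrix <- function(Q, t) {
  assert_that(is.numeric(t) && length(t) == 1 && t >= 0,
              "branch length t must be a single value >= 0")
  P <- cpp_expm(unclass_matrix(Q), t)
  dimnames(P) <- dimnames(Q)
  P
}

unclass_matrix <- function(Q) {
  attributes(Q) <- list(dim = dim(Q))
  Q
}
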