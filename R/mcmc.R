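#' Prior specification for transition rates
#'
#' Two kinds are supported: `uniform_fixed`, independent uniform(lo, hi)
#' priors on every free rate (default 0-100), and `exp_hyper`, exponential
#' priors whose mean is itself a sampled hyperparameter with a uniform
#' hyperprior (default 0-10).
#'
#' @param kind `"uniform_fixed"` or `"exp_hyper"`.
#' @param lo,hi uniform rate prior bounds (`uniform_fixed`).
#' @param hyper_lo,hyper_hi bounds of the uniform hyperprior on the
#'   exponential mean (`exp_hyper`).
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(kind = c("uniform_fixed", "exp_hyper"),
                       lo = 0, hi = 100, hyper_lo = 0, hyper_hi = 10) {
  kind <- match.arg(kind)
  assert_that(is.finite(lo) && is.finite(hi) && lo < hi,
              "rate prior bounds must be finite with lo < hi")
  assert_that(is.finite(hyper_lo) && is.finite(hyper_hi) && hyper_lo < hyper_hi,
              "hyperprior bounds must be finite with lo < hi")
  structure(list(kind = kind, lo = lo, hi = hi,
                 hyper_lo = hyper_lo, hyper_hi = hyper_hi),
            class = "prior_spec")
}

#' Single rate proposal (exposed for kernel checks)
#'
#' Sliding-window proposal with reflection at the prior bounds under a
#' `uniform_fixed` prior (symmetric, Hastings ratio 1), or a multiplier
#' proposal under `exp_hyper` (Hastings ratio proposed/current).
#'
#' @param rate current rate value.
#' @param prior a [prior_spec()].
#' @param window window width (uniform) or multiplier scale (exp_hyper).
#' @return list with `value` and `log_hastings`.
#' @export
propose_rate <- function(rate, prior = prior_spec(), window = 1) {
  if (prior$kind == "uniform_fixed") {
    value <- cpp_reflect(rate + window * (runif(1) - 0.5), prior$lo, prior$hi)
    list(value = value, log_hastings = 0)
  } else {
    value <- rate * exp(window * (runif(1) - 0.5))
    list(value = value, log_hastings = log(value / rate))
  }
}

#' Run a Metropolis-Hastings chain over rates, trees and rate classes
#'
#' Samples transition rates (and, with `scheme$rj`, the reversible-jump
#' partition of rates into shared classes including a ZERO class) jointly
#' with uniform resampling of trees from the tree sample. Records every
#' `thin`-th state; when `queries` are given, per-sample marginal node-state
#' probabilities are recorded for each query.
#'
#' @param trees a [tree_sample] (or single `phylo`).
#' @param scheme a `coding_scheme` with tips attached.
#' @param iterations number of MCMC iterations (>= 10 * thin).
#' @param seed integer seed (required; identical seed and settings give a
#'   bit-identical trace).
#' @param prior a [prior_spec()].
#' @param thin record every `thin`-th iteration.
#' @param constraints tibble of [node_constraint()] rows applied throughout.
#' @param queries clade queries ([clade_query()] tibble or named list of tip
#'   sets) whose marginal state probabilities are recorded per sample.
#' @param likelihood set `FALSE` to sample the prior (likelihood term off).
#' @param move_weights weights for the move types
#'   `c(tree, rate, rj, hyper)`; rj and hyper weights are dropped
#'   automatically when inapplicable.
#' @param root_prior root state prior (see [prune_loglik()]).
#' @param tune_frac fraction of iterations during which proposal windows are
#'   adapted (target acceptance 0.2-0.4), frozen afterwards.
#' @param record_all_nodes record marginals for every internal node
#'   (requires all trees in the sample to share one topology).
#' @param max_init_retries prior draws attempted before giving up on a
#'   zero-likelihood initial state.
#' @return an object of class `chain_trace`: list with `samples` (tibble),
#'   `marginals` (sample x query x state array or NULL), `queries`,
#'   `accept` (tibble of per-move acceptance counts), and `settings`.
#' @export
run_chain <- function(trees, scheme, iterations, seed,
                      prior = prior_spec(), thin = max(1L, iterations %/% 1000L),
                      constraints = NULL, queries = NULL,
                      likelihood = TRUE,
                      move_weights = c(tree = 1, rate = 2, rj = 1, hyper = 2),
                      root_prior = NULL, tune_frac = 0.25,
                      record_all_nodes = FALSE, max_init_retries = 200L) {
  if (inherits(trees, "phylo")) trees <- tree_sample(trees)
  assert_that(inherits(trees, "tree_sample"), "trees must be a tree_sample")
  assert_that(!missing(seed) && is.numeric(seed), "an integer seed is required")
  assert_that(iterations >= 10 * thin, "iterations must be >= 10 * thin")
  k <- length(scheme$states)
  cells <- allowed_cells(scheme)
  pi <- default_root_prior(scheme, root_prior)

  if (record_all_nodes) {
    same <- all(vapply(trees$trees, function(tr) {
      identical(tr$tip.label, trees$trees[[1]]$tip.label) &&
        identical(tr$edge, trees$trees[[1]]$edge)
    }, logical(1)))
    assert_that(same,
                "record_all_nodes requires all trees in the sample to share one topology")
  }

  enc <- lapply(trees$trees, encode_tree, scheme = scheme,
                constraints = constraints)
  if (record_all_nodes) {
    nodes <- (enc[[1]]$ntip + 1):enc[[1]]$nnode
    queries_tbl <- tibble(label = paste0("node", nodes), taxa = as.list(nodes))
    query_nodes <- matrix(rep(nodes, each = length(enc)),
                          nrow = length(enc))
  } else if (!is.null(queries)) {
    queries_tbl <- as_clade_queries(queries)
    query_nodes <- vapply(seq_len(nrow(queries_tbl)), function(q) {
      vapply(enc, function(td) mrca_node(td$tree, queries_tbl$taxa[[q]]),
             integer(1))
    }, integer(length(enc)))
    query_nodes <- matrix(query_nodes, nrow = length(enc))
  } else {
    queries_tbl <- NULL
    query_nodes <- matrix(integer(0), nrow = length(enc), ncol = 0)
  }

  w <- c(move_weights[["tree"]], move_weights[["rate"]],
         if (scheme$rj) move_weights[["rj"]] else 0,
         if (prior$kind == "exp_hyper") move_weights[["hyper"]] else 0)
  cpp_trees <- lapply(enc, function(td) {
    list(edge = td$edge, blen = td$blen, tippart = td$tippart, mask = td$mask)
  })

  set.seed(as.integer(seed))
  res <- cpp_run_chain(cpp_trees, k, as.matrix(cells_index(cells, scheme)),
                       pi,
                       list(kind = prior$kind, lo = prior$lo, hi = prior$hi,
                            hyper_lo = prior$hyper_lo, hyper_hi = prior$hyper_hi),
                       scheme$rj, w, as.integer(iterations), as.integer(thin),
                       as.integer(floor(tune_frac * iterations)),
                       isTRUE(likelihood), trees$weights, query_nodes,
                       as.integer(max_init_retries))

  samples <- as_tibble(as.data.frame(res$samples))
  names(samples) <- c("iteration", "tree_index", "logL", "log_prior",
                      "n_classes", "hyper_mean",
                      paste0("q_", gsub("->", ".", cells$cell, fixed = TRUE)))
  marg <- NULL
  if (!is.null(queries_tbl)) {
    marg <- res$marginals
    dimnames(marg) <- list(NULL, queries_tbl$label, scheme$states)
  }
  accept <- tibble(
    move = c("tree", "rate", "rj", "hyper"),
    proposals = res$accept[, 1], accepts = res$accept[, 2],
    unavailable = res$accept[, 3]) |>
    dplyr::mutate(rate = ifelse(.data$proposals > 0,
                                .data$accepts / .data$proposals, NA_real_))
  structure(
    list(samples = samples, marginals = marg, queries = queries_tbl,
         accept = accept, cells = cells,
         settings = list(iterations = iterations, thin = thin, seed = seed,
                         prior = prior, scheme = scheme$name, rj = scheme$rj,
                         states = scheme$states, likelihood = isTRUE(likelihood),
                         n_trees = length(trees$trees),
                         windows = res$windows)),
    class = "chain_trace")
}

cells_index <- function(cells, scheme) {
  cbind(match(cells$from, scheme$states), match(cells$to, scheme$states))
}

#' @export
print.chain_trace <- function(x, ...) {
  cat(sprintf("<chain_trace> %d samples (thin %d) of %d iterations; %d free rate cell(s)%s\n",
              nrow(x$samples), x$settings$thin, x$settings$iterations,
              nrow(x$cells), if (x$settings$rj) " [reversible jump]" else ""))
  if (!is.null(x$queries)) {
    cat(sprintf("  marginal probabilities recorded for %d node quer%s\n",
                nrow(x$queries), if (nrow(x$queries) == 1) "y" else "ies"))
  }
  invisible(x)
}

#' Harmonic-mean log marginal-likelihood estimate
#'
#' `log(n / sum(exp(-logL_i)))` over post-burn-in likelihood samples,
#' computed in log space; invariant to sample order.
#'
#' @param trace a `chain_trace` or a numeric vector of log-likelihoods.
#' @param burnin number of leading samples to discard (for a `chain_trace`;
#'   default the trace's fixed-fraction burn-in, 0 for a plain vector).
#' @return log marginal-likelihood (double).
#' @export
harmonic_mean_logml <- function(trace, burnin = NULL) {
  x <- if (inherits(trace, "chain_trace")) {
    b <- burnin %||% detect_burnin(trace, "fixed_fraction", min_length = 0L)
    tail(trace$samples$logL, nrow(trace$samples) - b)
  } else {
    if (!is.null(burnin) && burnin > 0) tail(trace, length(trace) - burnin)
    else trace
  }
  assert_that(length(x) >= 2, "harmonic mean needs at least 2 samples")
  if (length(x) < 100) {
    warn("harmonic-mean estimate from fewer than 100 post-burn-in samples is unreliable")
  }
  log(length(x)) - logsumexp(-x)
}

#' Burn-in detection
#'
#' `fixed_fraction` discards a fixed leading fraction of the trace
#' (default 0.25). `geweke` scans candidate burn-in points and returns the
#' first from which the log-likelihood trace passes a Geweke stationarity
#' check (|z| < 2 comparing the first 10% against the last 50% of the
#' remaining trace, with AR spectral variance estimates).
#'
#' @param trace a `chain_trace` or numeric vector (log-likelihoods).
#' @param policy `"fixed_fraction"` or `"geweke"`.
#' @param fraction fraction for `fixed_fraction`.
#' @param min_length minimum trace length required (default 200).
#' @return integer burn-in index (number of leading samples to discard).
#' @export
detect_burnin <- function(trace, policy = c("fixed_fraction", "geweke"),
                          fraction = 0.25, min_length = 200L) {
  policy <- match.arg(policy)
  x <- if (inherits(trace, "chain_trace")) trace$samples$logL else as.numeric(trace)
  n <- length(x)
  assert_that(n >= min_length,
              sprintf("trace too short for burn-in detection (%d < %d)", n, min_length))
  if (policy == "fixed_fraction") {
    return(as.integer(ceiling(fraction * n)))
  }
  starts <- unique(as.integer(seq(0, floor(0.5 * n), length.out = 11)))
  for (s in starts) {
    z <- geweke_z(x[(s + 1):n])
    if (is.finite(z) && abs(z) < 2) return(as.integer(s))
  }
  abort("Geweke diagnostic never stabilized: run the chain longer")
}

geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(max(2, floor(frac1 * n)))]
  b <- x[(n - max(2, floor(frac2 * n)) + 1):n]
  va <- spectrum0_ar(a) / length(a)
  vb <- spectrum0_ar(b) / length(b)
  if (va + vb <= 0) return(0)
  (mean(a) - mean(b)) / sqrt(va + vb)
}

# spectral density at frequency zero via an AR fit (variance of the mean of
# an autocorrelated series)
spectrum0_ar <- function(x) {
  if (var(x) == 0) return(0)
  fit <- tryCatch(ar(x, aic = TRUE, order.max = min(20, length(x) %/% 4)),
                  error = function(e) NULL)
  if (is.null(fit)) return(var(x))
  if (length(fit$ar) == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}
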