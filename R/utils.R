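#' Numerically stable log-sum-exp
#'
#' @param x numeric vector (may contain `-Inf`).
#' @return `log(sum(exp(x)))` computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Derive a stream of child seeds from one master seed, keeping every value a
# valid 32-bit R integer. Used so replicate chains / BF arms are independent
# but reproducible from a single seed.
derive_seeds <- function(master_seed, n, stream = 0L) {
  master_seed <- as.integer(master_seed)
  a <- 48271
  m <- 2147483647
  x <- (abs(master_seed) %% (m - 1L)) + 1L
  x <- as.integer((as.double(x) * a + 12345 + 997 * stream) %% m)
  out <- integer(n)
  for (i in seq_len(n)) {
    x <- as.integer((as.double(x) * a) %% m)
    out[i] <- x
  }
  out
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}
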