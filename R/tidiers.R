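#' Tidy a chain trace into long format
#'
#' @param x a `chain_trace`.
#' @param ... unused.
#' @return tibble with columns `iteration`, `parameter`, `value` covering
#'   logL and every free rate (plus `hyper_mean` / `n_classes` when present).
#' @export
tidy.chain_trace <- function(x, ...) {
  keep <- c("logL", grep("^q_", names(x$samples), value = TRUE))
  if (!all(is.na(x$samples$hyper_mean))) keep <- c(keep, "hyper_mean")
  if (!all(is.na(x$samples$n_classes))) keep <- c(keep, "n_classes")
  x$samples |>
    dplyr::select("iteration", dplyr::all_of(keep)) |>
    tidyr::pivot_longer(-"iteration", names_to = "parameter",
                        values_to = "value")
}

#' One-row chain summary
#'
#' @param x a `chain_trace`.
#' @param ... unused.
#' @return tibble: sample count, mean/sd of logL, per-move acceptance rates.
#' @export
glance.chain_trace <- function(x, ...) {
  acc <- setNames(x$accept$rate, paste0("accept_", x$accept$move))
  dplyr::bind_cols(
    tibble(n_samples = nrow(x$samples),
           iterations = x$settings$iterations,
           logL_mean = mean(x$samples$logL),
           logL_sd = sd(x$samples$logL)),
    as_tibble(as.list(acc)))
}

#' Trace plot of a chain
#'
#' @param object a `chain_trace`.
#' @param parameters which parameters to show (default logL and all rates).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.chain_trace <- function(object, parameters = NULL, ...) {
  df <- tidy(object)
  if (!is.null(parameters)) df <- df[df$parameter %in% parameters, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
tidy.bf_result <- function(x, ...) as_tibble(x)

#' Posterior probability bars per node and state
#'
#' @param object an `ancestral_summary`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ancestral_summary <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$pp_mean)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(0, .data$pp_mean - .data$pp_se),
                                        ymax = pmin(1, .data$pp_mean + .data$pp_se)),
                           width = 0.2) +
    ggplot2::facet_wrap(~node) +
    ggplot2::labs(x = NULL, y = "posterior probability") +
    ggplot2::theme_minimal()
}

#' Bayes Factor bars with the strong-support threshold
#'
#' @param object a `bf_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.bf_result <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[is.finite(df$bf_mean), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comparison, y = .data$bf_mean)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$bf_mean - .data$bf_se,
                                        ymax = .data$bf_mean + .data$bf_se),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = 5, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Bayes Factor (2 x log HM difference)") +
    ggplot2::theme_minimal()
}
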