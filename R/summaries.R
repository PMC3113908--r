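#' Replicate-averaged ancestral-state posterior probabilities
#'
#' Per replicate chain, the post-burn-in mean of the per-sample marginal
#' node-state probabilities; across replicates, the mean and standard error
#' (sd / sqrt(n)) of those per-trace means.
#'
#' @param traces a `chain_trace` or list of replicate `chain_trace`s sharing
#'   the same queries.
#' @param burnin_fraction leading fraction of each trace discarded.
#' @return tibble of class `ancestral_summary` with columns `node`, `state`,
#'   `pp_mean`, `pp_se`, `n_replicates`.
#' @export
summarize_ancestral <- function(traces, burnin_fraction = 0.25) {
  if (inherits(traces, "chain_trace")) traces <- list(traces)
  assert_that(length(traces) >= 1, "need at least one trace")
  q1 <- traces[[1]]$queries
  assert_that(!is.null(q1), "traces carry no node queries")
  for (tr in traces) {
    if (is.null(tr$queries) || !identical(tr$queries$label, q1$label)) {
      abort("all traces must share the same queries")
    }
  }
  per_rep <- lapply(traces, function(tr) {
    ns <- dim(tr$marginals)[1]
    b <- ceiling(burnin_fraction * ns)
    m <- tr$marginals[(b + 1):ns, , , drop = FALSE]
    pp <- apply(m, c(2, 3), mean) # query x state
    bad <- abs(rowSums(pp) - 1) > 1e-6
    if (any(bad)) {
      abort(sprintf("per-replicate node probabilities do not sum to 1 at: %s",
                    paste(rownames(pp)[bad], collapse = ", ")))
    }
    pp
  })
  n <- length(per_rep)
  arr <- simplify2array(per_rep) # query x state x rep
  if (length(dim(arr)) == 2) arr <- array(arr, dim = c(dim(arr), 1))
  pp_mean <- apply(arr, c(1, 2), mean)
  pp_se <- if (n >= 2) apply(arr, c(1, 2), sd) / sqrt(n) else pp_mean * 0
  states <- dimnames(traces[[1]]$marginals)[[3]]
  out <- tidyr::expand_grid(node = q1$label, state = states) |>
    dplyr::mutate(
      pp_mean = as.vector(t(pp_mean)),
      pp_se = as.vector(t(pp_se)),
      n_replicates = n)
  class(out) <- c("ancestral_summary", class(out))
  attr(out, "per_replicate") <- arr
  out
}

#' @rdname summarize_ancestral
#' @param summary an `ancestral_summary`.
#' @param path output TSV file.
#' @export
write_ancestral_summary <- function(summary, path) {
  readr::write_tsv(as_tibble(summary), path)
  invisible(path)
}

#' Bayes Factor support categories
#'
#' `bf < 0` "against", `0 <= bf <= 2` "weak", `2 < bf <= 5` "positive",
#' `bf > 5` "strong" (the strong threshold follows the >5 convention for
#' twice the log marginal-likelihood difference).
#'
#' @param bf numeric vector of Bayes Factors (2 x log scale).
#' @return character vector of categories.
#' @export
bf_category <- function(bf) {
  dplyr::case_when(
    is.na(bf) ~ NA_character_,
    bf < 0 ~ "against",
    bf <= 2 ~ "weak",
    bf <= 5 ~ "positive",
    TRUE ~ "strong")
}

#' Bayes Factor test of alternative fixed states at a node
#'
#' For each candidate state, runs replicate chains with the node fossilized
#' to that state; per replicate i, `BF_i(s1 vs s2) = 2 * (logHM_i(s1) -
#' logHM_i(s2))` where logHM is the harmonic-mean log marginal likelihood.
#' Replicates are paired across states (replicate i of every arm shares one
#' derived seed), and the first state in `states` is the reference compared
#' against each alternative.
#'
#' A state whose fossilization makes the likelihood identically zero is
#' reported as impossible, with `BF = +Inf` against it.
#'
#' @inheritParams run_chain
#' @param node tip labels whose MRCA is fossilized (or a [clade_query()] row).
#' @param states candidate states; the first is the reference.
#' @param n_replicates replicate chains per state (>= 2).
#' @param burnin_fraction leading fraction of each trace discarded before the
#'   harmonic mean.
#' @param scale `"pagel"` (BF = 2 x log harmonic-mean difference, default) or
#'   `"raw"` (plain log difference).
#' @return tibble of class `bf_result` with columns `comparison`, `state1`,
#'   `state2`, `bf_mean`, `bf_se`, `n`, `category`, `note`; attribute
#'   `replicates` holds the per-replicate log harmonic means.
#' @export
bayes_factor_test <- function(trees, scheme, node, states, iterations, seed,
                              n_replicates = 20, prior = prior_spec(),
                              thin = max(1L, iterations %/% 1000L),
                              constraints = NULL, burnin_fraction = 0.25,
                              scale = c("pagel", "raw"), root_prior = NULL,
                              ...) {
  scale <- match.arg(scale)
  if (is.data.frame(node)) node <- node$taxa[[1]]
  assert_that(all(states %in% scheme$states), "unknown state in `states`")
  assert_that(n_replicates >= 2, "need n_replicates >= 2 for a standard error")
  seeds <- derive_seeds(seed, n_replicates, stream = 7L)
  base <- as_node_constraints(constraints)

  loghm <- matrix(NA_real_, n_replicates, length(states),
                  dimnames = list(NULL, states))
  for (s in seq_along(states)) {
    cons <- dplyr::bind_rows(base,
                             node_constraint(node, states[s], label = "bf_node"))
    for (i in seq_len(n_replicates)) {
      tr <- tryCatch(
        run_chain(trees, scheme, iterations = iterations, seed = seeds[i],
                  prior = prior, thin = thin, constraints = cons,
                  root_prior = root_prior, ...),
        error = function(e) {
          if (grepl("zero likelihood", conditionMessage(e))) NULL else stop(e)
        })
      if (!is.null(tr)) {
        ns <- nrow(tr$samples)
        loghm[i, s] <- suppressWarnings(
          harmonic_mean_logml(tr$samples$logL,
                              burnin = ceiling(burnin_fraction * ns)))
      }
    }
  }
  impossible <- apply(loghm, 2, function(col) all(is.na(col)))
  loghm[, impossible] <- -Inf

  fac <- if (scale == "pagel") 2 else 1
  out <- purrr::map_dfr(states[-1], function(s2) {
    s1 <- states[1]
    bfi <- fac * (loghm[, s1] - loghm[, s2])
    note <- if (impossible[s2]) {
      sprintf("state %s impossible at node", s2)
    } else if (impossible[s1]) {
      sprintf("state %s impossible at node", s1)
    } else {
      NA_character_
    }
    tibble(
      comparison = paste(s1, "vs", s2), state1 = s1, state2 = s2,
      bf_mean = mean(bfi),
      bf_se = if (all(is.finite(bfi))) sd(bfi) / sqrt(length(bfi)) else NA_real_,
      n = sum(!is.na(bfi)),
      note = note)
  })
  out$category <- bf_category(out$bf_mean)
  class(out) <- c("bf_result", class(out))
  attr(out, "replicates") <- loghm
  attr(out, "bf_replicates") <- vapply(states[-1], function(s2) {
    fac * (loghm[, states[1]] - loghm[, s2])
  }, numeric(n_replicates))
  out
}

#' @rdname bayes_factor_test
#' @param result a `bf_result`.
#' @param path output TSV file.
#' @export
write_bf_result <- function(result, path) {
  readr::write_tsv(as_tibble(result), path)
  invisible(path)
}

#' Map reconstructed states onto a chronogram
#'
#' Labels each queried node with its modal reconstructed state (ties are
#' labeled `"ambiguous"`); clades whose modal state is in `focal_states` get
#' crown ages with HPD intervals from [clade_age_report()].
#'
#' @param chronograms ultrametric [tree_sample] (or single `phylo`); ages in
#'   million years.
#' @param ancestral an `ancestral_summary`.
#' @param queries the clade queries used for the summary (label-matched).
#' @param focal_states states whose clades are dated (default: all).
#' @param mass HPD mass.
#' @return object of class `annotated_chronogram`: list with `tree` (first
#'   chronogram, node labels set to `state|pp`), `labels` (tibble: node,
#'   modal_state, pp, tie_states), `ages` (clade age tibble).
#' @export
annotate_chronogram <- function(chronograms, ancestral, queries,
                                focal_states = NULL, mass = 0.95) {
  if (inherits(chronograms, "phylo")) chronograms <- tree_sample(chronograms)
  queries <- as_clade_queries(queries)
  labels <- as_tibble(ancestral) |>
    dplyr::group_by(.data$node) |>
    dplyr::summarise(
      modal_state = {
        mx <- max(.data$pp_mean)
        winners <- .data$state[.data$pp_mean >= mx - 1e-12]
        if (length(winners) > 1) "ambiguous" else winners
      },
      pp = max(.data$pp_mean),
      tie_states = paste(.data$state[.data$pp_mean >= max(.data$pp_mean) - 1e-12],
                         collapse = "|"),
      .groups = "drop") |>
    dplyr::rename(label = "node")
  labels <- dplyr::left_join(queries, labels, by = "label")
  missing <- labels$label[is.na(labels$modal_state)]
  if (length(missing) > 0) {
    abort(sprintf("no ancestral summary for quer%s: %s",
                  if (length(missing) == 1) "y" else "ies",
                  paste(missing, collapse = ", ")))
  }
  if (is.null(focal_states)) {
    focal <- labels
  } else {
    focal <- labels[labels$modal_state %in% focal_states, ]
  }
  ages <- if (nrow(focal) > 0) {
    clade_age_report(chronograms, focal[, c("label", "taxa")], mass = mass)
  } else {
    clade_age_report(chronograms, queries, mass = mass)[0, ]
  }
  tree <- chronograms$trees[[1]]
  ntip <- ape::Ntip(tree)
  node_lab <- rep("", tree$Nnode)
  for (i in seq_len(nrow(labels))) {
    nd <- mrca_node(tree, labels$taxa[[i]])
    node_lab[nd - ntip] <- sprintf("%s|pp=%.3f", labels$modal_state[i],
                                   labels$pp[i])
  }
  tree$node.label <- node_lab
  structure(list(tree = tree,
                 labels = labels[, c("label", "modal_state", "pp", "tie_states")],
                 ages = ages),
            class = "annotated_chronogram")
}

#' @export
print.annotated_chronogram <- function(x, ...) {
  cat("<annotated_chronogram>\n")
  print(x$labels)
  if (nrow(x$ages) > 0) print(x$ages)
  invisible(x)
}

#' Write an annotated chronogram as NEXUS plus an age TSV
#'
#' @param x an `annotated_chronogram`.
#' @param tree_path NEXUS output (node labels carry `state|pp=`).
#' @param age_path optional TSV for the clade ages.
#' @export
write_annotated_chronogram <- function(x, tree_path, age_path = NULL) {
  ape::write.nexus(x$tree, file = tree_path)
  if (!is.null(age_path)) write_age_report(x$ages, age_path)
  invisible(tree_path)
}
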