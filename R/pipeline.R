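#' Read and validate a pipeline run configuration
#'
#' Single structured-text (YAML) file with sections mirroring the analysis
#' stages: `paths` (trees, traits, scheme, chronograms, out), `prior`,
#' `mcmc` (iterations, thin, replicates, seed, burnin_fraction), `queries`
#' (label: tip list), `bf` (node, states, replicates), `dating`
#' (focal_states, mass), `sim` (fixture or generator settings).
#'
#' @param path YAML config file.
#' @return nested list of class `run_config` with defaults filled.
#' @export
read_run_config <- function(path) {
  assert_that(file.exists(path), sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  cfg$paths <- cfg$paths %||% list()
  cfg$paths$out <- cfg$paths$out %||% "apisoc_out"
  cfg$paths <- lapply(cfg$paths, function(p) {
    # YAML parses bare '.' as a (failed) float; insist on real strings
    if (length(p) != 1 || is.na(p)) {
      abort("config paths must be scalar strings (quote values like \".\")")
    }
    as.character(p)
  })
  cfg$prior <- do.call(prior_spec, c(
    list(kind = cfg$prior$kind %||% "uniform_fixed"),
    cfg$prior[intersect(names(cfg$prior), c("lo", "hi", "hyper_lo", "hyper_hi"))]))
  m <- cfg$mcmc %||% list()
  cfg$mcmc <- list(iterations = m$iterations %||% 100000L,
                   thin = m$thin %||% 100L,
                   replicates = m$replicates %||% 5L,
                   seed = m$seed %||% 1L,
                   burnin_fraction = m$burnin_fraction %||% 0.25)
  assert_that(cfg$mcmc$replicates >= 1, "mcmc replicates must be >= 1")
  structure(cfg, class = "run_config")
}

load_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  assert_that(inherits(config, "run_config"), "config must be a run_config or path")
  config
}

config_scheme <- function(config) {
  scheme <- if (!is.null(config$scheme) && is.character(config$scheme)) {
    builtin_scheme(config$scheme)
  } else if (!is.null(config$paths$scheme)) {
    read_scheme(config$paths$scheme)
  } else {
    abort("config names no coding scheme (`scheme:` or `paths: scheme:`)")
  }
  if (!is.null(config$paths$traits)) {
    scheme <- set_tips(scheme, read_traits(config$paths$traits))
  }
  assert_that(length(scheme$tips) > 0,
              "no tip codings: supply `paths: traits:` or a scheme file with tips")
  scheme
}

config_queries <- function(config) {
  assert_that(!is.null(config$queries), "config lists no node queries")
  as_clade_queries(lapply(config$queries, as.character))
}

write_manifest <- function(config, out, stage, extra = list()) {
  manifest <- c(list(stage = stage,
                     package_version = as.character(utils::packageVersion("apisoc")),
                     seed = config$mcmc$seed,
                     mcmc = config$mcmc,
                     prior = unclass(config$prior)),
                extra)
  yaml::write_yaml(manifest, file.path(out, paste0("manifest_", stage, ".yml")))
}

#' Pipeline stage: simulate inputs
#'
#' With `sim: fixture: true` writes the apid-like fixture files; otherwise
#' builds a [sim_config()] from the `sim` section (n_tips, rates, root_state,
#' scheme, ...) and writes the simulated dataset plus its ground-truth
#' sidecar.
#'
#' @param config a `run_config` or path to one.
#' @return the output directory, invisibly.
#' @export
pipeline_simulate <- function(config) {
  config <- load_config(config)
  out <- config$paths$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  sim <- config$sim %||% list(fixture = TRUE)
  if (isTRUE(sim$fixture)) {
    fx <- make_apid_fixture(sample_size = sim$sample_size %||% 100,
                            jitter = sim$jitter %||% 0.05,
                            seed = config$mcmc$seed)
    write_trees(fx$trees, file.path(out, "trees.nwk"))
    write_trees(fx$tree, file.path(out, "chronogram.nwk"))
    write_traits(fx$traditional, file.path(out, "traits_traditional.tsv"))
    write_traits(fx$complex, file.path(out, "traits_complex.tsv"))
    write_scheme(fx$traditional, file.path(out, "scheme_traditional.yml"))
    write_scheme(fx$complex, file.path(out, "scheme_complex.yml"))
    yaml::write_yaml(setNames(fx$queries$taxa, fx$queries$label),
                     file.path(out, "queries.yml"))
    message(sprintf("wrote apid fixture (%d trees, %d tips) to %s",
                    length(fx$trees), ape::Ntip(fx$tree), out))
  } else {
    scheme <- config_scheme_for_sim(sim)
    n_tips <- sim$n_tips %||% abort("sim section needs n_tips")
    cfg <- sim_config(master_seed = config$mcmc$seed, n_tips = n_tips,
                      scheme = scheme, rates = unlist(sim$rates),
                      root_state = sim$root_state,
                      birth = sim$birth %||% 1, death = sim$death %||% 0,
                      depth = sim$depth %||% 1,
                      sample_size = sim$sample_size %||% 50,
                      jitter = sim$jitter %||% 0.1,
                      polymorphism_prob = sim$polymorphism_prob %||% 0.05)
    ds <- simulate_dataset(cfg)
    write_dataset(ds, out)
    message(sprintf("wrote simulated dataset (%d tips, %d trees, %d events) to %s",
                    cfg$n_tips, cfg$sample_size, nrow(ds$history$events), out))
  }
  write_manifest(config, out, "simulate")
  invisible(out)
}

config_scheme_for_sim <- function(sim) {
  if (!is.null(sim$scheme) && is.character(sim$scheme)) builtin_scheme(sim$scheme)
  else if (!is.null(sim$scheme_file)) read_scheme(sim$scheme_file)
  else abort("sim section needs `scheme` (builtin name) or `scheme_file`")
}

#' Pipeline stage: fit replicate chains and summarize ancestral states
#'
#' Runs `replicates` chains with seeds derived from the master seed, writes
#' one trace TSV per chain and the replicate-combined ancestral summary.
#'
#' @param config a `run_config` or path.
#' @return the `ancestral_summary`, invisibly.
#' @export
pipeline_fit <- function(config) {
  config <- load_config(config)
  out <- config$paths$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  assert_that(!is.null(config$paths$trees), "config$paths$trees is required")
  trees <- read_trees(config$paths$trees)
  scheme <- config_scheme(config)
  queries <- config_queries(config)
  seeds <- derive_seeds(config$mcmc$seed, config$mcmc$replicates, stream = 1L)
  traces <- vector("list", config$mcmc$replicates)
  for (i in seq_len(config$mcmc$replicates)) {
    tr <- run_chain(trees, scheme, iterations = config$mcmc$iterations,
                    thin = config$mcmc$thin, seed = seeds[i],
                    prior = config$prior, queries = queries)
    readr::write_tsv(tr$samples, file.path(out, sprintf("trace_%02d.tsv", i)))
    message(sprintf("chain %d/%d: mean logL %.2f; acceptance %s", i,
                    config$mcmc$replicates, mean(tr$samples$logL),
                    paste(sprintf("%s %.2f", tr$accept$move, tr$accept$rate),
                          collapse = ", ")))
    traces[[i]] <- tr
  }
  summary <- summarize_ancestral(traces,
                                 burnin_fraction = config$mcmc$burnin_fraction)
  write_ancestral_summary(summary, file.path(out, "ancestral_summary.tsv"))
  write_manifest(config, out, "fit",
                 list(replicate_seeds = as.list(seeds),
                      burnin = ceiling(config$mcmc$burnin_fraction *
                                         nrow(traces[[1]]$samples))))
  invisible(summary)
}

#' Pipeline stage: Bayes Factor tests of fixed ancestral states
#'
#' @param config a `run_config` or path.
#' @return the `bf_result`, invisibly.
#' @export
pipeline_bf <- function(config) {
  config <- load_config(config)
  out <- config$paths$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  assert_that(!is.null(config$bf), "config has no `bf` section")
  trees <- read_trees(config$paths$trees)
  scheme <- config_scheme(config)
  res <- bayes_factor_test(
    trees, scheme, node = as.character(config$bf$node),
    states = as.character(config$bf$states),
    iterations = config$mcmc$iterations, thin = config$mcmc$thin,
    seed = config$mcmc$seed, n_replicates = config$bf$replicates %||% 20,
    prior = config$prior,
    burnin_fraction = config$mcmc$burnin_fraction)
  write_bf_result(res, file.path(out, "bayes_factors.tsv"))
  write_manifest(config, out, "bf")
  invisible(res)
}

#' Pipeline stage: date focal clades on a chronogram
#'
#' Requires the ancestral summary written by [pipeline_fit()]; annotates the
#' chronogram's queried nodes with modal states and reports crown ages with
#' HPD intervals for clades in the focal states.
#'
#' @param config a `run_config` or path.
#' @return the `annotated_chronogram`, invisibly.
#' @export
pipeline_date <- function(config) {
  config <- load_config(config)
  out <- config$paths$out
  assert_that(!is.null(config$paths$chronograms),
              "config$paths$chronograms is required for dating")
  summary_path <- file.path(out, "ancestral_summary.tsv")
  if (!file.exists(summary_path)) {
    abort("no ancestral summary found: run pipeline_fit() before pipeline_date()")
  }
  summary <- readr::read_tsv(summary_path, show_col_types = FALSE)
  class(summary) <- c("ancestral_summary", class(summary))
  chrono <- read_trees(config$paths$chronograms)
  ann <- annotate_chronogram(chrono, summary, config_queries(config),
                             focal_states = config$dating$focal_states,
                             mass = config$dating$mass %||% 0.95)
  write_annotated_chronogram(ann, file.path(out, "annotated_chronogram.nex"),
                             file.path(out, "clade_ages.tsv"))
  write_manifest(config, out, "date")
  invisible(ann)
}

#' Pipeline stage: collate outputs into one summary document
#'
#' @param config a `run_config` or path.
#' @return path of the report, invisibly.
#' @export
pipeline_report <- function(config) {
  config <- load_config(config)
  out <- config$paths$out
  lines <- c("apisoc run report", strrep("=", 17), "")
  for (f in c("ancestral_summary.tsv", "bayes_factors.tsv", "clade_ages.tsv")) {
    p <- file.path(out, f)
    if (file.exists(p)) {
      lines <- c(lines, f, strrep("-", nchar(f)),
                 readLines(p, warn = FALSE), "")
    }
  }
  path <- file.path(out, "report.txt")
  writeLines(lines, path)
  invisible(path)
}
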