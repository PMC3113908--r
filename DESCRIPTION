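Package: apisoc
Title: Bayesian Ancestral-State Reconstruction of Social Behavior on
    Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constrained multi-state Markov models of discrete trait
    evolution on phylogenies, aimed at the evolution of eusociality in
    apid bees. Implements Felsenstein pruning with polymorphic
    (ambiguous) tip codings and node fossilization, Metropolis-Hastings
    MCMC over a posterior sample of trees with uniform or
    exponential-hyperprior rate priors and reversible-jump rate classes,
    harmonic-mean marginal likelihoods and Bayes Factor node tests,
    replicate-averaged ancestral-state posterior summaries, and dating of
    trait origins on ultrametric chronograms via highest-posterior-density
    intervals of clade ages. A synthetic-data generator (birth-death
    trees, Gillespie character histories under constrained rate matrices,
    pseudo-posterior tree samples, an apid-like fixture) provides inputs
    with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
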