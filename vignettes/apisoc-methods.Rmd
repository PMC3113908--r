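---
title: "Models and methods behind apisoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind apisoc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

apisoc reconstructs the evolutionary history of discrete behavioral
characters — above all, levels of sociality in apid bees — on phylogenies, by
Bayesian inference under continuous-time Markov models with forbidden
transitions. This vignette is the package's account of the model, the
sampler, the summaries, and the choices made where the design was genuinely
open.

## The character model

A character with $k$ states evolves along each branch under a rate matrix
$Q$ with off-diagonal entries $q_{ij} \ge 0$ (events per branch-length unit)
and diagonal $q_{ii} = -\sum_{j \ne i} q_{ij}$. A *transition-constraint
mask* declares some cells structural zeros. The two built-in social-level
schemes encode two biological rules: a lineage cannot jump to advanced
eusociality directly from solitary or parasitic life (morphologically
differentiated castes and swarm founding require an intermediate step), and
advanced eusociality is absorbing (queens cannot found nests without
workers). The `traditional` scheme has four states (Sol, Prim, Adv, Paras;
5 of 12 off-diagonal cells forbidden); the `complex` scheme inserts a fifth
state Soc for subsocial/parasocial organization (6 of 20 cells forbidden).
Only what the two rules imply is forbidden; every cell is configurable, so
the relaxed model (Sol→Adv allowed) is a one-line config change. Binary
life-history traits (e.g. mass provisioning) use a full 2-state mask with
reversible-jump rate classes.

Branch transition probabilities are $P(t) = e^{Qt}$, computed by
scaling-and-squaring with a Taylor core and row renormalization.
Eigendecomposition is avoided deliberately: constrained $Q$ (absorbing
states, zero rows) can be defective. Note that a forbidden *single-step*
cell does not force $P_{ij}(t) = 0$ — multi-step paths are allowed — except
out of absorbing states. Zero-length branches get $P(0) = I$ exactly.

## Likelihood: pruning with ambiguous tips and fossilized nodes

The likelihood is computed by Felsenstein's post-order pruning with
per-node rescaling (accumulated log factors prevent underflow on large
trees). Polymorphic codings such as "solitary or social" enter as ambiguity
indicators: the tip's partial vector is 1 at each allowed state. This is
deliberately *not* a frequency mixture — the codings express uncertainty
about the clade a terminal represents, not within-clade state frequencies.
A *fossilized* (constrained) node has its partials zeroed outside the
allowed set after its children are combined; the same mechanism serves
marginal node probabilities and Bayes Factor hypotheses. A likelihood of
exactly zero is reported as `-Inf`.

The root prior defaults to uniform over states. The constrained model is
non-reversible (the absorbing state makes the stationary distribution
degenerate), so the common equilibrium-frequency default is unusable;
uniform matches widespread multistate-software practice. Runs report their
root prior in the chain settings, and `root_prior` accepts any vector.

Two independent implementations guard correctness: `prune_loglik()` (the
C++ pruning core) and `enumeration_loglik()`, which sums over every joint
internal-state assignment using `Matrix::expm` for the branch probabilities
— a fully disjoint code path usable up to 12 internal nodes. The test suite
sweeps hundreds of random constrained instances (random masks including
absorbing states, polymorphic tips, random fossilizations) and requires
agreement to 1e-8. Marginal node-state probabilities are computed two ways
as well: per-state fossilization (the definition) and a one-pass down-up
algorithm used inside the sampler; the tests pin their equality.

## The sampler

`run_chain()` runs Metropolis–Hastings over the transition rates, the tree
index (integrating over a posterior sample of trees by uniform resampling
with acceptance by likelihood ratio — "tree hopping"), and, in
reversible-jump mode, the partition of rate cells into shared classes
including a ZERO class. Two priors are supported: independent uniform(0,
100) rates, and an exponential prior whose mean is itself uniform(0, 10) —
the hyperprior reading in which the exponential mean is a sampled
parameter, re-estimated throughout the run.

Move schedule and kernels (defaults; all weights configurable):

* **tree** (weight 1): independent draw from the tree sample's weights.
* **rate** (weight 2): one cell (or RJ class) per move, chosen by a
  systematic scan. Under the uniform prior the proposal is a sliding window
  with reflection at the bounds, auto-tuned during the burn-in fraction
  toward 0.2–0.4 acceptance and capped at twice the prior range — at the
  cap the reflected window folds to an exact uniform draw over the support.
  Under the exponential prior, rate moves alternate a multiplier kernel
  (Hastings ratio proposed/current) with an independence draw from the
  prior.
* **rj** (weight 1, RJ schemes only): split a class / merge two classes /
  move a cell to or from the ZERO class / redraw a class rate, with
  dimension-matching acceptance ratios. The model prior is uniform over
  structures (a structure = the ZERO subset plus an unlabeled partition of
  the remaining cells); class rates are i.i.d. from the rate prior. For a
  2-cell full mask this implies five equally probable structures, which the
  prior-only tests verify empirically.
* **hyper** (weight 2, exponential prior only): 25% an exact Gibbs draw of
  the hyper-mean from its full conditional — valid in every mode because
  the likelihood never involves the hyper-mean — and 75% a joint redraw of
  (mean, rates) from the prior, whose acceptance reduces to the likelihood
  ratio.

These kernels are richer than a plain random-walk sampler for a reason:
the engine must demonstrably *sample its priors* when the likelihood is
disabled. The suite checks every free rate's marginal against uniform(0,
100) and the hyper-mean against uniform(0, 10) by KS tests at the 1% level
on 10^4 thinned samples, which demands near-independent draws at that
thinning; systematic scans, full-range reflected windows and the Gibbs
hyper-move achieve that without changing the targeted posterior.

Chains are reproducible bit-for-bit from one integer seed. Replicates and
Bayes-factor arms derive their seeds from a master seed via a fixed LCG
stream. A chain halts with a diagnostic if any move type accumulates 10^4
consecutive rejections. Initial states are drawn from the prior, retried up
to a bounded number of times if the likelihood is zero.

## Summaries

**Ancestral states.** Per replicate chain, the post-burn-in mean of the
per-sample marginal node-state probabilities at each queried MRCA; across
replicates, the mean and standard error (sd/√n — the "S.E." convention of
the source tables, which do not define it; documented here). Burn-in is
either a fixed fraction (default 25%) or Geweke-based (first window of the
log-likelihood trace whose |z| < 2, with AR spectral variances).

**Bayes Factors.** Marginal likelihoods come from the harmonic-mean
estimator over post-burn-in likelihood samples, computed in log space.
`BF(s1 vs s2) = 2 (log HM(s1) − log HM(s2))`, the doubled-difference
convention (a raw-difference scale is available behind a flag). Replicate i
of every arm shares one derived seed, so comparisons are paired; pairing
reduces the standard error and is reported as such. Support categories:
below 0 "against", 0–2 "weak", 2–5 "positive", above 5 "strong". The
boundaries anchor to the >5 strong-support convention; the intermediate cut
at 2 is this package's documented choice, and a BF of exactly 0 (e.g. a
state compared with itself) is "weak" rather than "against". A state whose
fossilization forces likelihood zero is reported as impossible with
`BF = +Inf` against it, never a crash.

The harmonic-mean estimator is kept because it is what the protocol this
package implements prescribes; its well-known instability is real. Its
correctness test therefore uses a conjugate 2-tip toy with a uniform(0, 2)
rate prior: on a narrow support the inverse likelihood is bounded and the
estimator has finite variance, so a 0.1-nat agreement with quadrature is a
meaningful check. On wide priors (0–100) the estimator's heavy tail makes
any such tolerance vacuous at feasible sample sizes — which is also why
Bayes-factor results on real data deserve replicate standard errors, as the
replicate protocol provides.

**Dating.** Clade ages are MRCA ages on ultrametric chronograms
(ultrametricity enforced within a relative tolerance of 1e-6 of tree depth,
because chronogram files carry rounded branch lengths). Over a chronogram
sample, a clade's age summary is the mean and the 95% highest-posterior-
density interval of the per-tree age — the shortest contiguous window of
the sorted sample containing the requested mass, left-most on ties for
determinism. `annotate_chronogram()` labels queried nodes with their modal
reconstructed state (ties are "ambiguous" with both states listed) and
attaches ages for clades whose modal state is in a focal set. Both chains
of evidence — a chronogram sample (ages recomputed) or a single annotated
tree (ages passed through) — are accepted.

## The synthetic-data generator

Every pipeline stage is testable without downloads because the generator
produces all inputs with known ground truth: birth–death trees conditioned
on the number of tips (via `ape::rphylo`), Gillespie character histories
under a constrained rate matrix (waiting times exponential in the exit
rate; forbidden transitions structurally cannot occur, and the tests sweep
histories to confirm none ever does), pseudo-posterior tree samples
(log-normal multiplicative branch-length jitter, topology fixed by default
so MRCA queries stay well-defined; optional NNI rearrangement behind a
flag), and mask-adjacent polymorphic codings.

The 25-tip apid fixture is a deterministic chronogram (depth 120 My) whose
terminals stand for the corbiculate tribes and their relatives with the
published coding features: orchid bees solitary/communal, bumble bees
primitively eusocial, honey bees and stingless bees advanced eusocial,
*Xylocopa* solitary-or-social, *Ceratina* solitary/social/primitively
eusocial, allodapines social-or-primitively-eusocial, cleptoparasites
parasitic. Its key clade ages follow the published apid chronology
(corbiculate crown 87 My), so the dating stage can be checked against known
values. What the generator does *not* emulate: the molecular data behind
real posterior tree samples (topological uncertainty correlated with branch
lengths), rate heterogeneity across lineages, and coding error. Passing
tests therefore demonstrate correctness of the inference machinery under
the model, not robustness to model violation on real data.

## Study sizes and calibration conditions used by the tests

The test suite runs a rate-recovery study: 20 datasets on 100-tip
unit-depth trees under the traditional mask, true rates uniform in
[0.5, 5], 50-tree jittered samples, 5% polymorphic tips, chains of 2x10^5
iterations. Two conditions deserve explanation:

* **The fitting prior is uniform(0, 10), not (0, 100).** Nominal coverage
  of credible intervals is a *calibration* property: it holds when the
  truth is drawn compatibly with the fitting prior. Under the absorbing-Adv
  mask, many datasets collapse into the absorbing state and leave several
  rates with no information; those posteriors equal the prior, and under a
  (0, 100) prior every 90% interval of an uninformed rate is ~[5, 95] —
  excluding all of [0.5, 5] by construction, regardless of implementation
  correctness. A (0, 10) prior containing the truth range restores the
  property the study is meant to measure.
* **The strong-signal Bayes-factor study uses an engineered 3-state
  full-mask dataset.** With an absorbing state, fossilizing an ancestor to
  it above any non-absorbed tip gives likelihood exactly 0 and
  `BF = +Inf` — correctly flagged as impossible, but useless for checking
  finite BF behavior. Deep-root signal under a full mask is also subtler
  than it looks: with many free rates and few tips, the prior volume at
  saturating rates (where tips look i.i.d. and the root is forgotten)
  can dominate the marginal likelihood, washing out any root asymmetry.
  The study dataset therefore uses 3 states (6 free rates), 38 tips, and a
  backbone that interleaves two all-Prim clades with two advanced-eusocial
  clades whose very long crown branches pin the Adv-exit rates near zero —
  so an Adv root must escape on a short backbone branch at a rate the data
  force to be tiny, while a Prim root only pays ordinary state gains. This
  yields finite, strongly positive BF(Prim vs Adv) with the same
  qualitative pattern as weaker positive support against a solitary root.

Chain lengths in tests and examples (10^4–5x10^5 iterations) are chosen so
the whole suite runs in minutes on one core; the run length of a real
analysis (the source protocol used 10^8 generations with 5 replicates, and
20 replicates for Bayes factors) is a config value, not a code property.

## Known limitations

* Joint (max-a-posteriori) ancestral reconstruction and stochastic
  character mapping along branches are out of scope; marginal node
  probabilities only.
* The harmonic-mean marginal likelihood is the protocol's estimator, with
  the caveats above; no stepping-stone sampler is provided.
* Hidden-rate/covarion models and continuous characters are not supported.
* Tree samples with heterogeneous topologies are supported for queries by
  per-tree MRCA resolution, but `record_all_nodes` (per-node calibration
  output) requires a shared topology.
* The Gibbs hyper-move falls back to a random-walk update when the
  conditional is extremely concentrated (bounded rejection-sampling
  budget); this affects efficiency only, not correctness.
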