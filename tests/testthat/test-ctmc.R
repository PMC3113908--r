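test_that("transition matrices behave like a CTMC semigroup", {
  trad <- builtin_scheme("traditional")
  set.seed(21)
  Q <- rate_matrix(trad, runif(7, 0.2, 3))
  expect_equal(transition_matrix(Q, 0), diag(4), ignore_attr = TRUE)
  P <- transition_matrix(Q, 0.7)
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(P >= 0 & P <= 1))
  # absorbing advanced-eusocial row stays an indicator for any t
  for (t in c(0.1, 1, 10, 100)) {
    expect_equal(unname(transition_matrix(Q, t)["Adv", ]), c(0, 0, 1, 0),
                 tolerance = 1e-12)
  }
  # forbidden single-step cells can still be reached by multi-step paths
  expect_gt(P["Sol", "Adv"], 0)
  # 2-state symmetric rate-1 closed form: stay prob (1 + exp(-2qt)) / 2
  Q2 <- rate_matrix(coding_scheme(c("A", "B")), c(1, 1))
  expect_equal(transition_matrix(Q2, 0.5)[1, 1], 0.5 * (1 + exp(-1)),
               tolerance = 1e-12)
  expect_error(transition_matrix(Q, -1), ">= 0")
  # agreement with the independent Pade implementation
  expect_equal(unclass(transition_matrix(Q, 1.3)),
               as.matrix(Matrix::expm(apisoc:::unclass_matrix(Q) * 1.3)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("pruning equals brute-force enumeration on random constrained instances", {
  for (seed in 1:100) {
    inst <- random_instance(seed)
    lp <- prune_loglik(inst$tree, inst$Q, inst$scheme,
                       constraints = inst$constraints)
    le <- enumeration_loglik(inst$tree, inst$Q, inst$scheme,
                             constraints = inst$constraints)
    if (is.finite(lp) || is.finite(le)) {
      expect_lt(abs(lp - le), 1e-10)
    } else {
      expect_identical(is.finite(lp), is.finite(le))
    }
  }
})

test_that("degenerate likelihoods match hand arithmetic", {
  tree <- ape::read.tree(text = "(A:1,B:2);")
  sch <- set_tips(coding_scheme(c("A", "B")), list(A = "-", B = "-"))
  Q <- rate_matrix(sch, c(0.7, 1.3))
  # fully ambiguous tips: likelihood 1 for any rates and prior
  expect_equal(prune_loglik(tree, Q, sch), 0)
  # explicit 2-term sum over root states for observed tips
  sch2 <- set_tips(coding_scheme(c("A", "B")), list(A = "A", B = "B"))
  P1 <- transition_matrix(Q, 1)
  P2 <- transition_matrix(Q, 2)
  byhand <- log(0.5 * (P1[1, 1] * P2[1, 2]) + 0.5 * (P1[2, 1] * P2[2, 2]))
  expect_equal(prune_loglik(tree, Q, sch2), byhand)
  expect_equal(enumeration_loglik(tree, Q, sch2), byhand)
  # root fossilized to the absorbing state above a solitary tip: impossible
  trad <- set_tips(builtin_scheme("traditional"),
                   list(A = "Sol", B = "Adv", C = "Adv", D = "Adv"))
  Qt <- rate_matrix(trad, runif(7, 0.5, 2))
  t4 <- balanced4()
  expect_identical(
    prune_loglik(t4, Qt, trad,
                 constraints = node_constraint(t4$tip.label, "Adv")),
    -Inf)
  # zero-length branches: P(0) = I exactly, likelihood well-defined
  t0 <- ape::read.tree(text = "(A:0,B:0);")
  expect_equal(prune_loglik(t0, Q, sch2), -Inf) # A and B cannot both hold
  expect_equal(prune_loglik(t0, Q, set_tips(sch, list(A = "A", B = "A"))),
               log(0.5))
})

test_that("likelihood invariances hold: child order, relabeling, ambiguity, scaling", {
  for (seed in 101:130) {
    inst <- random_instance(seed)
    base <- prune_loglik(inst$tree, inst$Q, inst$scheme,
                         constraints = inst$constraints)
    if (!is.finite(base)) next
    # child order: rotate children at the root
    rot <- ape::rotate(inst$tree, ape::Ntip(inst$tree) + 1)
    expect_equal(prune_loglik(rot, inst$Q, inst$scheme,
                              constraints = inst$constraints), base,
                 tolerance = 1e-10)
    # consistent state relabeling (reverse the state order everywhere)
    k <- length(inst$scheme$states)
    perm <- rev(seq_len(k))
    sch2 <- coding_scheme(inst$scheme$states[perm], name = "perm")
    sch2$mask <- inst$scheme$mask[perm, perm]
    sch2$tips <- inst$scheme$tips
    Q2 <- apisoc:::unclass_matrix(inst$Q)[perm, perm]
    dimnames(Q2) <- list(sch2$states, sch2$states)
    attr(Q2, "scheme") <- sch2
    expect_equal(prune_loglik(inst$tree, Q2, sch2,
                              constraints = inst$constraints), base,
                 tolerance = 1e-10)
    # enlarging a tip's state set never decreases the likelihood
    sch3 <- inst$scheme
    tx <- sample(names(sch3$tips), 1)
    sch3$tips[[tx]] <- sch3$states
    expect_gte(prune_loglik(inst$tree, inst$Q, sch3,
                            constraints = inst$constraints) + 1e-10, base)
    # rate/branch-length scaling identity
    c0 <- 3.7
    Qs <- apisoc:::unclass_matrix(inst$Q) * c0
    dimnames(Qs) <- dimnames(inst$Q)
    attr(Qs, "scheme") <- inst$scheme
    tr2 <- inst$tree
    tr2$edge.length <- tr2$edge.length / c0
    expect_equal(prune_loglik(tr2, Qs, inst$scheme,
                              constraints = inst$constraints), base,
                 tolerance = 1e-9)
  }
})

test_that("marginal node probabilities are exact conditionals", {
  tree <- balanced4()
  sch <- coding_scheme(c("A", "B", "C"))
  sch <- set_tips(sch, list(A = "A", B = c("A", "B"), C = "C", D = "B"))
  set.seed(31)
  Q <- rate_matrix(sch, runif(6, 0.2, 2))
  p <- marginal_node_probs(tree, Q, c("A", "B"), sch)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # oracle: conditional probability from enumeration with the node fossilized
  node_ll <- vapply(sch$states, function(s) {
    enumeration_loglik(tree, Q, sch,
                       constraints = node_constraint(c("A", "B"), s))
  }, numeric(1))
  expect_equal(unname(p), unname(exp(node_ll - apisoc:::logsumexp(node_ll))),
               tolerance = 1e-10)
  # the one-pass all-node algorithm agrees with per-state fossilization
  allm <- node_marginals_all(tree, Q, sch)
  nd <- mrca_node(ape::reorder.phylo(tree, "postorder"), c("A", "B"))
  expect_equal(unname(allm[, nd]), unname(p), tolerance = 1e-10)
  # a node already fossilized in the inputs yields an indicator
  pfix <- marginal_node_probs(tree, Q, c("A", "B"), sch,
                              constraints = node_constraint(c("A", "B"), "B"))
  expect_equal(unname(pfix), c(0, 1, 0))
  # inconsistent data/model errors rather than returning NaN
  schbad <- coding_scheme(c("A", "B"), forbidden = c("A->B", "B->A"))
  schbad <- set_tips(schbad, list(A = "A", B = "B", C = "A", D = "B"))
  Qb <- rate_matrix(schbad, numeric(0))
  expect_error(marginal_node_probs(tree, Qb, c("A", "B"), schbad),
               "inconsistent")
})
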