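test_that("birth-death trees honor the conditioning and ultrametry contracts", {
  set.seed(51)
  tr <- simulate_tree(25, birth = 1, death = 0.3)
  expect_equal(ape::Ntip(tr), 25)
  expect_true(ape::is.ultrametric(tr, tol = 1e-6))
  two <- simulate_tree(2, birth = 1, death = 0)
  d <- ape::node.depth.edgelength(two)
  expect_equal(d[1], d[2])
  expect_error(simulate_tree(10, birth = 0.5, death = 0.7), "birth > death")
  expect_equal(max(ape::node.depth.edgelength(rescale_tree_depth(tr, 1))), 1)
})

test_that("character histories follow Gillespie dynamics and the mask", {
  trad <- builtin_scheme("traditional")
  t4 <- balanced4()
  # zero rates: everything inherits the root state, no events
  Q0 <- rate_matrix(trad, rep(0, 7))
  set.seed(52)
  h0 <- simulate_history(t4, Q0, "Prim")
  expect_true(all(h0$tip_states == "Prim"))
  expect_equal(nrow(h0$events), 0)
  # absorbing state: no lineage ever leaves Adv; no forbidden event at all
  set.seed(53)
  long <- ape::read.tree(text = "(A:30,B:30);")
  Q <- rate_matrix(trad, runif(7, 0.5, 2))
  for (i in 1:200) {
    h <- simulate_history(long, Q, sample(c("Sol", "Prim"), 1))
    if (nrow(h$events) > 0) {
      expect_false(any(h$events$from == "Adv"))
      allowed <- trad$mask[cbind(match(h$events$from, trad$states),
                                 match(h$events$to, trad$states))]
      expect_true(all(allowed))
    }
  }
  # 2-state symmetric rate 1, t = 0.5: stay fraction near (1+e^-1)/2
  b2 <- coding_scheme(c("A", "B"))
  Qb <- rate_matrix(b2, c(1, 1))
  tb <- ape::read.tree(text = "(A:0.5,B:0.5);")
  set.seed(54)
  stay <- replicate(4000, {
    h <- simulate_history(tb, Qb, "A")
    h$tip_states[["A"]] == "A"
  })
  p <- 0.5 * (1 + exp(-1))
  expect_lt(abs(mean(stay) - p), 3 * sqrt(p * (1 - p) / 4000))
})

test_that("pseudo-posterior tree samples jitter branch lengths log-normally", {
  tr <- balanced4()
  same <- make_tree_sample(tr, 10, jitter = 0)
  for (t2 in same$trees) expect_equal(t2$edge.length, tr$edge.length)
  expect_length(make_tree_sample(tr, 500, jitter = 0.2), 500)
  set.seed(55)
  ts <- make_tree_sample(tr, 2000, jitter = 0.3)
  lens <- vapply(ts$trees, function(x) mean(x$edge.length), numeric(1))
  expected <- mean(tr$edge.length) * exp(0.3^2 / 2)
  se <- sd(lens) / sqrt(2000)
  expect_lt(abs(mean(lens) - expected), 3 * se)
  expect_equal(ts$trees[[7]]$tip.label, tr$tip.label)
})

test_that("chronogram samples stay ultrametric while ages spread", {
  tr <- ape::read.tree(text = "((A:5,B:5):5,(C:5,D:5):5);")
  same <- make_chronogram_sample(tr, 5, jitter = 0)
  for (t2 in same$trees) {
    expect_equal(sort(t2$edge.length), sort(tr$edge.length))
  }
  set.seed(58)
  cs <- make_chronogram_sample(tr, 400, jitter = 0.1)
  for (t2 in cs$trees[1:20]) expect_true(ape::is.ultrametric(t2, tol = 1e-8))
  expect_true(all(unlist(lapply(cs$trees, function(x) x$edge.length)) >= 0))
  ages <- vapply(cs$trees, function(x) node_age(x, mrca_node(x, c("A", "B"))),
                 numeric(1))
  expect_gt(sd(ages), 0.2)             # ages really do spread
  expect_lt(abs(mean(ages) - 5), 0.2)  # around the input age
  expect_error(make_chronogram_sample(balanced4() |>
                                        (\(x) { x$edge.length[1] <- 9; x })(),
                                      2),
               "ultrametric")
})

test_that("polymorphism injection adds only mask-adjacent states", {
  trad <- set_tips(builtin_scheme("traditional"),
                   list(A = "Sol", B = "Prim", C = "Adv", D = "Paras"))
  expect_equal(add_polymorphism(trad, 0)$tips, trad$tips)
  set.seed(56)
  poly <- add_polymorphism(trad, 1)
  expect_true(all(lengths(poly$tips) >= 2))
  for (tx in names(poly$tips)) {
    added <- setdiff(poly$tips[[tx]], trad$tips[[tx]])
    for (s in added) {
      base <- trad$tips[[tx]]
      expect_true(any(trad$mask[base, s] | trad$mask[s, base]))
    }
  }
  # ambiguity monotonicity: polymorphized data are at least as likely
  t4 <- balanced4()
  set.seed(57)
  Q <- rate_matrix(trad, runif(7, 0.3, 2))
  ll0 <- prune_loglik(t4, Q, trad)
  llp <- prune_loglik(t4, Q, poly)
  expect_gte(llp + 1e-12, ll0)
})

test_that("topology enumeration matches the double-factorial counts", {
  expect_length(enumerate_topologies(2), 1)
  expect_length(enumerate_topologies(3), 3)
  t4 <- enumerate_topologies(4)
  expect_length(t4, 15)
  expect_length(enumerate_topologies(5), 105)
  # duplicate-free: every topology has a distinct clade set
  clade_key <- vapply(t4, function(tr) {
    parts <- ape::prop.part(tr)
    paste(sort(vapply(parts, function(p) {
      paste(sort(tr$tip.label[p]), collapse = ",")
    }, character(1))), collapse = ";")
  }, character(1))
  expect_equal(length(unique(clade_key)), 15)
  expect_true(all(vapply(t4, ape::is.binary, logical(1))))
  expect_true(all(vapply(t4, ape::is.rooted, logical(1))))
  expect_error(enumerate_topologies(9), "2..7|supported")
})

test_that("simulated datasets are reproducible and self-consistent", {
  trad <- builtin_scheme("traditional")
  cfg <- sim_config(77, 30, trad, rates = rep(1, 7), root_state = "Sol",
                    sample_size = 10, jitter = 0.1, polymorphism_prob = 0.2)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$history$events, d2$history$events)
  expect_identical(d1$scheme$tips, d2$scheme$tips)
  expect_identical(vapply(d1$trees$trees, function(x) sum(x$edge.length), 1),
                   vapply(d2$trees$trees, function(x) sum(x$edge.length), 1))
  # tip states consistent with the recorded history
  expect_true(all(vapply(names(d1$history$tip_states), function(tx) {
    d1$history$tip_states[[tx]] %in% d1$scheme$tips[[tx]]
  }, logical(1))))
  # ground-truth sidecar round-trips the true rates
  dir <- withr::local_tempdir()
  write_dataset(d1, dir)
  truth <- yaml::read_yaml(file.path(dir, "ground_truth.yml"))
  expect_equal(unname(unlist(truth$rates)), rep(1, 7))
  expect_equal(truth$root_state, "Sol")
  expect_length(read_trees(file.path(dir, "trees.nwk")), 10)
})

test_that("the apid fixture exhibits every coding feature and dates correctly", {
  fx <- make_apid_fixture(sample_size = 30, jitter = 0)
  expect_equal(ape::Ntip(fx$tree), 25)
  expect_true(ape::is.ultrametric(fx$tree, tol = 1e-8))
  # honey bee is advanced eusocial under the traditional coding
  expect_equal(unname(tip_partial(fx$traditional, "Apis_mellifera")),
               c(0, 0, 1, 0))
  # Ceratina carries three states under the complex coding
  expect_equal(sum(tip_partial(fx$complex, "Ceratina_calcarata")), 3)
  expect_equal(names(which(tip_partial(fx$complex, "Ceratina_calcarata") > 0)),
               c("Sol", "Soc", "Prim"))
  # trait files round-trip unchanged
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_traits(fx$complex, tf)
  back <- set_tips(builtin_scheme("complex"), read_traits(tf))
  expect_equal(back$tips, fx$complex$tips)
  # seven key nodes resolve on every tree; fixture ages match the design
  ages <- clade_age_report(fx$trees, fx$queries)
  expect_equal(nrow(ages), 7)
  corb <- ages[ages$clade == "corbiculates", ]
  expect_equal(corb$mean_age, 87)
  expect_equal(fx$true_ages$age[fx$true_ages$clade == "corbiculates"], 87)
})
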