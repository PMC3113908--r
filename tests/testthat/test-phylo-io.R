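test_that("tree reading, validation and round-trips preserve structure", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,(C:1,D:1):1);", path)
  ts <- read_trees(path)
  expect_s3_class(ts, "tree_sample")
  expect_length(ts, 1)
  expect_setequal(ts$trees[[1]]$tip.label, c("A", "B", "C", "D"))
  root_children <- ts$trees[[1]]$edge[ts$trees[[1]]$edge[, 1] == 5, 2]
  expect_length(root_children, 2)

  # 100 identical newick lines -> sample of 100 with uniform weights
  writeLines(rep("((A:1,B:1):1,(C:1,D:1):1);", 100), path)
  ts100 <- read_trees(path)
  expect_length(ts100, 100)
  expect_equal(ts100$weights, rep(0.01, 100))

  # round-trip: random branch lengths survive write/read to 10 sig digits
  set.seed(7)
  trees <- lapply(1:5, function(i) {
    tr <- ape::rtree(8)
    tr$edge.length <- runif(nrow(tr$edge), 0.001, 5)
    tr
  })
  ts <- tree_sample(trees)
  out <- withr::local_tempfile(fileext = ".nwk")
  write_trees(ts, out)
  back <- read_trees(out)
  for (i in 1:5) {
    expect_equal(back$trees[[i]]$tip.label, ts$trees[[i]]$tip.label)
    expect_equal(back$trees[[i]]$edge, ts$trees[[i]]$edge)
    expect_equal(back$trees[[i]]$edge.length, ts$trees[[i]]$edge.length,
                 tolerance = 1e-10)
  }
  # NEXUS round-trip applies the translate table
  nex <- withr::local_tempfile(fileext = ".nex")
  write_trees(ts, nex, format = "nexus")
  backnex <- read_trees(nex)
  expect_setequal(backnex$trees[[1]]$tip.label, ts$trees[[1]]$tip.label)
  expect_length(backnex, 5)
})

test_that("malformed and inconsistent tree inputs are rejected", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,(C:1;", path)
  expect_error(read_trees(path), "parse")
  writeLines(c("((A:1,B:1):1,C:1);", "((A:1,X:1):1,C:1);"), path)
  expect_error(read_trees(path), "different tip set")
  writeLines("((A:1,A:1):1,C:1);", path)
  expect_error(read_trees(path), "duplicate")
  tr <- ape::rtree(4)
  tr$edge.length[1] <- -0.1
  expect_error(tree_sample(tr), "negative")
})

test_that("mrca resolves queries, including enlargement to the realized clade", {
  tr <- balanced4()
  ab <- mrca_node(tr, c("A", "B"))
  expect_equal(sort(clade_tips(tr, ab)), c("A", "B"))
  expect_equal(mrca_node(tr, c("A", "C")), 5L) # root: only common ancestor
  expect_equal(mrca_node(tr, tr$tip.label), 5L)
  # idempotent under enlargement to the realized clade
  tr2 <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  nd <- mrca_node(tr2, c("A", "C"))
  expect_equal(mrca_node(tr2, clade_tips(tr2, nd)), nd)
  expect_error(mrca_node(tr, c("A", "Z")), "not in tree")
})

test_that("node ages respect the ultrametricity tolerance contract", {
  tr <- ape::read.tree(text = "((A:5,B:5):5,(C:5,D:5):5);")
  expect_equal(node_age(tr, 5), 10)
  expect_equal(node_age(tr, mrca_node(tr, c("A", "B"))), 5)
  expect_equal(node_age(tr, 1), 0) # tips have age 0
  # within-tolerance wobble accepted
  tol <- 1e-6 * 10
  tr2 <- tr
  tr2$edge.length[tr2$edge[, 2] == 1] <- 5 + tol / 2
  expect_equal(node_age(tr2, 5), 10, tolerance = 1e-6)
  # beyond tolerance: error names the worst tip pair
  tr3 <- tr
  tr3$edge.length[tr3$edge[, 2] == 1] <- 6
  expect_error(node_age(tr3, 5), "A.*differ|differ.*A")
})

test_that("hpd_interval returns the left-most shortest covering window", {
  expect_equal(hpd_interval(rep(5, 30), 0.95), c(lower = 5, upper = 5))
  # sorted grid 1..100: all width-94 windows tie; left-most wins
  expect_equal(hpd_interval(1:100, 0.95), c(lower = 1, upper = 95))
  # large normal sample: endpoints near the +/-1.96 quantiles
  set.seed(11)
  x <- rnorm(1e5)
  h <- hpd_interval(x, 0.95)
  expect_lt(abs(h[["lower"]] + 1.96), 0.05)
  expect_lt(abs(h[["upper"]] - 1.96), 0.05)
  # containment + minimality over the sorted sample
  set.seed(12)
  y <- rexp(500)
  h <- hpd_interval(y, 0.9)
  expect_gte(mean(y >= h[1] & y <= h[2]), 0.9)
  ys <- sort(y)
  m <- ceiling(0.9 * 500)
  widths <- ys[m:500] - ys[1:(500 - m + 1)]
  expect_equal(h[["upper"]] - h[["lower"]], min(widths))
  expect_error(hpd_interval(1:10, 0.95), "at least 20")
  expect_error(hpd_interval(1:100, 1.2), "mass")
})

test_that("clade_age_report summarizes MRCA ages over a chronogram sample", {
  tr <- ape::read.tree(text = "((A:5,B:5):5,(C:5,D:5):5);")
  rep1 <- clade_age_report(tr, list(ab = c("A", "B")))
  expect_equal(rep1$mean_age, 5)
  expect_equal(rep1$hpd_low, 5)
  expect_equal(rep1$hpd_high, 5)

  # 1000 chronograms with the queried MRCA age fixed at 87
  make_chrono <- function(age_ab, depth = 120) {
    txt <- sprintf("((A:%.12g,B:%.12g):%.12g,C:%.12g);",
                   age_ab, age_ab, depth - age_ab, depth)
    ape::read.tree(text = txt)
  }
  const <- tree_sample(replicate(1000, make_chrono(87), simplify = FALSE))
  repc <- clade_age_report(const, list(ab = c("A", "B")))
  expect_equal(repc$mean_age, 87)
  expect_equal(c(repc$hpd_low, repc$hpd_high), c(87, 87))

  # ages uniform(78, 95): HPD endpoints near the central-95% shortest window
  set.seed(13)
  ages <- runif(1000, 78, 95)
  unif <- tree_sample(lapply(ages, make_chrono))
  repu <- clade_age_report(unif, list(ab = c("A", "B")))
  expect_equal(repu$mean_age, mean(ages))
  expect_lt(abs(repu$hpd_low - 78.4), 0.5)
  expect_lt(abs(repu$hpd_high - 94.6), 0.5)

  # errors carry the tree index
  bad <- unif
  bad$trees[[3]]$edge.length[1] <- 50
  expect_error(clade_age_report(bad, list(ab = c("A", "B"))), "tree 3")
})
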