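# Shared generators for randomized oracle sweeps.

# cache of enumerated topologies per tip count (enumeration is deterministic)
topo_cache <- new.env(parent = emptyenv())
cached_topologies <- function(n) {
  key <- as.character(n)
  if (is.null(topo_cache[[key]])) topo_cache[[key]] <- enumerate_topologies(n)
  topo_cache[[key]]
}

# random constrained-Mk instance: topology <= 7 tips, k in 2..5, random mask
# (possibly with an absorbing last state), random polymorphic tips, random
# fossilization of one internal node
random_instance <- function(seed) {
  set.seed(seed)
  n <- sample(3:7, 1)
  k <- sample(2:5, 1)
  states <- LETTERS[seq_len(k)]
  tree <- cached_topologies(n)[[sample(cached_topologies(n) |> length(), 1)]]
  tree$edge.length <- runif(nrow(tree$edge), 0.05, 2)
  forbidden <- character()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j && runif(1) < 0.25) {
      forbidden <- c(forbidden, paste0(states[i], "->", states[j]))
    }
  }
  if (runif(1) < 0.3) { # absorbing terminal state, like advanced eusociality
    forbidden <- c(forbidden, paste0(states[k], "->", states[-k]))
  }
  scheme <- coding_scheme(states, forbidden = unique(forbidden))
  tips <- lapply(tree$tip.label, function(tx) {
    sub <- states[runif(k) < 0.4]
    if (length(sub) == 0) sub <- sample(states, 1)
    sub
  })
  scheme <- set_tips(scheme, stats::setNames(tips, tree$tip.label))
  Q <- rate_matrix(scheme, runif(nrow(allowed_cells(scheme)), 0.05, 3))
  constraints <- NULL
  if (runif(1) < 0.5) {
    taxa <- sample(tree$tip.label, sample(2:n, 1))
    sub <- states[runif(k) < 0.5]
    if (length(sub) == 0) sub <- sample(states, 1)
    constraints <- node_constraint(taxa, sub)
  }
  list(tree = tree, scheme = scheme, Q = Q, constraints = constraints)
}

# deterministic 4-tip tree used across files
balanced4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# binary scheme with informative tips on the 4-tip tree
binary_scheme4 <- function(rj = FALSE) {
  sch <- coding_scheme(c("A", "B"), rj = rj, name = "binary")
  set_tips(sch, list(A = "A", B = "B", C = "A", D = "B"))
}
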