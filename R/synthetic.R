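#' Simulate a birth-death tree conditioned on the number of tips
#'
#' Complete (extinct lineages pruned) ultrametric birth-death tree with
#' exactly `n_tips` extant tips, via `ape::rphylo`.
#'
#' @param n_tips number of surviving tips (>= 2).
#' @param birth,death per-lineage rates (per My); `birth > death >= 0`.
#' @return an ultrametric `phylo`.
#' @export
simulate_tree <- function(n_tips, birth = 1, death = 0) {
  assert_that(n_tips >= 2, "need at least 2 tips")
  assert_that(birth > death && death >= 0, "need birth > death >= 0")
  tree <- ape::rphylo(n_tips, birth = birth, death = death, fossils = FALSE)
  tree$tip.label <- sprintf("t%03d", seq_len(n_tips))
  tree
}

#' Rescale a tree to a given depth
#'
#' @param tree a `phylo`.
#' @param depth target root-to-tip depth (default 1).
#' @return rescaled tree.
#' @export
rescale_tree_depth <- function(tree, depth = 1) {
  d <- max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
  tree$edge.length <- tree$edge.length * depth / d
  tree
}

#' Simulate a character history under a constrained rate matrix
#'
#' Gillespie simulation along each branch: from state s, waiting times are
#' exponential with rate `-Q[s, s]`, and jumps go to j with probability
#' `Q[s, j] / -Q[s, s]`. Forbidden transitions (structural zeros) can never
#' occur.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param Q rate matrix from [rate_matrix()].
#' @param root_state state name at the root.
#' @param scheme coding scheme (defaults to the one stored in `Q`).
#' @return list with `tip_states` (named character), `node_states` (named by
#'   node number, internal nodes), `events` (tibble: edge, parent, child,
#'   time, from, to), and `tree`.
#' @export
simulate_history <- function(tree, Q, root_state, scheme = attr(Q, "scheme")) {
  states <- scheme$states
  assert_that(root_state %in% states, "unknown root state")
  tree <- validate_phylo(tree)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  # preorder: parents before children
  pre <- ape::reorder.phylo(tree, "cladewise")
  state_at <- integer(nnode)
  state_at[ntip + 1] <- match(root_state, states)
  ev <- list()
  for (e in seq_len(nrow(pre$edge))) {
    p <- pre$edge[e, 1]
    ch <- pre$edge[e, 2]
    len <- pre$edge.length[e]
    s <- state_at[p]
    t <- 0
    repeat {
      out_rate <- -Q[s, s]
      if (out_rate <= 0) break
      t <- t + rexp(1, out_rate)
      if (t >= len) break
      j <- sample.int(length(states), 1, prob = pmax(Q[s, ], 0))
      ev[[length(ev) + 1]] <- tibble(edge = e, parent = p, child = ch,
                                     time = t, from = states[s], to = states[j])
      s <- j
    }
    state_at[ch] <- s
  }
  events <- if (length(ev) > 0) dplyr::bind_rows(ev) else
    tibble(edge = integer(), parent = integer(), child = integer(),
           time = numeric(), from = character(), to = character())
  tips <- setNames(states[state_at[seq_len(ntip)]], tree$tip.label)
  nodes <- setNames(states[state_at[(ntip + 1):nnode]], (ntip + 1):nnode)
  list(tip_states = tips, node_states = nodes, events = events, tree = tree)
}

#' Pseudo-posterior tree sample by branch-length jitter
#'
#' `size` copies of the tree with each branch length multiplied by an
#' independent log-normal(0, jitter) factor (mean factor `exp(jitter^2/2)`),
#' emulating posterior branch-length spread while preserving positivity.
#' Optional local rearrangement of topologies is available behind
#' `rearrange_prob` (off by default so MRCA queries stay well-defined in
#' every tree).
#'
#' @param tree a `phylo`.
#' @param size number of trees.
#' @param jitter log-normal sd of the branch-length factors (>= 0).
#' @param rearrange_prob probability that a tree is perturbed by one random
#'   NNI move (requires phangorn).
#' @return a [tree_sample].
#' @export
make_tree_sample <- function(tree, size, jitter = 0.1, rearrange_prob = 0) {
  assert_that(jitter >= 0, "jitter must be >= 0")
  trees <- lapply(seq_len(size), function(i) {
    tr <- tree
    if (rearrange_prob > 0 && runif(1) < rearrange_prob) {
      if (!requireNamespace("phangorn", quietly = TRUE)) {
        abort("topology rearrangement requires the phangorn package")
      }
      tr <- phangorn::rNNI(tr, 1)
    }
    if (jitter > 0) {
      tr$edge.length <- tr$edge.length *
        rlnorm(length(tr$edge.length), 0, jitter)
    }
    tr
  })
  tree_sample(trees)
}

#' Pseudo-posterior chronogram sample by node-age jitter
#'
#' Branch-wise jitter (as in [make_tree_sample()]) breaks ultrametricity, so
#' chronogram samples are generated differently: each internal node age is
#' multiplied by an independent log-normal(0, jitter) factor and parent ages
#' are then raised to stay above their children, preserving an ultrametric,
#' positively-branched tree while spreading clade ages as a dating posterior
#' would.
#'
#' @param tree an ultrametric `phylo` (ages in My).
#' @param size number of chronograms.
#' @param jitter log-normal sd of the per-node age factors (>= 0).
#' @return a [tree_sample] of ultrametric trees.
#' @export
make_chronogram_sample <- function(tree, size, jitter = 0.05) {
  assert_that(jitter >= 0, "jitter must be >= 0")
  chk <- ultrametric_check(tree, 1e-6)
  assert_that(chk$ok, "chronogram jitter requires an ultrametric input tree")
  ntip <- ape::Ntip(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  age <- chk$depth - ape::node.depth.edgelength(po)
  age[seq_len(ntip)] <- 0
  trees <- lapply(seq_len(size), function(i) {
    a <- age
    nn <- (ntip + 1):(ntip + po$Nnode)
    a[nn] <- a[nn] * rlnorm(length(nn), 0, jitter)
    # postorder edges visit children before parents: lift parents as needed
    for (e in seq_len(nrow(po$edge))) {
      p <- po$edge[e, 1]
      ch <- po$edge[e, 2]
      if (a[p] < a[ch]) a[p] <- a[ch]
    }
    out <- po
    out$edge.length <- a[po$edge[, 1]] - a[po$edge[, 2]]
    out
  })
  tree_sample(trees)
}

#' Add polymorphic codings to a scheme's tips
#'
#' Each tip independently, with probability `prob`, gains one state adjacent
#' to its coded state in the constraint mask's transition graph (so synthetic
#' polymorphism stays coherent with the model). Enlarging a tip's state set
#' never decreases the likelihood.
#'
#' @param scheme a `coding_scheme` with (typically single-state) tips.
#' @param prob per-tip probability of adding a state.
#' @return the scheme with updated tips.
#' @export
add_polymorphism <- function(scheme, prob) {
  assert_that(prob >= 0 && prob <= 1, "prob must be in [0, 1]")
  states <- scheme$states
  scheme$tips <- lapply(scheme$tips, function(st) {
    if (runif(1) >= prob) return(st)
    s <- st[sample.int(length(st), 1)]
    adj <- states[(scheme$mask[s, ] | scheme$mask[, s]) & !(states %in% st)]
    if (length(adj) == 0) return(st)
    add <- adj[sample.int(length(adj), 1)]
    states[states %in% c(st, add)]
  })
  scheme
}

#' All rooted binary labeled topologies on n tips
#'
#' Exhaustive, duplicate-free enumeration by stepwise tip insertion into
#' every edge (plus the new-root position); there are `(2n-3)!!` such
#' topologies (15 for n = 4). Used for exhaustive small-tree test sweeps.
#'
#' @param n_tips 2..7.
#' @param labels tip labels (default `t1..tn`).
#' @param branch_length branch length assigned to every edge.
#' @return list of `phylo` objects.
#' @export
enumerate_topologies <- function(n_tips, labels = paste0("t", seq_len(n_tips)),
                                 branch_length = 1) {
  assert_that(n_tips >= 2 && n_tips <= 7,
              "enumeration supported for 2..7 tips only")
  # nested-list representation: a tree is a tip index or list(left, right)
  grow <- function(tree, tip) {
    out <- list(list(tree, tip)) # new root above the old one
    if (is.list(tree)) {
      for (side in 1:2) {
        for (sub in grow(tree[[side]], tip)) {
          t2 <- tree
          t2[[side]] <- sub
          out <- c(out, list(t2))
        }
      }
    }
    out
  }
  trees <- list(list(1L, 2L))
  for (tip in seq_len(n_tips)[-(1:2)]) {
    trees <- unlist(lapply(trees, grow, tip = tip), recursive = FALSE)
  }
  to_newick <- function(tr) {
    if (!is.list(tr)) return(paste0(labels[tr], ":", branch_length))
    paste0("(", to_newick(tr[[1]]), ",", to_newick(tr[[2]]), "):", branch_length)
  }
  lapply(trees, function(tr) {
    ape::read.tree(text = paste0("(", to_newick(tr[[1]]), ",",
                                 to_newick(tr[[2]]), ");"))
  })
}

#' Simulation configuration and full synthetic dataset
#'
#' Bundles every knob of the generator; [simulate_dataset()] turns it into a
#' dataset with known ground truth (true tree, jittered pseudo-posterior tree
#' sample, tip codings with optional polymorphism, the full event history and
#' true node states).
#'
#' @param master_seed integer seed; the dataset is a deterministic function
#'   of the config.
#' @param n_tips tips of the true tree.
#' @param birth,death birth-death rates for the true tree.
#' @param depth rescale the true tree to this depth (NULL keeps raw depth).
#' @param sample_size trees in the pseudo-posterior sample.
#' @param jitter branch-length jitter (log-normal sd).
#' @param scheme `coding_scheme` supplying states and mask.
#' @param rates true rates (vector in [allowed_cells()] order or named).
#' @param root_state true root state.
#' @param polymorphism_prob per-tip probability of a polymorphic coding.
#' @return `sim_config`: a classed list echoing the arguments.
#' @export
sim_config <- function(master_seed, n_tips, scheme, rates, root_state,
                       birth = 1, death = 0, depth = 1, sample_size = 50,
                       jitter = 0.1, polymorphism_prob = 0.05) {
  structure(list(master_seed = as.integer(master_seed), n_tips = n_tips,
                 scheme = scheme, rates = rates, root_state = root_state,
                 birth = birth, death = death, depth = depth,
                 sample_size = sample_size, jitter = jitter,
                 polymorphism_prob = polymorphism_prob),
            class = "sim_config")
}

#' @rdname sim_config
#' @param config a `sim_config`.
#' @return `simulate_dataset`: a `sim_dataset` list with `tree`, `trees`
#'   ([tree_sample]), `scheme` (tips attached), `Q` (true rate matrix),
#'   `history`, `config`.
#' @export
simulate_dataset <- function(config) {
  set.seed(config$master_seed)
  Q <- rate_matrix(config$scheme, config$rates)
  tree <- simulate_tree(config$n_tips, config$birth, config$death)
  if (!is.null(config$depth)) tree <- rescale_tree_depth(tree, config$depth)
  hist <- simulate_history(tree, Q, config$root_state, config$scheme)
  scheme <- set_tips(config$scheme,
                     as.list(setNames(hist$tip_states, names(hist$tip_states))))
  if (config$polymorphism_prob > 0) {
    scheme <- add_polymorphism(scheme, config$polymorphism_prob)
  }
  trees <- make_tree_sample(tree, config$sample_size, config$jitter)
  structure(list(tree = tree, trees = trees, scheme = scheme, Q = Q,
                 history = hist, config = config),
            class = "sim_dataset")
}

#' Write a simulated dataset's files and ground-truth sidecar
#'
#' Emits the same formats the pipeline reads: Newick tree sample, trait TSV,
#' scheme YAML, plus a YAML sidecar with the true rates, root state and
#' per-node true states for recovery scoring.
#'
#' @param dataset a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trees(dataset$trees, file.path(dir, "trees.nwk"))
  write_trees(dataset$tree, file.path(dir, "true_tree.nwk"))
  write_traits(dataset$scheme, file.path(dir, "traits.tsv"))
  write_scheme(dataset$scheme, file.path(dir, "scheme.yml"))
  cells <- allowed_cells(dataset$scheme)
  truth <- list(
    root_state = dataset$config$root_state,
    rates = setNames(as.list(dataset$Q[as.matrix(cells_index(cells, dataset$scheme))]),
                     cells$cell),
    node_states = as.list(dataset$history$node_states),
    n_events = nrow(dataset$history$events))
  yaml::write_yaml(truth, file.path(dir, "ground_truth.yml"))
  invisible(dir)
}
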