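#' Bundle trees into a tree sample
#'
#' A tree sample is an ordered collection of rooted phylogenies sharing one
#' tip set, typically a posterior sample of trees (topology and branch-length
#' variation) over which downstream MCMC integrates by uniform resampling.
#'
#' @param trees a single `phylo` object, a `multiPhylo`, or a list of `phylo`.
#' @param weights optional numeric resampling weights, one per tree
#'   (default uniform).
#' @return an object of class `tree_sample`: a list with elements `trees`
#'   (list of `phylo`) and `weights` (normalized numeric).
#' @export
tree_sample <- function(trees, weights = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  assert_that(length(trees) >= 1, "tree sample must contain at least one tree")
  trees <- lapply(trees, validate_phylo)
  tips1 <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), tips1)) {
      abort(sprintf("tree %d has a different tip set from tree 1", i))
    }
  }
  if (is.null(weights)) {
    weights <- rep(1 / length(trees), length(trees))
  } else {
    assert_that(length(weights) == length(trees) && all(weights > 0),
                "weights must be positive, one per tree")
    weights <- weights / sum(weights)
  }
  structure(list(trees = trees, weights = weights), class = "tree_sample")
}

#' @export
print.tree_sample <- function(x, ...) {
  cat(sprintf("<tree_sample> %d tree(s), %d tips\n",
              length(x$trees), length(x$trees[[1]]$tip.label)))
  invisible(x)
}

#' @export
length.tree_sample <- function(x) length(x$trees)

validate_phylo <- function(tree) {
  assert_that(inherits(tree, "phylo"), "trees must be `phylo` objects")
  assert_that(ape::is.rooted(tree), "tree must be rooted")
  if (anyDuplicated(tree$tip.label) > 0) {
    abort(sprintf("duplicate tip labels: %s",
                  paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                        collapse = ", ")))
  }
  if (is.null(tree$edge.length)) {
    abort("tree has no branch lengths")
  }
  if (any(tree$edge.length < 0)) {
    abort("negative branch lengths are not allowed")
  }
  tree
}

#' Read a sample of phylogenies from Newick or NEXUS
#'
#' NEXUS translate tables are applied; tree order in the file is preserved.
#' Underscores in labels are kept literal (BayesTraits-style inputs), unless
#' `underscores_to_spaces = TRUE`.
#'
#' @param path file containing one or more trees.
#' @param format `"auto"` (sniff `#NEXUS` header), `"newick"`, or `"nexus"`.
#' @param weights optional per-tree resampling weights.
#' @param underscores_to_spaces convert `_` to spaces in tip labels.
#' @return a [tree_sample].
#' @export
read_trees <- function(path, format = c("auto", "newick", "nexus"),
                       weights = NULL, underscores_to_spaces = FALSE) {
  format <- match.arg(format)
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^\\s*#NEXUS", first, ignore.case = TRUE)) "nexus" else "newick"
  }
  trees <- tryCatch(
    if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path),
    error = function(e) {
      abort(sprintf("failed to parse %s tree file '%s': %s",
                    format, path, conditionMessage(e)))
    }
  )
  if (is.null(trees)) abort(sprintf("no trees could be parsed from '%s'", path))
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!is.null(attr(trees, "TipLabel"))) {
    trees <- ape::.uncompressTipLabel(trees)
  }
  if (underscores_to_spaces) {
    trees <- lapply(trees, function(tr) {
      tr$tip.label <- gsub("_", " ", tr$tip.label)
      tr
    })
  }
  tree_sample(trees, weights = weights)
}

#' Write a tree sample to Newick or NEXUS
#'
#' @param sample a [tree_sample] or `phylo`.
#' @param path output file.
#' @param format `"newick"` or `"nexus"` (NEXUS includes a translate table).
#' @return `path`, invisibly.
#' @export
write_trees <- function(sample, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (inherits(sample, "phylo")) sample <- tree_sample(sample)
  trees <- sample$trees
  class(trees) <- "multiPhylo"
  if (format == "newick") {
    ape::write.tree(trees, file = path)
  } else {
    ape::write.nexus(trees, file = path, translate = TRUE)
  }
  invisible(path)
}

#' Construct a clade query
#'
#' A clade query addresses the most recent common ancestor (MRCA) of a set of
#' tips, resolvable on any tree of a sample.
#'
#' @param taxa character vector of at least two tip labels.
#' @param label short name for the node.
#' @return a one-row tibble with columns `label` and `taxa` (list column).
#' @export
clade_query <- function(taxa, label = paste(taxa, collapse = "+")) {
  assert_that(is.character(taxa) && length(taxa) >= 2,
              "a clade query needs at least two tip labels")
  tibble(label = label, taxa = list(unique(taxa)))
}

as_clade_queries <- function(queries) {
  if (is.data.frame(queries)) {
    assert_that(all(c("label", "taxa") %in% names(queries)),
                "query table needs columns `label` and `taxa`")
    return(as_tibble(queries))
  }
  if (is.character(queries)) queries <- list(query = queries)
  assert_that(is.list(queries), "queries must be a tibble or named list of tip sets")
  if (is.null(names(queries)) || any(names(queries) == "")) {
    names(queries) <- paste0("node", seq_along(queries))
  }
  tibble(label = names(queries), taxa = unname(queries))
}

#' Most recent common ancestor of a set of tips
#'
#' @param tree a `phylo`.
#' @param taxa character vector of tip labels (length >= 2).
#' @return the internal node number of the MRCA. The realized clade may be
#'   larger than the query set; see [clade_tips()].
#' @export
mrca_node <- function(tree, taxa) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing) > 0) {
    abort(sprintf("taxa not in tree: %s", paste(missing, collapse = ", ")))
  }
  if (length(unique(taxa)) == length(tree$tip.label)) {
    return(ape::Ntip(tree) + 1L)
  }
  node <- ape::getMRCA(tree, unique(taxa))
  as.integer(node)
}

#' Tips descending from a node
#'
#' @param tree a `phylo`.
#' @param node node number.
#' @return character vector of tip labels in the clade (the realized clade).
#' @export
clade_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- node
  edge <- tree$edge
  tips <- integer(0)
  while (length(kids) > 0) {
    ch <- edge[edge[, 1] %in% kids, 2]
    tips <- c(tips, ch[ch <= ntip])
    kids <- ch[ch > ntip]
  }
  tree$tip.label[tips]
}

# Relative ultrametricity tolerance: chronogram files carry rounded branch
# lengths, so exact tip-depth equality cannot be required.
ultrametric_check <- function(tree, tol_rel = 1e-6) {
  nd <- ape::node.depth.edgelength(tree)
  ntip <- ape::Ntip(tree)
  depths <- nd[seq_len(ntip)]
  depth <- max(depths)
  spread <- depth - min(depths)
  ok <- spread <= tol_rel * depth
  list(ok = ok, depth = depth, node_depth = nd,
       worst = tree$tip.label[c(which.max(depths), which.min(depths))],
       spread = spread)
}

#' Age of a node on an ultrametric tree
#'
#' @param tree an ultrametric `phylo` (chronogram; branch lengths in My).
#' @param node node number (from [mrca_node()]).
#' @param tol_rel relative ultrametricity tolerance (fraction of tree depth).
#' @return the node's age: its distance to any descendant tip.
#' @export
node_age <- function(tree, node, tol_rel = 1e-6) {
  chk <- ultrametric_check(tree, tol_rel)
  if (!chk$ok) {
    abort(sprintf(
      "tree is not ultrametric within tolerance: tips '%s' and '%s' differ in root-to-tip distance by %g",
      chk$worst[1], chk$worst[2], chk$spread))
  }
  max(chk$node_depth[seq_len(ape::Ntip(tree))]) - chk$node_depth[node]
}

#' Highest posterior density interval of a sample
#'
#' The shortest contiguous window of the sorted sample containing at least
#' `ceiling(mass * n)` points; among equal-width windows the left-most is
#' returned (deterministic tie-break).
#'
#' @param sample numeric vector, length >= 20.
#' @param mass credibility mass in (0, 1); default 0.95.
#' @return named numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(sample, mass = 0.95) {
  assert_that(is.numeric(sample) && length(sample) >= 20,
              "HPD requires a sample of at least 20 values")
  assert_that(mass > 0 && mass < 1, "mass must be in (0, 1)")
  x <- sort(sample)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  starts <- seq_len(n - m + 1)
  widths <- x[starts + m - 1] - x[starts]
  i <- which.min(widths)  # which.min takes the left-most minimum
  c(lower = x[i], upper = x[i + m - 1])
}

#' Clade ages with HPD intervals over a chronogram sample
#'
#' For each query, resolves the MRCA on every chronogram, takes its age, and
#' summarizes the age sample by its mean and highest-posterior-density
#' interval.
#'
#' @param chronograms a [tree_sample] of ultrametric trees.
#' @param queries a query tibble ([clade_query()] rows) or named list of tip
#'   label vectors.
#' @param mass HPD credibility mass (default 0.95).
#' @param tol_rel ultrametricity tolerance passed to [node_age()].
#' @return a tibble with columns `clade`, `n_trees`, `mean_age`, `hpd_low`,
#'   `hpd_high`, `mass`.
#' @export
clade_age_report <- function(chronograms, queries, mass = 0.95, tol_rel = 1e-6) {
  if (inherits(chronograms, "phylo")) chronograms <- tree_sample(chronograms)
  queries <- as_clade_queries(queries)
  purrr::pmap_dfr(queries, function(label, taxa) {
    ages <- purrr::imap_dbl(chronograms$trees, function(tr, i) {
      tryCatch(
        node_age(tr, mrca_node(tr, taxa), tol_rel = tol_rel),
        error = function(e) abort(sprintf("tree %d, query '%s': %s",
                                          i, label, conditionMessage(e)))
      )
    })
    if (length(ages) >= 20) {
      hpd <- hpd_interval(ages, mass)
    } else {
      hpd <- c(lower = min(ages), upper = max(ages))
    }
    tibble(clade = label, n_trees = length(ages), mean_age = mean(ages),
           hpd_low = unname(hpd[1]), hpd_high = unname(hpd[2]), mass = mass)
  })
}

#' Write a clade age report as TSV
#'
#' @param report output of [clade_age_report()].
#' @param path output file.
#' @export
write_age_report <- function(report, path) {
  readr::write_tsv(report, path)
  invisible(path)
}
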