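#' Node constraint (fossilization)
#'
#' Restricts an internal node (the MRCA of `taxa`) to a subset of states
#' during likelihood evaluation; a singleton subset fixes ("fossilizes") the
#' node. Used both for Bayes Factor tests and marginal node probabilities.
#'
#' @param taxa tip labels whose MRCA is constrained (a single label
#'   constrains that tip).
#' @param states character vector of allowed state names (nonempty).
#' @param label optional name.
#' @return one-row tibble with columns `label`, `taxa`, `states`.
#' @export
node_constraint <- function(taxa, states, label = paste(taxa, collapse = "+")) {
  assert_that(length(states) >= 1, "constraint needs a nonempty state set")
  tibble(label = label, taxa = list(taxa), states = list(states))
}

as_node_constraints <- function(constraints) {
  if (is.null(constraints)) {
    return(tibble(label = character(), taxa = list(), states = list()))
  }
  if (is.data.frame(constraints)) return(as_tibble(constraints))
  abort("constraints must be a tibble of node_constraint() rows (or NULL)")
}

# Encode a tree + scheme (+ constraints) for the C++ pruning core:
# postorder edge matrix, branch lengths, k x ntip tip partials and a
# k x nnode constraint mask.
encode_tree <- function(tree, scheme, constraints = NULL) {
  tree <- validate_phylo(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  k <- length(scheme$states)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  tippart <- tip_partial_matrix(scheme, po$tip.label)
  mask <- matrix(1, k, nnode)
  constraints <- as_node_constraints(constraints)
  if (nrow(constraints) > 0) {
    for (i in seq_len(nrow(constraints))) {
      taxa <- constraints$taxa[[i]]
      node <- if (length(taxa) == 1) {
        j <- match(taxa, po$tip.label)
        if (is.na(j)) abort(sprintf("constraint taxon '%s' not in tree", taxa))
        j
      } else {
        mrca_node(po, taxa)
      }
      st <- constraints$states[[i]]
      bad <- setdiff(st, scheme$states)
      if (length(bad) > 0) {
        abort(sprintf("constraint '%s' uses unknown state(s): %s",
                      constraints$label[i], paste(bad, collapse = ", ")))
      }
      mask[, node] <- mask[, node] * as.numeric(scheme$states %in% st)
      if (all(mask[, node] == 0)) {
        abort(sprintf("constraint '%s' leaves no allowed state at its node",
                      constraints$label[i]))
      }
    }
  }
  list(edge = po$edge, blen = po$edge.length, tippart = tippart, mask = mask,
       ntip = ntip, nnode = nnode, tree = po)
}

default_root_prior <- function(scheme, root_prior = NULL) {
  k <- length(scheme$states)
  if (is.null(root_prior)) {
    # uniform: the constrained model is non-reversible (absorbing states), so
    # the stationary distribution is degenerate and unusable as a default
    return(rep(1 / k, k))
  }
  if (is.character(root_prior)) {
    assert_that(all(root_prior %in% scheme$states), "unknown root state")
    return(as.numeric(scheme$states %in% root_prior) / length(root_prior))
  }
  assert_that(length(root_prior) == k && all(root_prior >= 0) &&
                abs(sum(root_prior) - 1) < 1e-8,
              "root_prior must be a probability vector over the states")
  as.numeric(root_prior)
}

#' Pruning log-likelihood of a discrete character on a tree
#'
#' Felsenstein's post-order pruning with per-node rescaling. Polymorphic tip
#' codings enter as ambiguity indicators; node constraints zero the
#' constrained node's partials outside the allowed set after its children are
#' combined. Returns `-Inf` when the likelihood is exactly 0.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param Q rate matrix from [rate_matrix()].
#' @param scheme a `coding_scheme` with tips attached (used for tip partials;
#'   defaults to the scheme stored in `Q`).
#' @param root_prior probability vector over states, a character vector of
#'   root states (uniform over them), or `NULL` for uniform over all states.
#' @param constraints tibble of [node_constraint()] rows, or `NULL`.
#' @return log-likelihood (double).
#' @export
prune_loglik <- function(tree, Q, scheme = attr(Q, "scheme"),
                         root_prior = NULL, constraints = NULL) {
  td <- encode_tree(tree, scheme, constraints)
  pi <- default_root_prior(scheme, root_prior)
  cpp_prune_loglik(td$edge, td$blen, td$tippart, td$mask,
                   unclass_matrix(Q), pi)
}

#' Brute-force likelihood by enumeration of internal-state assignments
#'
#' Independent oracle for [prune_loglik()]: sums, over every joint assignment
#' of states to internal nodes, the root prior times the product of branch
#' transition probabilities (tips summed over their allowed states), with
#' constraint-inconsistent assignments excluded. Transition probabilities
#' come from `Matrix::expm`, a code path disjoint from the pruning core.
#'
#' @inheritParams prune_loglik
#' @param max_internal refuse trees with more internal nodes than this
#'   (the sum has k^internal terms).
#' @return log-likelihood (double).
#' @export
enumeration_loglik <- function(tree, Q, scheme = attr(Q, "scheme"),
                               root_prior = NULL, constraints = NULL,
                               max_internal = 12) {
  td <- encode_tree(tree, scheme, constraints)
  k <- length(scheme$states)
  ntip <- td$ntip
  ni <- td$nnode - ntip
  assert_that(ni <= max_internal,
              sprintf("too many internal nodes for enumeration (%d > %d)",
                      ni, max_internal))
  pi <- default_root_prior(scheme, root_prior)
  Qm <- unclass_matrix(Q)

  Ps <- lapply(seq_along(td$blen), function(e) {
    as.matrix(Matrix::expm(Qm * td$blen[e]))
  })
  nassign <- k^ni
  # assignment matrix: one column per internal node (node ntip+i), values 1..k
  assign_idx <- function(col) ((seq_len(nassign) - 1) %/% k^(col - 1)) %% k + 1
  A <- vapply(seq_len(ni), assign_idx, numeric(nassign))
  A <- matrix(A, nrow = nassign)

  w <- pi[A[, 1]] # root is node ntip+1 -> first internal column
  for (n in seq_len(ni)) {
    w <- w * td$mask[cbind(A[, n], n + ntip)]
  }
  for (e in seq_along(td$blen)) {
    p <- td$edge[e, 1] - ntip
    ch <- td$edge[e, 2]
    sp <- A[, p]
    if (ch <= ntip) {
      v <- Ps[[e]] %*% (td$tippart[, ch] * td$mask[, ch])
      w <- w * v[sp]
    } else {
      w <- w * Ps[[e]][cbind(sp, A[, ch - ntip])]
    }
  }
  L <- sum(w)
  if (L <= 0) -Inf else log(L)
}

#' Marginal posterior state probabilities at a queried node
#'
#' Component s is the likelihood with the node fossilized to s, normalized
#' over states. States unreachable at the node get probability 0.
#'
#' @inheritParams prune_loglik
#' @param taxa tip labels whose MRCA is queried.
#' @return named probability vector over the scheme's states.
#' @export
marginal_node_probs <- function(tree, Q, taxa, scheme = attr(Q, "scheme"),
                                root_prior = NULL, constraints = NULL) {
  base <- as_node_constraints(constraints)
  lls <- vapply(scheme$states, function(s) {
    cons <- dplyr::bind_rows(base, node_constraint(taxa, s, label = "query"))
    tryCatch(prune_loglik(tree, Q, scheme, root_prior, cons),
             error = function(e) {
               # fossilizing outside an existing constraint set: probability 0
               if (grepl("no allowed state", conditionMessage(e))) -Inf
               else stop(e)
             })
  }, numeric(1))
  if (all(!is.finite(lls))) {
    abort("likelihood is zero for every state at the queried node: data and model are inconsistent")
  }
  p <- exp(lls - logsumexp(lls))
  setNames(p, scheme$states)
}

#' Marginal state probabilities at every node in one pass
#'
#' Down-up (inside-outside) algorithm; equivalent to fossilizing each node to
#' each state in turn but linear in tree size. Columns are nodes in the
#' tree's node numbering (tips first), rows states.
#'
#' @inheritParams prune_loglik
#' @return k x nnode matrix with attribute `loglik`.
#' @export
node_marginals_all <- function(tree, Q, scheme = attr(Q, "scheme"),
                               root_prior = NULL, constraints = NULL) {
  td <- encode_tree(tree, scheme, constraints)
  pi <- default_root_prior(scheme, root_prior)
  marg <- cpp_node_marginals(td$edge, td$blen, td$tippart, td$mask,
                             unclass_matrix(Q), pi)
  rownames(marg) <- scheme$states
  marg
}
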