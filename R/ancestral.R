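#' Marginal ancestral state probabilities at internal nodes
#'
#' For every internal node, computes the marginal posterior distribution
#' over geographic regions given all tip data under the fitted equal-rates
#' Mk model. The computation combines the downward conditional likelihoods
#' from the pruning pass with a preorder "rest-of-tree" pass (the partial
#' likelihood of everything outside the node's subtree), which is
#' equivalent to re-rooting the tree at each node; because the ER model is
#' time-reversible with a uniform stationary distribution, branch
#' directions need no flux correction.
#'
#' @param fit An `mk_fit` from [fit_mk()].
#' @return An object of class `ancestral_states`: a matrix of probabilities
#'   (internal nodes in `ape` numbering as rows, states as columns; each
#'   row sums to 1), carrying the tree and fit as attributes.
#' @examples
#' tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' fit <- fit_mk(tree, c(A = "Africa", B = "Africa", C = "Asia", D = "Asia"))
#' marginal_ancestral_states(fit)
#' @export
marginal_ancestral_states <- function(fit) {
  stopifnot(inherits(fit, "mk_fit"))
  tree <- fit$tree
  cd <- list(states = fit$states,
             assignment = fit$assignment,
             tip_state = match(fit$assignment, fit$states))
  k <- fit$k
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  down <- pruning_pass(tree, cd, fit$q, fit$root_prior)

  # preorder rest-of-tree pass; each node's vector normalized to sum 1,
  # constants cancel in the per-node marginal
  G <- matrix(NA_real_, ntip + nnode, k)
  root <- ntip + 1L
  G[root, ] <- fit$root_prior
  tr <- ape::reorder.phylo(tree, "postorder")
  edges <- tr$edge[rev(seq_len(nrow(tr$edge))), , drop = FALSE]  # preorder
  elen <- tr$edge.length[rev(seq_len(nrow(tr$edge)))]
  # per-parent: contributions of each child, to divide out for siblings
  child_msg <- matrix(NA_real_, ntip + nnode, k)  # message child -> parent
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  for (ei in seq_len(nrow(edges))) {
    parent <- edges[ei, 1]
    child <- edges[ei, 2]
    P <- er_pmatrix(fit$q, elen[ei], k)
    # siblings' messages times parent's rest-of-tree vector
    sib_edges <- setdiff(tree$edge[kids[[as.character(parent)]], 2], child)
    h <- G[parent, ]
    for (s in sib_edges) {
      Ps <- er_pmatrix(fit$q, tree$edge.length[tree$edge[, 2] == s], k)
      h <- h * as.vector(Ps %*% down$L[s, ])
      if (max(h) > 0) h <- h / max(h)
    }
    g <- as.vector(t(P) %*% h)  # ER is symmetric; t() kept for clarity
    tot <- sum(g)
    G[child, ] <- if (tot > 0) g / tot else rep(1 / k, k)
  }

  probs <- matrix(NA_real_, nnode, k,
                  dimnames = list(root:(ntip + nnode), fit$states))
  for (v in root:(ntip + nnode)) {
    m <- G[v, ] * down$L[v, ]
    tot <- sum(m)
    probs[v - ntip, ] <- if (tot > 0) m / tot else rep(1 / k, k)
  }
  # normalized rest-of-tree predictions for every node (tips included):
  # the distribution the model implies at a node given all data OUTSIDE
  # the node's own subtree
  G <- G / rowSums(G)
  dimnames(G) <- list(seq_len(ntip + nnode), fit$states)
  structure(probs, class = c("ancestral_states", "matrix"),
            tree = tree, fit = fit, rest_of_tree = G)
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat(sprintf("Marginal ancestral state probabilities (%d internal nodes)\n",
              nrow(x)))
  print(unclass(x)[seq_len(min(10, nrow(x))), , drop = FALSE])
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' @describeIn marginal_ancestral_states Long tibble of per-node state
#'   probabilities (`node`, `state`, `probability`).
#' @param x An `ancestral_states` object.
#' @param ... Unused.
#' @method tidy ancestral_states
#' @export
tidy.ancestral_states <- function(x, ...) {
  tibble::tibble(
    node = rep(as.integer(rownames(x)), times = ncol(x)),
    state = rep(colnames(x), each = nrow(x)),
    probability = as.vector(unclass(x))
  ) |> dplyr::arrange(.data$node)
}

#' Flag lineages whose ancestry contradicts their observed region
#'
#' Calls invasions of the focal region: lineages occurring in the focal
#' region whose reconstructed ancestry points elsewhere — the signature of
#' a recent, possibly camouflaged, introduction. The unit of assessment is
#' the maximal clade consisting entirely of focal-region tips (a single
#' tip in the limiting case). For each such clade the decision statistic
#' is the rest-of-tree prediction at the clade's root: the probability
#' distribution over regions implied by the fitted model and all data
#' *outside* the clade (equivalently, the marginal reconstruction with the
#' clade's own tips left out). The clade is flagged when at least
#' `threshold` of that predictive mass lies on non-focal states — its
#' ancestry says it should not be where it is.
#'
#' Evaluating the prediction at the clade root, rather than the full
#' marginal at nodes inside the clade, is what makes multi-tip calls
#' possible at all: within an all-focal clade the marginal necessarily
#' follows the tips. It also separates recent introductions from old
#' colonizations: over a long stem branch the rest-of-tree prediction
#' decays toward the uniform distribution, so anciently established
#' focal-region clades are not flagged even when their ancestor was
#' elsewhere, while a lineage sitting shallowly in a foreign clade keeps a
#' confident non-focal prediction. All tips of a flagged clade share one
#' clade-level call; tips observed outside the focal region are never
#' flagged.
#'
#' @param fit An `mk_fit` from [fit_mk()].
#' @param anc Matching `ancestral_states` from [marginal_ancestral_states()].
#' @param focal_region The region in which invasions are sought (e.g.
#'   `"Africa"`).
#' @param threshold Minimum rest-of-tree probability mass on non-focal
#'   states; must lie in (0.5, 1\] (default 0.9).
#' @return A tibble with one row per focal-region tip: `tip_label`,
#'   `observed_region`, `clade_node` (root of the maximal focal clade the
#'   tip belongs to), `confidence` (rest-of-tree mass on non-focal states
#'   at the clade root), `source_region` (the most probable non-focal
#'   source), `flagged`, and `call_id` numbering the flagged clade-level
#'   calls (`NA` for unflagged tips).
#' @export
call_invasions <- function(fit, anc, focal_region, threshold = 0.9) {
  stopifnot(inherits(fit, "mk_fit"), inherits(anc, "ancestral_states"))
  if (!focal_region %in% fit$states) {
    abort(sprintf("focal_region '%s' is not in the state set", focal_region))
  }
  if (!is.numeric(threshold) || threshold <= 0.5 || threshold > 1) {
    abort("threshold must lie in (0.5, 1]")
  }
  tree <- fit$tree
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent_of <- setNames(tree$edge[, 1], tree$edge[, 2])
  non_focal <- setdiff(fit$states, focal_region)
  G <- attr(anc, "rest_of_tree")

  # postorder: which nodes subtend only focal-region tips
  tr <- ape::reorder.phylo(tree, "postorder")
  all_focal <- c(fit$assignment == focal_region, rep(FALSE, tree$Nnode))
  for (ei in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[ei, 1]
    if (ei == 1 || tr$edge[ei - 1, 1] != parent) all_focal[parent] <- TRUE
    all_focal[parent] <- all_focal[parent] && all_focal[tr$edge[ei, 2]]
  }
  if (all_focal[root]) {
    warn("every tip is in the focal region; no outside context to call against")
  }

  focal_tips <- which(fit$assignment == focal_region)
  out <- tibble::tibble(
    tip_label = tree$tip.label[focal_tips],
    observed_region = focal_region,
    clade_node = NA_integer_,
    confidence = NA_real_, source_region = NA_character_,
    flagged = FALSE, call_id = NA_integer_
  )
  # climb from each focal tip to the root of its maximal all-focal clade
  for (i in seq_along(focal_tips)) {
    node <- focal_tips[i]
    repeat {
      up <- unname(parent_of[as.character(node)])
      if (is.na(up) || !all_focal[up]) break
      node <- up
    }
    out$clade_node[i] <- node
    if (node == root) next  # clade is the whole tree: no outside context
    pv <- G[node, ]
    out$confidence[i] <- sum(pv[non_focal])
    out$source_region[i] <- non_focal[which.max(pv[non_focal])]
    out$flagged[i] <- out$confidence[i] >= threshold
  }
  flagged_clades <- unique(out$clade_node[out$flagged])
  out$call_id <- match(out$clade_node, flagged_clades)
  out$call_id[!out$flagged] <- NA_integer_
  out
}
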