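#' Read and validate a rooted phylogeny from a newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contract the
#' ancestral-range machinery needs: a single rooted tree, unique tip labels,
#' branch lengths on every edge, all non-negative with at least one
#' strictly positive. Polytomies are allowed.
#'
#' @param path Path to a newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) abort(paste0("newick parse error: ",
                                                    conditionMessage(e))))
  if (is.null(tree)) abort("newick parse error: no tree found")
  if (inherits(tree, "multiPhylo")) {
    abort("expected a single tree, found several")
  }
  validate_tree(tree)
  tree
}

#' Write a phylogeny to a newick file
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort("not a phylo tree")
  if (!ape::is.rooted(tree)) abort("tree must be rooted")
  if (anyDuplicated(tree$tip.label)) {
    abort(paste0("duplicate tip labels: ",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", ")))
  }
  if (is.null(tree$edge.length)) abort("tree must have branch lengths")
  if (anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))[1]
    abort(sprintf("missing branch length on the edge to node %d",
                  tree$edge[bad, 2]))
  }
  if (any(tree$edge.length < 0)) abort("negative branch lengths")
  if (all(tree$edge.length == 0)) {
    abort("at least one branch length must be positive")
  }
  invisible(tree)
}

tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree))
}
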