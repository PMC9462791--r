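#' Read a rooted phylogeny with branch lengths from a Newick file
#'
#' Thin wrapper around \code{\link[ape]{read.tree}} that enforces the
#' invariants downstream analyses rely on: a single root, unique tip
#' labels, and non-negative branch lengths on every non-root branch.
#' Polytomies are preserved.
#'
#' @param path Newick file.
#' @param missing_branch_length `"error"` (default) to fail if any branch
#'   length is absent, or `"zero"` to substitute 0 with a warning.
#' @return An \pkg{ape} `phylo` object.
#' @export
read_nka_tree <- function(path, missing_branch_length = c("error", "zero")) {
  missing_branch_length <- match.arg(missing_branch_length)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  if (is.null(tree$edge.length)) {
    if (missing_branch_length == "error") stop("tree has no branch lengths")
    warning("tree has no branch lengths; set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (missing_branch_length == "error") stop("tree has missing branch lengths")
    warning("missing branch lengths set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  validate_phylogeny(tree)
  tree
}

#' Validate phylogeny invariants
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly; errors on violation.
#' @export
validate_phylogeny <- function(tree) {
  stop_if_not(inherits(tree, "phylo"), "not a phylo object")
  stop_if_not(!anyDuplicated(tree$tip.label), "tip labels are not unique")
  stop_if_not(all(tree$edge.length >= 0), "negative branch lengths")
  ## exactly one root: one node that never appears as a child
  nodes <- seq_len(ape::Ntip(tree) + tree$Nnode)
  parents <- unique(tree$edge[, 1])
  children <- tree$edge[, 2]
  roots <- setdiff(parents, children)
  stop_if_not(length(roots) == 1, "tree must have exactly one root")
  stop_if_not(length(children) == length(unique(children)) &&
              setequal(c(roots, children), nodes),
              "tree is not connected and acyclic")
  invisible(tree)
}

#' Scale branch lengths to a target mean
#'
#' Multiplies all branch lengths by one constant so that the mean branch
#' length equals `target_mean` (the correlated-evolution analyses use a
#' mean of 0.1 substitutions/site).
#'
#' @param tree A `phylo` object.
#' @param target_mean Desired mean branch length.
#' @return The rescaled tree.
#' @export
scale_branch_lengths <- function(tree, target_mean = 0.1) {
  m <- mean(tree$edge.length)
  if (m <= 0) stop("cannot scale: all branch lengths are zero")
  tree$edge.length <- tree$edge.length * (target_mean / m)
  tree
}

## root node id of an ape phylo
root_node <- function(tree) ape::Ntip(tree) + 1L
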