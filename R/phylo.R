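#' UPGMA tree from a distance matrix
#'
#' Rooted ultrametric tree by unweighted pair-group agglomeration with
#' arithmetic-mean linkage: the closest pair of clusters is merged and the
#' updated distances are member-count-weighted averages, so every leaf ends
#' at the same depth. Exact on ultrametric inputs. Labels are sorted before
#' building so the output is invariant to input row order.
#'
#' @param m A labeled distance matrix (see [validate_labeled_matrix()]).
#' @return A rooted [ape::phylo] tree.
#' @export
upgma_tree <- function(m) {
  m <- prepare_matrix(m, min_labels = 2)
  phangorn::upgma(stats::as.dist(m))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou–Nei neighbor joining: agglomeration by the Q criterion with the
#' standard branch-length formulas. Exact on additive matrices. Negative
#' branch lengths — which NJ can produce on non-additive input — are clamped
#' to zero with the deficit moved to the sibling edge, preserving leaf-to-leaf
#' path lengths through that node.
#'
#' @inheritParams upgma_tree
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(m) {
  m <- prepare_matrix(m, min_labels = 3)
  clamp_negative_edges(ape::nj(m))
}

#' BIONJ tree from a distance matrix
#'
#' BIONJ follows the neighbor-joining agglomeration order but reduces the
#' matrix with a variance-weighted update (the mixing weight minimizes the
#' variance of the reduced distances), which makes it more robust to the
#' larger stochastic error of larger distances. On additive matrices it
#' coincides with plain NJ. This is the default tree builder of the pipeline.
#'
#' @inheritParams upgma_tree
#' @return An unrooted [ape::phylo] tree.
#' @export
bionj_tree <- function(m) {
  m <- prepare_matrix(m, min_labels = 3)
  # the BIONJ implementation caps pairwise distances at 100; rescaling is
  # safe because tree topology is invariant to positive scaling
  scale <- max(1, max(m) / 99)
  tree <- ape::bionj(m / scale)
  tree$edge.length <- tree$edge.length * scale
  clamp_negative_edges(tree)
}

#' Build a tree with a selectable method
#'
#' @inheritParams upgma_tree
#' @param method One of `"bionj"` (default), `"nj"`, `"upgma"`.
#' @param outgroup Optional leaf label to root the tree at.
#' @return An [ape::phylo] tree.
#' @export
build_tree <- function(m, method = c("bionj", "nj", "upgma"), outgroup = NULL) {
  method <- match.arg(method)
  tree <- switch(method,
                 bionj = bionj_tree(m),
                 nj = nj_tree(m),
                 upgma = upgma_tree(m))
  if (!is.null(outgroup)) {
    tree <- root_with_outgroup(tree, outgroup)
  }
  tree
}

#' Root a tree with an outgroup
#'
#' Places the root on the branch leading to the designated distantly related
#' taxon; the ingroup splits are unchanged.
#'
#' @param tree An [ape::phylo] tree.
#' @param outgroup A leaf label of `tree`.
#' @return A rooted [ape::phylo] tree with the outgroup as one child of the
#'   root.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  if (!outgroup %in% tree$tip.label) {
    abort(paste0("outgroup label not a leaf of the tree: ", outgroup))
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Robinson–Foulds distance between two trees
#'
#' The number of nontrivial bipartitions (internal splits) present in exactly
#' one of the two trees, over an identical leaf set. 0 means topologically
#' identical.
#'
#' @param t1,t2 [ape::phylo] trees with identical leaf label sets.
#' @return A non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label) ||
      length(t1$tip.label) != length(t2$tip.label)) {
    abort("trees have different leaf label sets")
  }
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}

#' Leaf-to-leaf path distances induced by a tree
#'
#' Used as the reconstruction oracle: on additive (NJ) or ultrametric (UPGMA)
#' input the induced distances reproduce the input matrix.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return A labeled matrix of path distances, labels sorted.
#' @export
tree_distances <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  labs <- sort(rownames(m))
  new_dnv_dist(m[labs, labs])
}

prepare_matrix <- function(m, min_labels) {
  m <- validate_labeled_matrix(unclass(m))
  if (nrow(m) < min_labels) {
    abort(paste0("need at least ", min_labels, " labels, got ", nrow(m)))
  }
  labs <- sort(rownames(m))
  m[labs, labs]
}

# Zero out negative branch lengths, transferring the deficit to the sibling
# edge so path lengths through the parent node are preserved where possible.
clamp_negative_edges <- function(tree) {
  if (is.null(tree$edge.length) || all(tree$edge.length >= 0)) {
    return(tree)
  }
  neg <- which(tree$edge.length < 0)
  inform(paste0("clamping ", length(neg),
                " negative branch length(s) to zero"))
  for (e in neg) {
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1]
    sibling <- setdiff(which(tree$edge[, 1] == parent), e)
    if (length(sibling) > 0) {
      s <- sibling[1]
      tree$edge.length[s] <- max(0, tree$edge.length[s] + deficit)
    }
  }
  tree
}
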