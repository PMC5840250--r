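#' Hierarchical clustering of a compound distance matrix
#'
#' Thin wrapper around [stats::hclust()] restricted to the monotone linkages
#' that make sense for building an ultrametric biosynthesis tree. The default
#' is complete linkage, the [stats::hclust()] default. Ward linkage uses the
#' squared-dissimilarity implementation (`"ward.D2"`).
#'
#' @param d a validated symmetric distance matrix over at least two compounds.
#' @param linkage one of `"complete"`, `"average"`, `"single"`, `"ward"`.
#' @return an object of class `"hclust"` (the merge sequence with heights).
#' @export
hierarchical_cluster <- function(d, linkage = c("complete", "average", "single", "ward")) {
  linkage <- match.arg(linkage)
  validate_distance_matrix(d)
  if (nrow(d) < 2) stop("need at least 2 compounds to cluster")
  method <- if (linkage == "ward") "ward.D2" else linkage
  stats::hclust(stats::as.dist(d), method = method)
}

#' Convert a dendrogram into a rooted tree with branch lengths
#'
#' The merge sequence is turned into a rooted ultrametric tree of class
#' `"phylo"`: every internal node sits at `merge height * height_scale`,
#' leaves sit at height 0, and each edge length is the height difference
#' between parent and child. With the default `height_scale = 0.5` the
#' leaf-to-leaf path length through the first common ancestor equals the
#' cophenetic merge height, so patristic distances on the tree reproduce the
#' clustering heights exactly. UniFrac distances are invariant under uniform
#' edge rescaling, so `height_scale` never changes a sample distance.
#'
#' Zero-height merges (compounds with identical feature sets, e.g. products
#' of one multi-product enzyme) are legal and yield zero-length edges with
#' the leaves kept as distinct tips.
#'
#' @param merges an `"hclust"` object from [hierarchical_cluster()].
#' @param height_scale positive multiplier applied to merge heights;
#'   0.5 (default) makes patristic distance = cophenetic distance, 1 keeps
#'   raw heights.
#' @return a rooted `"phylo"` tree whose tips are the clustered compounds.
#' @export
dendrogram_to_tree <- function(merges, height_scale = 0.5) {
  stopifnot(inherits(merges, "hclust"))
  if (any(merges$height < 0)) stop("negative merge heights")
  if (!(is.numeric(height_scale) && length(height_scale) == 1 && height_scale > 0))
    stop("height_scale must be a single positive number")
  tree <- ape::as.phylo(merges)   # places nodes at height/2
  tree$edge.length <- tree$edge.length * (height_scale / 0.5)
  tree
}

#' Patristic (cophenetic) distances between the tips of a tree
#'
#' Sums branch lengths along the tip-to-tip paths. For a tree built by
#' [dendrogram_to_tree()] with `height_scale = 0.5` this reproduces the
#' cophenetic merge heights of the clustering.
#'
#' @param tree an object of class `"phylo"`.
#' @return a symmetric tip x tip distance matrix, in the tree's tip order.
#' @export
cophenetic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label]
}
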