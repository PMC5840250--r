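#' Convert quantities to within-sample relative abundances
#'
#' @param m sample x compound quantity matrix with positive row sums.
#' @return the matrix with each row rescaled to sum to 1.
#' @export
relative_abundance <- function(m) {
  validate_sample_matrix(m)
  m / rowSums(m)
}

#' Bray-Curtis dissimilarities between sample profiles
#'
#' The conventional quantitative dissimilarity used as the comparison point
#' throughout: \eqn{d(A,B) = \sum_k |x_{Ak} - x_{Bk}| / \sum_k (x_{Ak} + x_{Bk})}.
#' Computed with [vegan::vegdist()].
#'
#' @param m sample x compound quantity matrix.
#' @return a symmetric sample x sample distance matrix with entries in \[0, 1\].
#' @export
bray_curtis <- function(m) {
  validate_sample_matrix(m)
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Biosynthetically informed distances between sample profiles
#'
#' The full pipeline: Sorensen dissimilarities between compounds from shared
#' features ([sorensen_matrix()]), hierarchical clustering into a biosynthesis
#' tree ([hierarchical_cluster()], [dendrogram_to_tree()]), then weighted
#' generalized UniFrac between samples over that tree
#' ([generalized_unifrac()]). The resulting distance reflects how similar the
#' biosynthetic machineries behind two profiles are, not merely how many
#' compounds they share: two samples dominated by different monoterpenes are
#' close, a monoterpene sample and an aromatic sample are far apart, even at
#' identical Bray-Curtis dissimilarity.
#'
#' Features may be enzymes (full resolution) or chemical classes / functional
#' groups (coarse resolution; see [merge_dist()] for the class-based variant
#' fused with Bray-Curtis).
#'
#' @param m sample x compound quantity (or presence/absence) matrix.
#' @param f compound x feature 0/1 matrix. Must cover every compound of `m`;
#'   compounds of `f` not appearing in `m` are ignored.
#' @param linkage clustering linkage, see [hierarchical_cluster()].
#' @param alpha UniFrac abundance exponent, see [generalized_unifrac()].
#' @param height_scale dendrogram-to-tree scaling, see [dendrogram_to_tree()].
#' @param missing_compounds what to do with compounds of `m` that have no
#'   feature annotation in `f`: `"error"` (default) or `"drop"` them from the
#'   analysis with a warning. Dropping changes the distances, so it is never
#'   silent.
#' @return a list of class `"biosyn_dist"` with elements `distances` (sample
#'   x sample UniFrac matrix), `tree` (the `"phylo"` biosynthesis tree),
#'   `compound_distances` (the Sorensen matrix) and `clustering` (the
#'   `"hclust"` merge sequence).
#' @export
biosyn_dist <- function(m, f, linkage = "complete", alpha = 0.5,
                        height_scale = 0.5,
                        missing_compounds = c("error", "drop")) {
  missing_compounds <- match.arg(missing_compounds)
  validate_sample_matrix(m)
  validate_feature_matrix(f)
  unannotated <- setdiff(colnames(m), rownames(f))
  if (length(unannotated)) {
    if (missing_compounds == "error")
      stop(sprintf("compound(s) without feature annotation: %s",
                   paste(unannotated, collapse = ", ")))
    warning(sprintf("dropping %d unannotated compound(s): %s",
                    length(unannotated), paste(unannotated, collapse = ", ")))
    m <- m[, setdiff(colnames(m), unannotated), drop = FALSE]
    validate_sample_matrix(m)   # a sample may have lost all its compounds
  }
  f <- f[colnames(m), , drop = FALSE]
  cd <- sorensen_matrix(f)
  if (nrow(cd) < 2)
    stop("need at least 2 compounds to build a biosynthesis tree")
  hc <- hierarchical_cluster(cd, linkage = linkage)
  tree <- dendrogram_to_tree(hc, height_scale = height_scale)
  dist <- if (nrow(m) == 1) {
    matrix(0, 1, 1, dimnames = list(rownames(m), rownames(m)))
  } else {
    generalized_unifrac(tree, m, alpha = alpha)
  }
  structure(list(distances = dist, tree = tree, compound_distances = cd,
                 clustering = hc),
            class = "biosyn_dist")
}

#' @export
print.biosyn_dist <- function(x, ...) {
  cat(sprintf("Biosynthetically informed distances: %d samples, %d compounds\n",
              nrow(x$distances), nrow(x$compound_distances)))
  cat(sprintf("  mean distance %.3f, range [%.3f, %.3f]\n",
              mean(x$distances[lower.tri(x$distances)]),
              min(x$distances[lower.tri(x$distances)]),
              max(x$distances[lower.tri(x$distances)])))
  invisible(x)
}
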