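#' Pairwise Sorensen dissimilarities between compounds
#'
#' For two compounds with `a` shared features, `b` features unique to the
#' first and `c` unique to the second, the Sorensen (Dice) dissimilarity is
#'
#' \deqn{d = 1 - \frac{2a}{2a + b + c}.}
#'
#' With features = biosynthetic enzymes, small values mean the two compounds
#' are produced by largely overlapping enzyme sets (e.g. two monoterpenes
#' sharing the MEP backbone); `d = 0` occurs for multi-product enzymes that
#' make the feature sets identical (alpha- and beta-pinene from the same
#' terpene synthase), and `d = 1` for compounds from disjoint pathways.
#'
#' @param features a validated compound x feature 0/1 matrix.
#' @return a symmetric compound x compound distance matrix with zero diagonal,
#'   entries in \[0, 1\].
#' @export
sorensen_matrix <- function(features) {
  validate_feature_matrix(features)
  a <- features %*% t(features)        # shared feature counts
  n <- rowSums(features)               # feature set sizes
  tot <- outer(n, n, `+`)              # 2a + b + c
  d <- 1 - 2 * a / tot
  diag(d) <- 0
  d[d < 0] <- 0                        # clamp -0 rounding
  dimnames(d) <- list(rownames(features), rownames(features))
  d
}
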