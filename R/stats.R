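#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries, with significance from
#' a one-sided permutation test: the rows and columns of `d2` are permuted
#' simultaneously `n_perm` times and
#' \deqn{p = \frac{\#\{r_{perm} \ge r_{obs}\} + 1}{n_{perm} + 1},}
#' so p is never exactly zero. With 999 permutations the smallest reportable
#' p is 0.001.
#'
#' @param d1,d2 distance matrices over identical samples in identical order;
#'   at least 4 samples are needed for a meaningful permutation null.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation stream.
#' @return a list of class `"mantel_result"`: `r`, `p`, `n_perm`, `seed`,
#'   and the vector `perm_r` of permuted statistics.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL) {
  validate_distance_matrix(d1)
  validate_distance_matrix(d2)
  check_same_ids(d1, d2)
  n <- nrow(d1)
  if (n < 4) stop("need at least 4 samples for a Mantel test")
  v1 <- d1[lower.tri(d1)]
  if (stats::sd(v1) == 0 || stats::sd(d2[lower.tri(d2)]) == 0)
    stop("constant distance matrix; correlation undefined")
  r <- stats::cor(v1, d2[lower.tri(d2)])
  if (!is.null(seed)) set.seed(seed)
  perm_r <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n)
    dp <- d2[idx, idx]
    stats::cor(v1, dp[lower.tri(dp)])
  }, numeric(1))
  p <- (sum(perm_r >= r) + 1) / (n_perm + 1)
  structure(list(r = r, p = p, n_perm = n_perm, seed = seed, perm_r = perm_r),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel statistic (Pearson): r = %.4f, p = %.4g (%d permutations)\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Runs [vegan::metaMDS()] (monotone stress-1 NMDS with multiple random
#' starts) on a distance matrix and returns the best configuration found.
#' Deterministic given `seed`.
#'
#' @param d a validated distance matrix over at least `k + 1` samples.
#' @param k number of ordination dimensions.
#' @param n_starts maximum number of random starts.
#' @param seed integer seed.
#' @return a list of class `"nmds_fit"`: `points` (sample x k coordinates),
#'   `stress`, `converged`, and the underlying `metaMDS` object as `fit`.
#' @export
nmds_ordination <- function(d, k = 2, n_starts = 20, seed = NULL) {
  validate_distance_matrix(d)
  if (k >= nrow(d)) stop("k must be smaller than the number of samples")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::metaMDS(stats::as.dist(d), k = k, trymax = n_starts,
                        trace = 0, autotransform = FALSE, wascores = FALSE)
  pts <- fit$points
  rownames(pts) <- rownames(d)
  structure(list(points = pts, stress = fit$stress,
                 converged = isTRUE(fit$converged > 0) || isTRUE(fit$converged),
                 fit = fit),
            class = "nmds_fit")
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf("NMDS: %d samples in %d dimensions, stress = %.4f\n",
              nrow(x$points), ncol(x$points), x$stress))
  invisible(x)
}

#' Goodness of fit of a grouping factor on ordination coordinates
#'
#' The centroid-based \eqn{r^2} used when fitting a factor onto an NMDS:
#' \deqn{r^2 = 1 - SS_{within} / SS_{total},}
#' where \eqn{SS_{within}} sums squared Euclidean deviations of the
#' coordinates from their group centroids and \eqn{SS_{total}} from the
#' grand centroid. Significance by permuting the group labels.
#'
#' @param coords sample x dimension coordinate matrix (e.g.
#'   `nmds_ordination(d)$points`).
#' @param labels grouping factor, one label per sample, at least two groups.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return a list of class `"factor_fit"`: `r2`, `p`, `n_perm`, `seed`.
#' @export
factor_fit <- function(coords, labels, n_perm = 999, seed = NULL) {
  coords <- as.matrix(coords)
  labels <- as.factor(labels)
  if (length(labels) != nrow(coords))
    stop("one label per sample required")
  if (nlevels(droplevels(labels)) < 2)
    stop("need at least two groups")
  r2 <- factor_r2(coords, labels)
  if (!is.null(seed)) set.seed(seed)
  perm_r2 <- vapply(seq_len(n_perm), function(i)
    factor_r2(coords, labels[sample.int(length(labels))]), numeric(1))
  p <- (sum(perm_r2 >= r2) + 1) / (n_perm + 1)
  structure(list(r2 = r2, p = p, n_perm = n_perm, seed = seed),
            class = "factor_fit")
}

factor_r2 <- function(coords, labels) {
  grand <- colMeans(coords)
  ss_tot <- sum(sweep(coords, 2, grand)^2)
  ss_within <- 0
  for (g in levels(labels)) {
    sub <- coords[labels == g, , drop = FALSE]
    if (nrow(sub) == 0) next
    ss_within <- ss_within + sum(sweep(sub, 2, colMeans(sub))^2)
  }
  1 - ss_within / ss_tot
}

#' @export
print.factor_fit <- function(x, ...) {
  cat(sprintf("Factor fit: r2 = %.4f, p = %.4g (%d permutations)\n",
              x$r2, x$p, x$n_perm))
  invisible(x)
}
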