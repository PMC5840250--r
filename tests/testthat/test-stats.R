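test_that("mantel r is the pearson correlation of the triangles", {
  set.seed(51)
  d1 <- random_distance_matrix(6)
  d2 <- random_distance_matrix(6)
  res <- mantel_test(d1, d2, n_perm = 99, seed = 1)
  expect_equal(res$r, stats::cor(d1[lower.tri(d1)], d2[lower.tri(d2)]))
  expect_equal(mantel_test(d1, d1, n_perm = 9, seed = 1)$r, 1)
  # symmetry in the matrix arguments
  expect_equal(mantel_test(d2, d1, n_perm = 9, seed = 1)$r, res$r)
  # the +1 correction keeps p strictly positive
  expect_gt(mantel_test(d1, d1, n_perm = 99, seed = 1)$p, 0)
  expect_error(mantel_test(d1[1:3, 1:3], d2[1:3, 1:3], seed = 1), "at least 4")
})

test_that("mantel agrees with vegan on the statistic", {
  set.seed(52)
  d1 <- random_distance_matrix(8)
  d2 <- random_distance_matrix(8)
  ours <- mantel_test(d1, d2, n_perm = 99, seed = 1)
  ref <- vegan::mantel(stats::as.dist(d1), stats::as.dist(d2), permutations = 99)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("mantel p converges to the exhaustive permutation null at n = 4", {
  # 4 samples: only 24 simultaneous row/column permutations exist
  set.seed(53)
  d1 <- random_distance_matrix(4)
  d2 <- random_distance_matrix(4)
  v1 <- d1[lower.tri(d1)]
  r_obs <- stats::cor(v1, d2[lower.tri(d2)])
  r_all <- vapply(all_perms(4), function(idx) {
    dp <- d2[idx, idx]
    stats::cor(v1, dp[lower.tri(dp)])
  }, numeric(1))
  p_exact <- mean(r_all >= r_obs)
  res <- mantel_test(d1, d2, n_perm = 9999, seed = 7)
  expect_lt(abs(res$p - p_exact), 0.02)
  # identity permutation is always counted: p_exact is itself >= 1/24
  expect_gte(p_exact, 1 / 24)
})

test_that("nmds embeds embeddable configurations at near-zero stress", {
  # three equidistant samples fit a plane exactly
  d3 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d3) <- 0
  fit3 <- suppressWarnings(nmds_ordination(d3, k = 2, seed = 1))
  expect_lt(fit3$stress, 1e-4)
  # distances from actual planar points: recovered at stress ~ 0 with
  # identical distance ranks
  set.seed(54)
  pts <- matrix(stats::rnorm(16), 8, 2)
  d <- as.matrix(stats::dist(pts))
  dimnames(d) <- list(paste0("s", 1:8), paste0("s", 1:8))
  fit <- suppressWarnings(nmds_ordination(d, k = 2, seed = 2))
  expect_lt(fit$stress, 0.01)
  rec <- stats::dist(fit$points)
  expect_gt(stats::cor(as.vector(rec), as.vector(stats::as.dist(d)),
                       method = "spearman"), 0.99)
  expect_error(nmds_ordination(d3, k = 3, seed = 1), "k must")
})

test_that("factor fit r2 matches its closed form and hits the bounds", {
  # two tight groups at distinct points: perfect split
  coords <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  fit <- factor_fit(coords, c("g1", "g1", "g2", "g2"), n_perm = 99, seed = 1)
  expect_equal(fit$r2, 1)
  # preset within/between sums of squares: SSw = 4, SStot = 20, r2 = 0.8
  coords2 <- rbind(c(0, 1), c(0, -1), c(4, 1), c(4, -1))
  fit2 <- factor_fit(coords2, c("a", "a", "b", "b"), n_perm = 99, seed = 1)
  expect_equal(fit2$r2, 0.8)
  expect_error(factor_fit(coords2, rep("a", 4), seed = 1), "two groups")
})

test_that("factor fit agrees with vegan's envfit goodness of fit", {
  set.seed(55)
  coords <- matrix(stats::rnorm(40), 20, 2)
  labels <- rep(c("x", "y"), each = 10)
  ours <- factor_fit(coords, labels, n_perm = 99, seed = 1)
  ref <- vegan::envfit(coords, data.frame(f = factor(labels)), permutations = 99)
  expect_equal(ours$r2, unname(ref$factors$r), tolerance = 1e-10)
})

test_that("factor fit r2 is near zero under random labels", {
  set.seed(56)
  coords <- matrix(stats::rnorm(120), 60, 2)
  r2s <- replicate(20, factor_r2_null <- {
    lab <- sample(rep(c("a", "b"), each = 30))
    factor_fit(coords, lab, n_perm = 1, seed = 1)$r2
  })
  expect_lt(mean(r2s), 0.1)
})
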