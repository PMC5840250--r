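test_that("relative abundance normalises rows exactly", {
  m <- rbind(s1 = c(2, 2, 0), s2 = c(1, 1, 1))
  colnames(m) <- paste0("c", 1:3)
  r <- relative_abundance(m)
  expect_equal(unname(r["s1", ]), c(0.5, 0.5, 0))
  expect_equal(unname(rowSums(r)), c(1, 1))
  pa <- rbind(s1 = c(1, 1, 1, 1)); colnames(pa) <- paste0("c", 1:4)
  expect_equal(unname(relative_abundance(pa)[1, ]), rep(0.25, 4))
  ds <- make_hypothetical_dataset()
  expect_lt(max(abs(rowSums(relative_abundance(ds$samples)) - 1)), 1e-12)
})

test_that("bray-curtis matches direct evaluation", {
  m <- rbind(A = c(1, 2, 0), B = c(0, 2, 3), C = c(1, 2, 0))
  colnames(m) <- paste0("c", 1:3)
  d <- bray_curtis(m)
  expect_equal(d["A", "B"], 0.5)          # (1+0+3)/(1+4+3)
  expect_identical(d["A", "C"], 0)
  disj <- rbind(A = c(1, 1, 0, 0), B = c(0, 0, 2, 5))
  colnames(disj) <- paste0("c", 1:4)
  expect_equal(bray_curtis(disj)["A", "B"], 1)
})

test_that("the pipeline composes its stages and returns inspectable parts", {
  ds <- make_hypothetical_dataset()
  res <- biosyn_dist(ds$samples, ds$enzymes)
  validate_distance_matrix(res$distances)
  expect_identical(rownames(res$distances), rownames(ds$samples))
  expect_s3_class(res$clustering, "hclust")
  expect_s3_class(res$tree, "phylo")
  expect_setequal(res$tree$tip.label, colnames(ds$samples))
  # the returned distances equal running the stages by hand
  tree <- dendrogram_to_tree(hierarchical_cluster(sorensen_matrix(ds$enzymes)))
  expect_equal(res$distances, generalized_unifrac(tree, ds$samples))
  # single sample: a 1x1 zero matrix
  one <- biosyn_dist(ds$samples[1, , drop = FALSE], ds$enzymes)
  expect_identical(one$distances, matrix(0, 1, 1, dimnames = list("A", "A")))
})

test_that("unannotated compounds are a hard error unless explicitly dropped", {
  ds <- make_hypothetical_dataset()
  f <- ds$enzymes[-1, ]   # drop alpha-pinene's annotation
  expect_error(biosyn_dist(ds$samples, f), "alpha-pinene")
  expect_warning(res <- biosyn_dist(ds$samples, f, missing_compounds = "drop"),
                 "alpha-pinene")
  expect_false("alpha-pinene" %in% res$tree$tip.label)
})

test_that("profiles sharing no compound but the same pathways stay close", {
  ds <- make_hypothetical_dataset()
  res <- biosyn_dist(ds$samples, ds$enzymes)
  bc <- bray_curtis(ds$samples)
  s_bio <- standardize_dist(res$distances)
  s_bc <- standardize_dist(bc)
  # C and D share not a single compound, so Bray-Curtis is maximal...
  expect_equal(bc["C", "D"], 1)
  # ...but biosynthetically they are near neighbours
  expect_lt(s_bio["C", "D"], s_bc["C", "D"])
  # E and F differ only in the products of one terpene synthase
  expect_equal(res$distances["E", "F"], 0)
  expect_gt(bc["E", "F"], 0)
})

test_that("table of distance-measure contrasts holds on the built-in fixture", {
  ds <- make_hypothetical_dataset()
  res <- biosyn_dist(ds$samples, ds$enzymes)
  s_bio <- standardize_dist(res$distances)
  s_bc <- standardize_dist(bray_curtis(ds$samples))
  contrasts <- c(list(c("C", "D"), c("E", "F"), c("G", "H")),
                 combn(c("I", "J", "K", "L"), 2, simplify = FALSE))
  for (pr in contrasts) {
    expect_lt(s_bio[pr[1], pr[2]], s_bc[pr[1], pr[2]])
  }
})

test_that("height_scale and branch rescaling never change sample distances", {
  ds <- make_hypothetical_dataset()
  d1 <- biosyn_dist(ds$samples, ds$enzymes, height_scale = 0.5)$distances
  d2 <- biosyn_dist(ds$samples, ds$enzymes, height_scale = 1)$distances
  expect_equal(d1, d2, tolerance = 1e-12)
})
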