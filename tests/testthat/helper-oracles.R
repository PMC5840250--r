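# Independent oracles and random-instance generators used across the suite.
# These deliberately avoid the package's own code paths: UniFrac by explicit
# per-edge enumeration via root paths, patristic distances by walking node
# paths, permutations by exhaustive recursion.

# generalized UniFrac between two named proportion vectors, enumerating every
# edge explicitly and finding its descendant tips through root-to-tip paths
oracle_unifrac <- function(tree, pA, pB, alpha) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  num <- 0
  den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    below <- Filter(function(tip) child %in% ape::nodepath(tree, root, tip),
                    seq_len(ntip))
    a <- sum(pA[tree$tip.label[below]])
    b <- sum(pB[tree$tip.label[below]])
    s <- a + b
    if (s > 0) {
      num <- num + tree$edge.length[e] * s^alpha * abs(a - b) / s
      den <- den + tree$edge.length[e] * s^alpha
    }
  }
  num / den
}

# patristic distance between two tips by summing edge lengths along the path
oracle_patristic <- function(tree, i, j) {
  path <- ape::nodepath(tree, i, j)
  total <- 0
  for (k in seq_len(length(path) - 1)) {
    e <- which((tree$edge[, 1] == path[k] & tree$edge[, 2] == path[k + 1]) |
               (tree$edge[, 1] == path[k + 1] & tree$edge[, 2] == path[k]))
    total <- total + tree$edge.length[e]
  }
  total
}

# all permutations of 1..n (exhaustive Mantel null at tiny n)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(sub, n, after = pos)
    }
  }
  out
}

# random valid sample matrix (proportional zeros, no empty rows)
random_sample_matrix <- function(n_samples, n_compounds, zero_prob = 0.3) {
  m <- matrix(stats::runif(n_samples * n_compounds, 0.1, 10),
              n_samples, n_compounds,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              paste0("c", seq_len(n_compounds))))
  m[stats::runif(length(m)) < zero_prob] <- 0
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1
  m
}

# random valid feature matrix (no empty compound rows)
random_feature_matrix <- function(n_compounds, n_features, p = 0.4) {
  f <- matrix(as.numeric(stats::runif(n_compounds * n_features) < p),
              n_compounds, n_features,
              dimnames = list(paste0("c", seq_len(n_compounds)),
                              paste0("e", seq_len(n_features))))
  empty <- rowSums(f) == 0
  f[cbind(which(empty), sample.int(n_features, sum(empty), replace = TRUE))] <- 1
  f
}

# random valid distance matrix from points in the plane
random_distance_matrix <- function(n, ids = paste0("s", seq_len(n))) {
  pts <- matrix(stats::rnorm(2 * n), n, 2)
  d <- as.matrix(stats::dist(pts))
  dimnames(d) <- list(ids, ids)
  d
}

# direct three-set Sorensen on two feature index sets
oracle_sorensen <- function(x, y) {
  a <- length(intersect(x, y))
  b <- length(setdiff(x, y))
  c_ <- length(setdiff(y, x))
  1 - 2 * a / (2 * a + b + c_)
}
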