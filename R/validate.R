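#' Validate a sample x compound quantity matrix
#'
#' Checks the invariants required of a sample profile matrix: a numeric matrix
#' with unique sample row names and compound column names, no missing entries,
#' no negative quantities, and at least one strictly positive entry per sample
#' (an empty profile carries no information and breaks normalisation).
#'
#' @param m numeric matrix, samples in rows, compounds in columns.
#' @return `m`, invisibly, if valid; otherwise an error describing the
#'   offending row/column.
#' @export
validate_sample_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("sample matrix must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("sample matrix must carry sample row names and compound column names")
  check_unique(rownames(m), "sample")
  check_unique(colnames(m), "compound")
  if (anyNA(m))
    stop("sample matrix contains missing values; encode absence as 0")
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative quantity at sample '%s', compound '%s'",
                 rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  zero <- rowSums(m) <= 0
  if (any(zero))
    stop(sprintf("sample '%s' has no positive entry", rownames(m)[which(zero)[1]]))
  invisible(m)
}

#' Validate a compound x feature presence/absence matrix
#'
#' Features are typically biosynthetic enzymes, but chemical classes,
#' functional groups or any other binary compound trait work identically.
#' Every entry must be 0 or 1 and every compound must carry at least one
#' feature (a compound with no annotated feature has no defined position in
#' the biosynthesis tree).
#'
#' @param f 0/1 matrix, compounds in rows, features in columns.
#' @return `f`, invisibly, if valid.
#' @export
validate_feature_matrix <- function(f) {
  if (!is.matrix(f) || !is.numeric(f))
    stop("feature matrix must be a numeric matrix")
  if (is.null(rownames(f)) || is.null(colnames(f)))
    stop("feature matrix must carry compound row names and feature column names")
  check_unique(rownames(f), "compound")
  check_unique(colnames(f), "feature")
  if (anyNA(f))
    stop("feature matrix contains missing values; presence/absence must be asserted")
  if (!all(f %in% c(0, 1))) {
    idx <- which(!(f %in% c(0, 1)))[1]
    ai <- arrayInd(idx, dim(f))
    stop(sprintf("feature matrix entry at compound '%s', feature '%s' is not 0/1",
                 rownames(f)[ai[1]], colnames(f)[ai[2]]))
  }
  zero <- rowSums(f) == 0
  if (any(zero))
    stop(sprintf("compound '%s' has no feature assigned", rownames(f)[which(zero)[1]]))
  invisible(f)
}

#' Validate a labelled symmetric distance matrix
#'
#' @param d numeric square matrix with identical row/column labels, symmetric,
#'   zero diagonal, all entries non-negative.
#' @param tol numeric tolerance for symmetry and the zero diagonal.
#' @return `d`, invisibly, if valid.
#' @export
validate_distance_matrix <- function(d, tol = 1e-8) {
  if (!is.matrix(d) || !is.numeric(d))
    stop("distance matrix must be a numeric matrix")
  if (nrow(d) != ncol(d))
    stop("distance matrix must be square")
  if (is.null(rownames(d)) || is.null(colnames(d)))
    stop("distance matrix must carry labels")
  if (!identical(rownames(d), colnames(d)))
    stop("distance matrix row and column labels differ")
  check_unique(rownames(d), "distance matrix label")
  if (anyNA(d)) stop("distance matrix contains missing values")
  if (any(abs(d - t(d)) > tol))
    stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > tol))
    stop("distance matrix diagonal is not zero")
  if (any(d < -tol))
    stop("distance matrix contains negative entries")
  invisible(d)
}

check_unique <- function(x, what) {
  dup <- x[duplicated(x)]
  if (length(dup))
    stop(sprintf("duplicate %s label: '%s'", what, dup[1]))
  invisible(x)
}

# shared guard: two distance matrices over the same samples in the same order
check_same_ids <- function(d1, d2) {
  if (!identical(rownames(d1), rownames(d2)))
    stop("distance matrices are not over identical samples in identical order")
  invisible(TRUE)
}
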