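#' Read a sample x compound quantity matrix from CSV
#'
#' Expects a delimited table with one header row and one label column.
#' The delimiter is auto-detected ("," vs ";"). Blank cells and NA cells are
#' read as 0, following the convention that an absent compound is simply not
#' listed in a profile. Quantities may be absolute or relative amounts or
#' 0/1 presence/absence; all downstream distances accept either.
#'
#' @param path path to a CSV file.
#' @param orientation `"samples_as_rows"` (default) if samples are the table
#'   rows, `"samples_as_cols"` if the table is transposed.
#' @return a numeric matrix with samples in rows and compounds in columns,
#'   validated by [validate_sample_matrix()].
#' @export
read_sample_matrix <- function(path,
                               orientation = c("samples_as_rows", "samples_as_cols")) {
  orientation <- match.arg(orientation)
  m <- read_labelled_csv(path)
  m[is.na(m)] <- 0
  if (orientation == "samples_as_cols") m <- t(m)
  validate_sample_matrix(m)
  m
}

#' Read a compound x feature presence/absence matrix from CSV
#'
#' TRUE/FALSE cells are coerced to 1/0. Any other non-0/1 entry, and any
#' missing cell, is an error: presence or absence of a feature must be
#' asserted explicitly for every compound.
#'
#' @param path path to a CSV file with compounds in rows, features
#'   (enzymes, chemical classes, ...) in columns.
#' @return a 0/1 matrix validated by [validate_feature_matrix()].
#' @export
read_feature_matrix <- function(path) {
  f <- read_labelled_csv(path, coerce_logical = TRUE)
  validate_feature_matrix(f)
  f
}

#' Read / write a labelled square distance matrix
#'
#' `write_distance_matrix()` writes a square labelled CSV;
#' `read_distance_matrix()` reads one back and validates symmetry, the zero
#' diagonal and non-negativity. A write/read round trip reproduces the matrix
#' to well below 1e-12 per entry.
#'
#' @param d a validated distance matrix.
#' @param path file path.
#' @return `read_distance_matrix()` returns the validated matrix;
#'   `write_distance_matrix()` returns `path` invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  validate_distance_matrix(d)
  df <- data.frame(id = rownames(d), d, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  d <- read_labelled_csv(path)
  colnames(d) <- enc2utf8(colnames(d))
  validate_distance_matrix(d)
  d
}

#' Write a tree in Newick format, quoting awkward labels
#'
#' Compound names routinely contain characters that are syntax in Newick —
#' commas, parentheses, colons ("(E)-beta-ocimene", "2,3-butanediol") — so
#' labels containing any such character are written single-quoted, with
#' embedded quotes doubled, per the Newick standard. `read_newick()` reads a
#' Newick file and strips that quoting again, so a write/read round trip
#' recovers labels verbatim.
#'
#' @param tree an object of class `"phylo"` (see [dendrogram_to_tree()]).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  tmp <- tree
  tmp$node.label <- NULL
  tmp$tip.label <- sprintf("xTIPx%dx", seq_along(tree$tip.label))
  s <- ape::write.tree(tmp)
  for (i in seq_along(tree$tip.label)) {
    s <- sub(sprintf("xTIPx%dx", i), quote_newick_label(tree$tip.label[i]),
             s, fixed = TRUE)
  }
  writeLines(s, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  tree$tip.label <- unquote_newick_label(tree$tip.label)
  tree
}

quote_newick_label <- function(x) {
  needs <- grepl("[][ ,;:()']", x)   # "]" first so the class parses as POSIX
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

unquote_newick_label <- function(x) {
  quoted <- grepl("^'.*'$", x)
  x[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[quoted]))
  x
}

# Delimited read with "," vs ";" auto-detection; first row = column labels,
# first column = row labels. Returns a numeric matrix.
read_labelled_csv <- function(path, coerce_logical = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (lengths(regmatches(header, gregexpr(";", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) ";" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          encoding = "UTF-8")
  if (ncol(df) < 2) stop(sprintf("'%s' does not parse as a labelled table", path))
  labels <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  if (coerce_logical) {
    body[] <- lapply(body, function(col) {
      if (is.logical(col)) as.numeric(col)
      else if (is.character(col)) {
        up <- toupper(trimws(col))
        out <- suppressWarnings(as.numeric(col))
        out[up == "TRUE"] <- 1
        out[up == "FALSE"] <- 0
        out
      } else col
    })
  }
  bad <- !vapply(body, is.numeric, logical(1))
  if (any(bad))
    stop(sprintf("column '%s' of '%s' is not numeric", names(body)[bad][1], path))
  m <- as.matrix(body)
  storage.mode(m) <- "double"
  rownames(m) <- enc2utf8(labels)
  colnames(m) <- enc2utf8(colnames(m))
  m
}
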