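#' Labeled sample-by-feature matrix
#'
#' Lightweight container for an omics data matrix: samples in rows, features in
#' columns, plus an optional binary class label per sample. Unlabeled matrices
#' (e.g. the "external" pre-training data) simply carry `labels = NULL`.
#'
#' @param values Numeric matrix, samples x features. Must contain no missing
#'   values.
#' @param labels Optional vector of class labels, one per row; must take
#'   exactly two distinct values when present.
#' @param feature_names Optional character vector of feature identifiers;
#'   defaults to the column names of `values` or `"f1"`, `"f2"`, ...
#'
#' @return An object of class `labeled_matrix` with elements `values`,
#'   `labels` and `feature_names`.
#' @export
labeled_matrix <- function(values, labels = NULL, feature_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  assert_that(!anyNA(values), "labeled_matrix values must not contain missing values")
  if (is.null(feature_names)) {
    feature_names <- colnames(values) %||% paste0("f", seq_len(ncol(values)))
  }
  assert_that(length(feature_names) == ncol(values),
              "feature_names length must match the number of columns")
  colnames(values) <- feature_names
  if (!is.null(labels)) {
    assert_that(length(labels) == nrow(values),
                "labels must have one entry per row of values")
    assert_that(length(unique(labels)) <= 2,
                "labels must take at most two distinct values")
  }
  structure(list(values = values, labels = labels, feature_names = feature_names),
            class = "labeled_matrix")
}

#' @export
print.labeled_matrix <- function(x, ...) {
  cat(sprintf("<labeled_matrix> %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  if (is.null(x$labels)) {
    cat("  unlabeled\n")
  } else {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.labeled_matrix <- function(x) dim(x$values)

# Subset rows, keeping labels aligned.
lm_subset <- function(x, idx) {
  labeled_matrix(x$values[idx, , drop = FALSE],
                 labels = if (!is.null(x$labels)) x$labels[idx],
                 feature_names = x$feature_names)
}

# Stack two labeled matrices with identical feature sets.
lm_rbind <- function(a, b) {
  assert_that(identical(a$feature_names, b$feature_names),
              "cannot combine matrices with different feature sets")
  labels <- if (is.null(a$labels) && is.null(b$labels)) NULL else c(a$labels, b$labels)
  labeled_matrix(rbind(a$values, b$values), labels = labels,
                 feature_names = a$feature_names)
}

#' Read / write labeled matrices as CSV
#'
#' CSV layout: samples as rows, a header row of feature names, and (for
#' labeled data) a final `label` column. Comma-separated, UTF-8, no row-name
#' column.
#'
#' @param x A [labeled_matrix()].
#' @param path File path.
#' @return `read_labeled_csv` returns a [labeled_matrix()];
#'   `write_labeled_csv` returns `path` invisibly.
#' @export
write_labeled_csv <- function(x, path) {
  df <- as.data.frame(x$values)
  if (!is.null(x$labels)) df$label <- x$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labeled_csv
#' @export
read_labeled_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- df$label
    df$label <- NULL
  }
  labeled_matrix(as.matrix(df), labels = labels, feature_names = names(df))
}
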