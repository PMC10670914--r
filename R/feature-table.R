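#' Construct a two-class feature table
#'
#' A `feature_table` is the currency of the pipeline: an `n x d` numeric
#' matrix of per-image features plus a binary label vector. Label 1 is the
#' positive (carcinoma-analog) class throughout the package; label 0 is the
#' normal class.
#'
#' @param features Numeric matrix (`n x d`), no missing values.
#' @param labels Integer vector of length `n` with values in \{0, 1\}.
#' @param feature_names Optional character vector of `d` column names.
#'   Defaults to `f0 ... f{d-1}`.
#' @return An object of class `feature_table` with elements `features`,
#'   `labels` and `feature_names`.
#' @examples
#' ft <- feature_table(matrix(rnorm(40), 8, 5), labels = rep(0:1, each = 4))
#' dim(ft)
#' @export
feature_table <- function(features, labels, feature_names = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (anyNA(features)) stop("feature_table: features contain missing values")
  n <- nrow(features)
  d <- ncol(features)
  if (d < 1L) stop("feature_table: need at least one feature column")
  labels <- as.integer(labels)
  if (length(labels) != n) {
    stop(sprintf("feature_table: %d labels for %d rows", length(labels), n))
  }
  if (n > 0L && !all(labels %in% c(0L, 1L))) {
    stop("feature_table: labels must be 0 (normal) or 1 (positive class)")
  }
  if (is.null(feature_names)) {
    feature_names <- paste0("f", seq_len(d) - 1L)
  }
  feature_names <- as.character(feature_names)
  if (length(feature_names) != d) {
    stop("feature_table: feature_names length must equal feature count")
  }
  colnames(features) <- feature_names
  structure(
    list(features = features, labels = labels, feature_names = feature_names),
    class = "feature_table"
  )
}

#' @export
dim.feature_table <- function(x) dim(x$features)

#' @export
print.feature_table <- function(x, ...) {
  n <- nrow(x$features)
  cat(sprintf(
    "feature_table: %d samples x %d features (%d normal / %d positive)\n",
    n, ncol(x$features), sum(x$labels == 0L), sum(x$labels == 1L)
  ))
  invisible(x)
}

#' Subset the rows of a feature table
#'
#' @param table A [feature_table()].
#' @param rows Integer row indices.
#' @return A `feature_table` containing the selected rows, in order.
#' @export
ft_rows <- function(table, rows) {
  stopifnot(inherits(table, "feature_table"))
  feature_table(
    table$features[rows, , drop = FALSE],
    table$labels[rows],
    table$feature_names
  )
}

#' Read a feature table from CSV
#'
#' Expects a header row naming the feature columns plus a final `label`
#' column. All feature cells must be numeric; `label` must be 0/1.
#'
#' @param path Path to a CSV file.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_feature_table: no such file '%s'", path))
  dt <- data.table::fread(path, header = TRUE, data.table = TRUE,
                          colClasses = NULL, showProgress = FALSE)
  if (ncol(dt) < 2L) stop("read_feature_table: need at least one feature column and a 'label' column")
  if (!("label" %in% names(dt))) {
    stop("read_feature_table: missing 'label' column in header")
  }
  if (names(dt)[ncol(dt)] != "label") {
    stop("read_feature_table: 'label' must be the final column")
  }
  feat_cols <- names(dt)[-ncol(dt)]
  if (nrow(dt) == 0L) {
    return(feature_table(matrix(numeric(0), 0L, length(feat_cols)),
                         integer(0), feat_cols))
  }
  for (j in feat_cols) {
    col <- dt[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      stop(sprintf("read_feature_table: non-numeric cell at row %d, column '%s'",
                   if (is.na(bad)) 1L else bad, j))
    }
  }
  mat <- as.matrix(dt[, feat_cols, with = FALSE])
  if (nrow(dt) == 0L) mat <- matrix(numeric(0), 0L, length(feat_cols))
  feature_table(mat, dt[["label"]], feat_cols)
}

#' Write a feature table to CSV
#'
#' Writes header `f0,...,f{d-1},label` (or the table's own feature names)
#' with full round-trip decimal precision, one row per sample.
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table$features)
  names(df) <- table$feature_names
  df$label <- table$labels
  # shortest round-trip decimal rendering: doubles re-read bit-exactly
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
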