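#' Stratified split specification
#'
#' @param train_frac,val_frac,test_frac Fractions in (0, 1) summing to 1;
#'   default 0.70 / 0.15 / 0.15.
#' @param seed Integer seed for the within-class shuffle.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_frac = 0.70, val_frac = 0.15, test_frac = 0.15,
                       seed = 0L) {
  fr <- c(train_frac, val_frac, test_frac)
  if (any(fr <= 0) || any(fr >= 1)) stop("split_spec: fractions must lie in (0, 1)")
  if (abs(sum(fr) - 1) > 1e-9) stop("split_spec: fractions must sum to 1")
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac, seed = as.integer(seed)),
            class = "split_spec")
}

#' Per-class split counts under the floor convention
#'
#' For a class of size `n`, the validation and test parts each receive
#' `floor(frac * n)` samples and the remainder goes to training.
#'
#' @param n Class size.
#' @param spec A [split_spec()].
#' @return Named integer vector `c(train, val, test)`.
#' @examples
#' split_counts(2494) # 1746, 374, 374
#' @export
split_counts <- function(n, spec = split_spec()) {
  n_val <- floor(spec$val_frac * n)
  n_test <- floor(spec$test_frac * n)
  c(train = as.integer(n - n_val - n_test),
    val = as.integer(n_val), test = as.integer(n_test))
}

#' Stratified shuffle split into train / validation / test tables
#'
#' Shuffles rows within each class with `spec$seed`, then assigns
#' `floor(val_frac * n_class)` rows to validation, `floor(test_frac *
#' n_class)` to test and the remainder to training, so the class ratio of
#' the input is preserved in all three parts. The three parts partition the
#' input rows exactly.
#'
#' @param table A [feature_table()]; every class needs >= 3 samples.
#' @param spec A [split_spec()].
#' @return A list of class `dataset_splits` with `train`, `val` and `test`
#'   feature tables, plus `indices` giving each part's original row numbers.
#' @export
stratified_split <- function(table, spec = split_spec()) {
  stopifnot(inherits(table, "feature_table"), inherits(spec, "split_spec"))
  classes <- sort(unique(table$labels))
  idx_train <- idx_val <- idx_test <- integer(0)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)
  for (cl in classes) {
    rows <- which(table$labels == cl)
    if (length(rows) < 3L) {
      stop(sprintf("stratified_split: class %d has %d samples (need >= 3)",
                   cl, length(rows)))
    }
    cnt <- split_counts(length(rows), spec)
    rows <- rows[sample.int(length(rows))]
    idx_train <- c(idx_train, rows[seq_len(cnt["train"])])
    idx_val <- c(idx_val, rows[cnt["train"] + seq_len(cnt["val"])])
    idx_test <- c(idx_test, rows[cnt["train"] + cnt["val"] + seq_len(cnt["test"])])
  }
  structure(list(
    train = ft_rows(table, idx_train),
    val = ft_rows(table, idx_val),
    test = ft_rows(table, idx_test),
    indices = list(train = idx_train, val = idx_val, test = idx_test)
  ), class = "dataset_splits")
}

#' @export
print.dataset_splits <- function(x, ...) {
  cat(sprintf("dataset_splits: train %d / val %d / test %d\n",
              nrow(x$train$features), nrow(x$val$features),
              nrow(x$test$features)))
  invisible(x)
}
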