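# Synthetic two-class embedding tables. Real inputs to the transform layer
# are pooled CNN embeddings (1280- or 1536-dimensional per image); the
# generator emulates their shape and a controllable amount of class signal so
# the whole pipeline is exercisable without images or pretrained weights.

#' Synthetic embedding-table specification
#'
#' Class-0 rows are i.i.d. Normal(0, sigma^2) per feature; class-1 rows are
#' identical except that a leading contiguous block of
#' `ceiling(shifted_fraction * dim)` features has its mean raised by
#' `mean_shift * sigma`. `mean_shift` is therefore the per-feature class
#' separation in units of sigma.
#'
#' @param n_class0,n_class1 Per-class sample counts (>= 1).
#' @param dim Feature dimension (>= 5; CNN-embedding presets are 1280 and
#'   1536).
#' @param mean_shift Class-mean gap in units of sigma (>= 0).
#' @param sigma Per-feature standard deviation (> 0).
#' @param shifted_fraction Fraction of features carrying the class signal,
#'   in (0, 1\].
#' @param relu_clip If `TRUE`, map all features through `max(0, .)` to mimic
#'   the non-negativity of ReLU-pooled embeddings.
#' @param seed Integer seed.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_class0 = 1000L, n_class1 = 1000L, dim = 32L,
                       mean_shift = 1, sigma = 1, shifted_fraction = 0.5,
                       relu_clip = FALSE, seed = 0L) {
  stopifnot(n_class0 >= 1L, n_class1 >= 1L, mean_shift >= 0, sigma > 0,
            shifted_fraction > 0, shifted_fraction <= 1)
  dim <- as.integer(dim)
  if (dim < 5L) stop("synth_spec: dim must be >= 5 (swarm transform minimum)")
  structure(list(n_class0 = as.integer(n_class0),
                 n_class1 = as.integer(n_class1), dim = dim,
                 mean_shift = mean_shift, sigma = sigma,
                 shifted_fraction = shifted_fraction,
                 relu_clip = isTRUE(relu_clip), seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic two-class feature table
#'
#' @param spec A [synth_spec()].
#' @return A [feature_table()] with `n_class0` label-0 rows followed by
#'   `n_class1` label-1 rows; deterministic under `spec$seed`.
#' @examples
#' ft <- generate_two_class_features(synth_spec(n_class0 = 10, n_class1 = 10,
#'                                              dim = 8, seed = 1))
#' dim(ft)
#' @export
generate_two_class_features <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)
  n <- spec$n_class0 + spec$n_class1
  x <- matrix(stats::rnorm(n * spec$dim, 0, spec$sigma), n, spec$dim)
  n_shift <- ceiling(spec$shifted_fraction * spec$dim)
  if (spec$n_class1 > 0L && n_shift >= 1L) {
    rows1 <- spec$n_class0 + seq_len(spec$n_class1)
    x[rows1, seq_len(n_shift)] <- x[rows1, seq_len(n_shift)] +
      spec$mean_shift * spec$sigma
  }
  if (spec$relu_clip) x <- pmax(x, 0)
  feature_table(x, c(rep(0L, spec$n_class0), rep(1L, spec$n_class1)))
}

# Per-class totals of the three benchmark image datasets.
dataset_class_counts <- function(dataset_id) {
  switch(as.character(dataset_id),
    "1" = c(n_class0 = 2494L, n_class1 = 2698L),
    "2" = c(n_class0 = 89L, n_class1 = 439L),
    "3" = c(n_class0 = 201L, n_class1 = 495L),
    stop("dataset_id must be 1, 2 or 3")
  )
}

#' Generate a fixture at a benchmark dataset's class counts
#'
#' Emulates the three histopathology benchmark datasets at their published
#' per-class totals (dataset 1: 2494 normal / 2698 positive; dataset 2:
#' 89 / 439; dataset 3: 201 / 495) via [generate_two_class_features()].
#'
#' @param dataset_id 1, 2 or 3.
#' @param dim Feature dimension (default 1280, the MobileNetV3 embedding
#'   width; 1536 matches the other two extractor presets).
#' @param ... Overrides passed to [synth_spec()] (e.g. `mean_shift`, `seed`).
#' @return A [feature_table()].
#' @export
generate_paper_scale_fixture <- function(dataset_id, dim = 1280L, ...) {
  cnt <- dataset_class_counts(dataset_id)
  spec <- synth_spec(n_class0 = cnt[["n_class0"]], n_class1 = cnt[["n_class1"]],
                     dim = dim, ...)
  generate_two_class_features(spec)
}
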