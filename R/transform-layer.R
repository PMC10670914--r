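#' Transform-layer parameters
#'
#' Pairs an algorithm choice with its parameter record and a global seed.
#' The per-row random streams of [transform_table()] are derived from
#' `(seed, row index)`, so transforming a subset of rows reproduces the
#' corresponding rows of a full-table transform.
#'
#' @param algorithm One of `"mgto"`, `"gto"`, `"pso"`, `"eho"`.
#' @param params Matching parameter record; defaults to the algorithm's
#'   defaults.
#' @param seed Integer global seed.
#' @return An object of class `layer_params`.
#' @export
layer_params <- function(algorithm = c("mgto", "gto", "pso", "eho"),
                         params = NULL, seed = 0L) {
  algorithm <- match.arg(algorithm)
  if (is.null(params)) params <- default_params_for(algorithm)
  expected <- switch(algorithm, gto = "mgto_params", mgto = "mgto_params",
                     pso = "pso_params", eho = "eho_params")
  if (!inherits(params, expected)) {
    stop(sprintf("layer_params: algorithm '%s' needs %s", algorithm, expected))
  }
  structure(list(algorithm = algorithm, params = params,
                 seed = as.integer(seed)),
            class = "layer_params")
}

# Deterministic per-sample seed below 2^31, a Lehmer-style mix of the global
# seed and the row index.
per_sample_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 30269 + 11) %% 2147483647)
}

#' Transform a feature table row-by-row
#'
#' Applies [run_swarm_transform()] to every row independently. Each row's
#' random stream is seeded from `(layer$seed, row index)`, so the transform
#' of any subset of rows equals the corresponding rows of the full-table
#' transform. Labels, shape and column order are unchanged, and every
#' transformed value stays within its input row's \[min, max\] range.
#'
#' @param table A [feature_table()] with >= 5 feature columns.
#' @param layer A [layer_params()].
#' @param row_ids Optional original row indices of `table`'s rows (defaults
#'   to `1:n`); pass these when transforming a subset so its per-row streams
#'   match the full table's.
#' @return A transformed [feature_table()] of identical shape.
#' @export
transform_table <- function(table, layer, row_ids = NULL) {
  stopifnot(inherits(table, "feature_table"), inherits(layer, "layer_params"))
  n <- nrow(table$features)
  if (ncol(table$features) < 5L) {
    stop("transform_table: need at least 5 feature columns")
  }
  if (is.null(row_ids)) row_ids <- seq_len(n)
  if (length(row_ids) != n) stop("transform_table: row_ids length mismatch")
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  out <- table$features
  for (i in seq_len(n)) {
    set.seed(per_sample_seed(layer$seed, row_ids[i]))
    out[i, ] <- run_swarm_transform(table$features[i, ], layer$algorithm,
                                    layer$params)
  }
  feature_table(out, table$labels, table$feature_names)
}

#' Hyperparameter grid specification
#'
#' Axes for the two-stage search of [fit_layer()]: stage 1 sweeps
#' `max_iter_values` with all other parameters held at 0.5; stage 2 sweeps
#' the Cartesian product of `axes` at the stage-1 winner. `axes` is a named
#' list of numeric vectors using the algorithm's own parameter names
#' (`p`, `beta` for the troop optimizers; `w`, `c1`, `c2` for particle
#' swarm; `alpha`, `beta_e` for elephant herding).
#'
#' @param max_iter_values Non-empty vector of positive integers.
#' @param axes Named list of non-empty numeric vectors.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(max_iter_values = 1:20,
                      axes = list(p = seq(0, 1, 0.1),
                                  beta = seq(0, 1, 0.1))) {
  if (length(max_iter_values) == 0L) stop("grid_spec: empty max_iter_values")
  if (any(max_iter_values < 1L)) stop("grid_spec: max_iter_values must be >= 1")
  if (length(axes) == 0L || is.null(names(axes)) || any(names(axes) == "")) {
    stop("grid_spec: axes must be a non-empty named list")
  }
  if (any(vapply(axes, length, 0L) == 0L)) stop("grid_spec: empty axis")
  # ascending order makes which.max's first-hit tie-break pick the smallest
  # max_iter, then the smallest value on each axis in turn
  structure(list(max_iter_values = sort(unique(as.integer(max_iter_values))),
                 axes = lapply(axes, function(a) sort(unique(a)))),
            class = "grid_spec")
}

default_grid_for <- function(algorithm) {
  switch(algorithm,
    gto = grid_spec(),
    mgto = grid_spec(),
    pso = grid_spec(axes = list(w = seq(0, 1, 0.1), c1 = seq(0, 1, 0.1),
                                c2 = seq(0, 1, 0.1))),
    eho = grid_spec(axes = list(alpha = seq(0, 1, 0.1),
                                beta_e = seq(0, 1, 0.1)))
  )
}

# Build the algorithm's parameter record from a named value list, all
# unspecified tunables at 0.5.
params_from_values <- function(algorithm, max_iter, values = list()) {
  at <- function(nm) if (!is.null(values[[nm]])) values[[nm]] else 0.5
  switch(algorithm,
    gto = ,
    mgto = mgto_params(p = at("p"), beta = at("beta"), max_iter = max_iter),
    pso = pso_params(w = at("w"), c1 = at("c1"), c2 = at("c2"),
                     max_iter = max_iter),
    eho = eho_params(alpha = at("alpha"), beta_e = at("beta_e"),
                     max_iter = max_iter)
  )
}

# One grid-point evaluation: transform train and val with the candidate
# layer, retrain the head from scratch at the shared head seed, and score
# validation accuracy.
eval_grid_point <- function(train, val, head_cfg, algorithm, max_iter, values,
                            seed) {
  lp <- layer_params(algorithm,
                     params_from_values(algorithm, max_iter, values),
                     seed = seed)
  tr <- transform_table(train, lp)
  va <- transform_table(val, lp, row_ids = nrow(train$features) +
                          seq_len(nrow(val$features)))
  head <- train_head(tr, va, head_cfg)
  pred <- predict(head, va)
  mean(pred$labels == va$labels)
}

#' Fit the transform layer by two-stage grid search
#'
#' Stage 1 sweeps `max_iter` with every other tunable held at 0.5 (the
#' midpoint of their \[0, 1\] range) and keeps the value with the highest
#' validation accuracy. Stage 2 fixes that `max_iter` and sweeps the
#' Cartesian product of the remaining axes. At every grid point the train
#' and validation tables are transformed with the candidate layer and the
#' classifier head is retrained from scratch at the same head seed, so
#' surface differences reflect only the transform. Ties break toward the
#' smaller `max_iter`, then the smaller value on each axis in order.
#'
#' @param train,val [feature_table()]s of identical dimensionality.
#' @param head_config A [head_config()].
#' @param grid A [grid_spec()]; defaults to the algorithm's standard grid.
#' @param algorithm One of `"mgto"`, `"gto"`, `"pso"`, `"eho"`.
#' @param seed Global layer seed (also used for per-sample transform
#'   streams).
#' @return An object of class `fit_result` with `best_params` (a
#'   [layer_params()]), `best_validation_accuracy` and `accuracy_surface`
#'   (a data.frame with one row per evaluated grid point, including a
#'   `stage` column).
#' @export
fit_layer <- function(train, val, head_config = head_config(), grid = NULL,
                      algorithm = c("mgto", "gto", "pso", "eho"), seed = 0L) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(train, "feature_table"), inherits(val, "feature_table"))
  if (ncol(train$features) != ncol(val$features)) {
    stop("fit_layer: train/val dimensionality mismatch")
  }
  if (is.null(grid)) grid <- default_grid_for(algorithm)
  stopifnot(inherits(grid, "grid_spec"))
  seed <- as.integer(seed)
  axis_names <- names(grid$axes)

  # Stage 1: max_iter sweep, other tunables at 0.5
  s1 <- data.frame(stage = 1L, max_iter = grid$max_iter_values)
  for (nm in axis_names) s1[[nm]] <- 0.5
  s1$val_accuracy <- vapply(grid$max_iter_values, function(mi) {
    eval_grid_point(train, val, head_config, algorithm, mi, list(), seed)
  }, 0)
  best_mi <- grid$max_iter_values[which.max(s1$val_accuracy)]

  # Stage 2: remaining axes at the fixed ideal max_iter
  combos <- expand.grid(rev(grid$axes), KEEP.OUT.ATTRS = FALSE)
  combos <- combos[, rev(seq_along(combos)), drop = FALSE]
  s2 <- data.frame(stage = 2L, max_iter = best_mi)
  s2 <- cbind(s2, combos)
  s2$val_accuracy <- vapply(seq_len(nrow(combos)), function(k) {
    eval_grid_point(train, val, head_config, algorithm, best_mi,
                    as.list(combos[k, , drop = FALSE]), seed)
  }, 0)
  best_k <- which.max(s2$val_accuracy)
  best_values <- as.list(combos[best_k, , drop = FALSE])

  best_params <- layer_params(
    algorithm, params_from_values(algorithm, best_mi, best_values), seed = seed
  )
  structure(list(
    best_params = best_params,
    best_validation_accuracy = s2$val_accuracy[best_k],
    accuracy_surface = rbind(s1, s2)
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  bp <- x$best_params
  tun <- bp$params[setdiff(names(bp$params),
                           c("max_iter", "const", "g_mode", "l_mode"))]
  cat(sprintf("fit_result: %s, max_iter=%d, %s -> validation accuracy %.4f\n",
              bp$algorithm, bp$params$max_iter,
              paste(sprintf("%s=%g", names(tun), unlist(tun)), collapse = ", "),
              x$best_validation_accuracy))
  invisible(x)
}

#' Serialize a fitted layer to JSON
#'
#' @param fit A [fit_layer()] result.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
layer_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  bp <- fit$best_params
  doc <- list(
    algorithm = bp$algorithm,
    params = unclass(bp$params),
    seed = bp$seed,
    best_validation_accuracy = fit$best_validation_accuracy,
    accuracy_surface = fit$accuracy_surface
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' Deserialize a fitted layer from JSON
#'
#' @param path Path to a [layer_to_json()] document (or the JSON string
#'   itself).
#' @return A `fit_result` equivalent to the serialized one.
#' @export
layer_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  pr <- doc$params
  params <- switch(doc$algorithm,
    gto = ,
    mgto = mgto_params(p = pr$p, beta = pr$beta, max_iter = pr$max_iter,
                       const = pr$const, g_mode = pr$g_mode,
                       l_mode = pr$l_mode),
    pso = pso_params(w = pr$w, c1 = pr$c1, c2 = pr$c2,
                     max_iter = pr$max_iter),
    eho = eho_params(alpha = pr$alpha, beta_e = pr$beta_e,
                     max_iter = pr$max_iter)
  )
  surf <- as.data.frame(doc$accuracy_surface)
  structure(list(
    best_params = layer_params(doc$algorithm, params, seed = doc$seed),
    best_validation_accuracy = doc$best_validation_accuracy,
    accuracy_surface = surf
  ), class = "fit_result")
}
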