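# End-to-end pipeline: split -> (optional) layer fit -> transform all three
# splits -> train head -> evaluate on test, with a no-layer baseline under
# the same seeds for the percentage-accuracy-increase statistic.

sl_log <- function(level, fmt, ...) {
  levels <- c(DEBUG = 1L, INFO = 2L, WARN = 3L)
  thr <- getOption("swarmlayer.log_level", "INFO")
  if (levels[[level]] >= levels[[thr]]) {
    message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    level, sprintf(fmt, ...)))
  }
  invisible(NULL)
}

# Transform the three splits with one fitted layer. Row streams are indexed
# train, then val, then test, so a pipeline run is reproducible from the
# split tables alone.
transform_splits <- function(splits, layer) {
  n_tr <- nrow(splits$train$features)
  n_va <- nrow(splits$val$features)
  n_te <- nrow(splits$test$features)
  list(
    train = transform_table(splits$train, layer),
    val = transform_table(splits$val, layer, row_ids = n_tr + seq_len(n_va)),
    test = transform_table(splits$test, layer,
                           row_ids = n_tr + n_va + seq_len(n_te))
  )
}

metrics_as_list <- function(m) {
  list(tp = m$tp, fp = m$fp, fn = m$fn, tn = m$tn, accuracy = m$accuracy,
       precision = m$precision, recall = m$recall, f1 = m$f1,
       degenerate = m$degenerate)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full evaluation pipeline
#'
#' Splits a feature table 70:15:15 (stratified), optionally fits and applies
#' a swarm transform layer to all three splits, trains the classifier head
#' on the (transformed) train/validation tables, predicts the test table and
#' reports confusion-matrix metrics. A no-layer baseline is always trained
#' under the same head seed, and the report carries the percentage accuracy
#' increase of the layered model over that baseline.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{input}{path to a feature-table CSV, or}
#'     \item{synth}{a list of [synth_spec()] arguments generating the input;}
#'     \item{algorithm}{`"none"`, `"mgto"`, `"gto"`, `"pso"` or `"eho"`;}
#'     \item{layer}{named list of layer parameter values (e.g. `max_iter`,
#'       `p`, `beta`), used directly when present;}
#'     \item{fit}{a list of [grid_spec()] arguments — when present (and
#'       `layer` absent) the layer is fitted by [fit_layer()];}
#'     \item{split}{[split_spec()] argument overrides;}
#'     \item{head}{[head_config()] argument overrides;}
#'     \item{seed}{master seed, defaulted into the split, head and layer
#'       seeds when those are not given.}
#'   }
#' @return A report list (class `pipeline_report`) with the split counts,
#'   the layer used, baseline and layered metrics, and
#'   `pct_accuracy_increase`; serialize with [report_to_json()].
#' @export
run_pipeline <- function(config) {
  seed <- as.integer(config$seed %||% 0L)
  algorithm <- config$algorithm %||% "none"

  tab <- run_stage("input", {
    if (!is.null(config$input)) {
      read_feature_table(config$input)
    } else if (!is.null(config$synth)) {
      sa <- config$synth
      if (is.null(sa$seed)) sa$seed <- seed
      generate_two_class_features(do.call(synth_spec, sa))
    } else {
      stop("config needs either 'input' or 'synth'")
    }
  })
  sl_log("INFO", "input: %d samples x %d features", nrow(tab$features),
         ncol(tab$features))

  sp_args <- config$split %||% list()
  if (is.null(sp_args$seed)) sp_args$seed <- seed
  splits <- run_stage("split", stratified_split(tab, do.call(split_spec, sp_args)))
  sl_log("INFO", "split (seed %d): train %d / val %d / test %d", sp_args$seed,
         nrow(splits$train$features), nrow(splits$val$features),
         nrow(splits$test$features))

  hd_args <- config$head %||% list()
  if (is.null(hd_args$seed)) hd_args$seed <- seed
  head_cfg <- run_stage("head-config", do.call(head_config, hd_args))

  baseline <- run_stage("baseline-head", {
    head <- train_head(splits$train, splits$val, head_cfg)
    pred <- predict(head, splits$test)
    confusion_and_metrics(splits$test$labels, pred$labels)
  })
  sl_log("INFO", "baseline test accuracy: %.4f", baseline$accuracy)

  layer_used <- NULL
  fit <- NULL
  layered <- NULL
  if (!identical(algorithm, "none")) {
    layer_used <- run_stage("fit-layer", {
      if (!is.null(config$layer)) {
        lv <- config$layer
        mi <- lv$max_iter %||% default_params_for(algorithm)$max_iter
        layer_params(algorithm, params_from_values(algorithm, mi, lv),
                     seed = as.integer(lv$seed %||% seed))
      } else if (!is.null(config$fit)) {
        grid <- do.call(grid_spec, config$fit)
        fit <<- fit_layer(splits$train, splits$val, head_cfg, grid,
                          algorithm, seed = seed)
        fit$best_params
      } else {
        layer_params(algorithm, seed = seed)
      }
    })
    layered <- run_stage("transform+head", {
      tx <- transform_splits(splits, layer_used)
      head <- train_head(tx$train, tx$val, head_cfg)
      pred <- predict(head, tx$test)
      confusion_and_metrics(tx$test$labels, pred$labels)
    })
    sl_log("INFO", "%s-layer test accuracy: %.4f", algorithm, layered$accuracy)
  }

  pct <- if (is.null(layered)) 0 else {
    pct_accuracy_increase(baseline$accuracy, layered$accuracy)
  }
  report <- list(
    algorithm = algorithm,
    seed = seed,
    n_samples = nrow(tab$features),
    n_features = ncol(tab$features),
    split_counts = list(train = nrow(splits$train$features),
                        val = nrow(splits$val$features),
                        test = nrow(splits$test$features)),
    layer = if (is.null(layer_used)) NULL else {
      list(algorithm = layer_used$algorithm,
           params = unclass(layer_used$params), seed = layer_used$seed)
    },
    fit = if (is.null(fit)) NULL else {
      list(best_validation_accuracy = fit$best_validation_accuracy,
           accuracy_surface = fit$accuracy_surface)
    },
    metrics_baseline = metrics_as_list(baseline),
    metrics_layer = if (is.null(layered)) NULL else metrics_as_list(layered),
    pct_accuracy_increase = pct
  )
  class(report) <- "pipeline_report"
  report
}

#' Serialize a pipeline report to JSON
#'
#' @param report A [run_pipeline()] report.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report (%s): baseline accuracy %.4f",
              x$algorithm, x$metrics_baseline$accuracy))
  if (!is.null(x$metrics_layer)) {
    cat(sprintf(", with layer %.4f (%+.2f%%)",
                x$metrics_layer$accuracy, x$pct_accuracy_increase))
  }
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
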