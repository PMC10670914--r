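#' Confusion matrix and classification scores
#'
#' Counts the two-class confusion matrix with label 1 as the positive class
#' and derives accuracy, precision, recall and F1. Precision and recall are
#' defined as 0 when their denominator is 0 (flagged in `degenerate`); the
#' raw values are kept at full precision, with rounding left to
#' [render_metrics_row()].
#'
#' @param y_true,y_pred Equal-length 0/1 label vectors (length >= 1).
#' @return A list of class `swarm_metrics` with `tp, fp, fn, tn`, the four
#'   scores, and a `degenerate` flag.
#' @examples
#' confusion_and_metrics(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_and_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("confusion_and_metrics: y_true and y_pred lengths differ")
  }
  if (length(y_true) < 1L) stop("confusion_and_metrics: empty label vectors")
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) {
    stop("confusion_and_metrics: labels must be 0 or 1")
  }
  tp <- sum(y_true == 1L & y_pred == 1L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  tn <- sum(y_true == 0L & y_pred == 0L)
  degenerate <- FALSE
  precision <- if (tp + fp == 0L) { degenerate <- TRUE; 0 } else tp / (tp + fp)
  recall <- if (tp + fn == 0L) { degenerate <- TRUE; 0 } else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = (tp + tn) / (tp + fp + fn + tn),
                 precision = precision, recall = recall, f1 = f1,
                 degenerate = degenerate),
            class = "swarm_metrics")
}

#' F1 score from precision and recall
#'
#' Harmonic mean of precision and recall; 0 when both are 0.
#'
#' @param precision,recall Reals in \[0, 1\].
#' @return The F1 score.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Percentage accuracy increase
#'
#' `100 * (acc_with - acc_without) / acc_without`; negative when the layer
#' hurts.
#'
#' @param acc_without Baseline accuracy (> 0).
#' @param acc_with Accuracy with the transform layer.
#' @return The percent increase.
#' @examples
#' pct_accuracy_increase(0.52, 0.90) # ~73
#' @export
pct_accuracy_increase <- function(acc_without, acc_with) {
  if (acc_without == 0) stop("pct_accuracy_increase: baseline accuracy is zero")
  100 * (acc_with - acc_without) / acc_without
}

#' Scatter-plot feature averages
#'
#' Splits a feature vector in half and returns the mean of each half
#' (`Average1`, `Average2`), the two coordinates used to scatter-plot
#' high-dimensional embeddings. Odd lengths assign the middle element to the
#' first half.
#'
#' @param features Numeric vector of length >= 2.
#' @return Named numeric vector `c(average1, average2)`.
#' @examples
#' scatter_averages(c(1, 2, 3, 4)) # 1.5, 3.5
#' @export
scatter_averages <- function(features) {
  d <- length(features)
  if (d < 2L) stop("scatter_averages: need at least 2 features")
  k <- ceiling(d / 2)
  c(average1 = mean(features[1:k]), average2 = mean(features[(k + 1L):d]))
}

#' Render one metrics row in report layout
#'
#' Two-decimal rendering used by the text report tables; raw values stay at
#' full precision inside the `swarm_metrics` object.
#'
#' @param metrics A [confusion_and_metrics()] result.
#' @param model,layer Row annotations (feature extractor, transform layer).
#' @return A single formatted line.
#' @export
render_metrics_row <- function(metrics, model = "features", layer = "none") {
  sprintf("%-16s %-8s %5.2f %5.2f %5.2f %5.2f%s",
          model, layer, metrics$accuracy, metrics$precision, metrics$recall,
          metrics$f1, if (isTRUE(metrics$degenerate)) "  [degenerate]" else "")
}

#' @export
print.swarm_metrics <- function(x, ...) {
  cat(sprintf("confusion: tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("accuracy=%.4f precision=%.4f recall=%.4f f1=%.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}
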