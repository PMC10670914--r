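# Small dense classifier head, implemented directly in base-R matrix code:
# batch normalization -> 256-unit ReLU dense with L2 kernel / L1 activity /
# L1 bias penalties -> dropout -> 2-unit softmax, trained with Adamax on
# sparse categorical cross-entropy, early stopping on validation loss and
# learning-rate reduction on plateau.

#' Classifier-head configuration
#'
#' Defaults follow the reference architecture: batch normalization
#' (momentum 0.99, epsilon 0.001), a 256-unit ReLU dense layer with an L2
#' kernel penalty (0.016) and L1 activity/bias penalties (0.006), dropout
#' 0.45, and a 2-unit softmax output, trained with Adamax (learning rate
#' 0.001) on sparse categorical cross-entropy for up to 100 epochs at batch
#' size 128, with early stopping on validation loss (patience 5, best weights
#' restored) and learning-rate reduction on plateau (factor 0.2, patience 4).
#'
#' @param bn_momentum,bn_epsilon Batch-normalization running-average momentum
#'   and variance floor.
#' @param dense_units Width of the hidden ReLU layer.
#' @param kernel_l2,activity_l1,bias_l1 Penalty coefficients of the hidden
#'   layer.
#' @param dropout_rate Dropout probability on the hidden activations.
#' @param epochs,batch_size,learning_rate Training protocol.
#' @param early_stop_patience,early_stop_min_delta Early stopping on
#'   validation loss; the best epoch's weights are restored.
#' @param lr_reduce_factor,lr_reduce_patience Learning-rate reduction on a
#'   validation-loss plateau.
#' @param seed Integer seed controlling initialization, epoch shuffling and
#'   dropout masks.
#' @return An object of class `head_config`.
#' @export
head_config <- function(bn_momentum = 0.99, bn_epsilon = 0.001,
                        dense_units = 256L, kernel_l2 = 0.016,
                        activity_l1 = 0.006, bias_l1 = 0.006,
                        dropout_rate = 0.45, epochs = 100L, batch_size = 128L,
                        learning_rate = 0.001, early_stop_patience = 5L,
                        early_stop_min_delta = 0,
                        lr_reduce_factor = 0.2, lr_reduce_patience = 4L,
                        seed = 0L) {
  stopifnot(dropout_rate > 0, dropout_rate < 1,
            early_stop_patience >= 1L, lr_reduce_patience >= 1L,
            epochs >= 1L, batch_size >= 1L, dense_units >= 1L)
  structure(list(
    bn_momentum = bn_momentum, bn_epsilon = bn_epsilon,
    dense_units = as.integer(dense_units), kernel_l2 = kernel_l2,
    activity_l1 = activity_l1, bias_l1 = bias_l1,
    dropout_rate = dropout_rate, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), learning_rate = learning_rate,
    early_stop_patience = as.integer(early_stop_patience),
    early_stop_min_delta = early_stop_min_delta,
    lr_reduce_factor = lr_reduce_factor,
    lr_reduce_patience = as.integer(lr_reduce_patience),
    seed = as.integer(seed)
  ), class = "head_config")
}

# Glorot-uniform initial weights, keras-style.
glorot_uniform <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

head_init_weights <- function(d, config) {
  u <- config$dense_units
  list(
    gamma = rep(1, d), beta_bn = rep(0, d),
    running_mean = rep(0, d), running_var = rep(1, d),
    W1 = glorot_uniform(d, u), b1 = rep(0, u),
    W2 = glorot_uniform(u, 2L), b2 = rep(0, 2L)
  )
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass. In training mode batch statistics drive the normalization and
# a dropout mask is drawn; in inference mode the running statistics are used
# and dropout is disabled.
head_forward <- function(w, x, config, training = FALSE) {
  b <- nrow(x)
  if (training) {
    mu <- colMeans(x)
    va <- colMeans(x^2) - mu^2
  } else {
    mu <- w$running_mean
    va <- w$running_var
  }
  inv_sd <- 1 / sqrt(va + config$bn_epsilon)
  xhat <- sweep(sweep(x, 2L, mu), 2L, inv_sd, `*`)
  bn <- sweep(sweep(xhat, 2L, w$gamma, `*`), 2L, w$beta_bn, `+`)
  z1 <- sweep(bn %*% w$W1, 2L, w$b1, `+`)
  a1 <- pmax(z1, 0)
  if (training) {
    keep <- matrix(stats::runif(b * config$dense_units) >= config$dropout_rate,
                   b, config$dense_units)
    drop_scale <- 1 / (1 - config$dropout_rate)
    d1 <- a1 * keep * drop_scale
  } else {
    keep <- NULL
    d1 <- a1
  }
  logits <- sweep(d1 %*% w$W2, 2L, w$b2, `+`)
  probs <- softmax_rows(logits)
  list(mu = mu, va = va, inv_sd = inv_sd, xhat = xhat, bn = bn, z1 = z1,
       a1 = a1, keep = keep, d1 = d1, probs = probs)
}

# Regularisation penalty: keras-style sums for kernel L2 and bias L1; the
# activity L1 term is averaged over the batch so the penalty is batch-size
# invariant.
head_reg_penalty <- function(w, a1, config) {
  config$kernel_l2 * sum(w$W1^2) + config$bias_l1 * sum(abs(w$b1)) +
    config$activity_l1 * sum(abs(a1)) / nrow(a1)
}

head_loss <- function(w, x, y, config) {
  fw <- head_forward(w, x, config, training = FALSE)
  p <- fw$probs[cbind(seq_along(y), y + 1L)]
  ce <- -mean(log(pmax(p, 1e-12)))
  list(loss = ce + head_reg_penalty(w, fw$a1, config),
       accuracy = mean(max.col(fw$probs) - 1L == y))
}

#' Train the classifier head
#'
#' Trains the batch-norm / dense / dropout / softmax head on a training
#' table, monitoring a validation table for early stopping and learning-rate
#' reduction. Fully deterministic under `config$seed`.
#'
#' @param train,val [feature_table()]s with identical feature dimensionality
#'   and labels in \{0, 1\}; `train` must contain both classes.
#' @param config A [head_config()].
#' @return An object of class `trained_head` with elements `weights`,
#'   `config` and `training_log` (a data.frame of per-epoch train/validation
#'   loss and accuracy plus the learning rate). The stored weights are those
#'   of the best validation-loss epoch.
#' @export
train_head <- function(train, val, config = head_config()) {
  stopifnot(inherits(train, "feature_table"), inherits(val, "feature_table"),
            inherits(config, "head_config"))
  if (nrow(train$features) == 0L || nrow(val$features) == 0L) {
    stop("train_head: empty training or validation table")
  }
  if (ncol(train$features) != ncol(val$features)) {
    stop("train_head: train/val feature dimensionality mismatch")
  }
  if (length(unique(train$labels)) < 2L) {
    stop("train_head: training set contains a single class")
  }
  x <- train$features
  y <- train$labels
  n <- nrow(x)
  d <- ncol(x)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  w <- head_init_weights(d, config)
  # Adamax state (keras defaults beta1 = 0.9, beta2 = 0.999, eps = 1e-7)
  beta1 <- 0.9
  beta2 <- 0.999
  adamax_eps <- 1e-7
  names_upd <- c("gamma", "beta_bn", "W1", "b1", "W2", "b2")
  m <- lapply(w[names_upd], function(p) p * 0)
  u <- lapply(w[names_upd], function(p) p * 0)
  step <- 0L
  lr <- config$learning_rate

  log_rows <- vector("list", config$epochs)
  best_val <- Inf
  best_w <- w
  es_wait <- 0L
  lr_wait <- 0L
  n_batches <- ceiling(n / config$batch_size)

  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    for (bi in seq_len(n_batches)) {
      idx <- perm[((bi - 1L) * config$batch_size + 1L):min(bi * config$batch_size, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      bsz <- length(idx)
      fw <- head_forward(w, xb, config, training = TRUE)

      # running statistics, keras convention
      w$running_mean <- config$bn_momentum * w$running_mean +
        (1 - config$bn_momentum) * fw$mu
      w$running_var <- config$bn_momentum * w$running_var +
        (1 - config$bn_momentum) * fw$va

      onehot <- matrix(0, bsz, 2L)
      onehot[cbind(seq_len(bsz), yb + 1L)] <- 1
      dlogits <- (fw$probs - onehot) / bsz
      gW2 <- crossprod(fw$d1, dlogits)
      gb2 <- colSums(dlogits)
      dd1 <- dlogits %*% t(w$W2)
      da1 <- dd1
      if (!is.null(fw$keep)) {
        da1 <- da1 * fw$keep / (1 - config$dropout_rate)
      }
      da1 <- da1 + config$activity_l1 * sign(fw$a1) / bsz
      dz1 <- da1 * (fw$z1 > 0)
      gW1 <- crossprod(fw$bn, dz1) + 2 * config$kernel_l2 * w$W1
      gb1 <- colSums(dz1) + config$bias_l1 * sign(w$b1)
      dbn <- dz1 %*% t(w$W1)
      ggamma <- colSums(dbn * fw$xhat)
      gbeta <- colSums(dbn)

      grads <- list(gamma = ggamma, beta_bn = gbeta,
                    W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
      step <- step + 1L
      corr <- lr / (1 - beta1^step)
      for (nm in names_upd) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grads[[nm]]
        u[[nm]] <- pmax(beta2 * u[[nm]], abs(grads[[nm]]))
        w[[nm]] <- w[[nm]] - corr * m[[nm]] / (u[[nm]] + adamax_eps)
      }
    }

    tr_eval <- head_loss(w, x, y, config)
    va_eval <- head_loss(w, val$features, val$labels, config)
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, lr = lr,
      train_loss = tr_eval$loss, train_accuracy = tr_eval$accuracy,
      val_loss = va_eval$loss, val_accuracy = va_eval$accuracy
    )

    if (va_eval$loss < best_val - config$early_stop_min_delta) {
      best_val <- va_eval$loss
      best_w <- w
      es_wait <- 0L
      lr_wait <- 0L
    } else {
      es_wait <- es_wait + 1L
      lr_wait <- lr_wait + 1L
      if (lr_wait >= config$lr_reduce_patience) {
        lr <- lr * config$lr_reduce_factor
        lr_wait <- 0L
      }
      if (es_wait >= config$early_stop_patience) break
    }
  }

  structure(list(
    weights = best_w, config = config,
    training_log = do.call(rbind, log_rows[!vapply(log_rows, is.null, TRUE)])
  ), class = "trained_head")
}

#' Predict labels and class-1 probabilities
#'
#' @param object A [train_head()] result.
#' @param table A [feature_table()] with the training dimensionality.
#' @param ... Unused.
#' @return A list with `labels` (0/1 integer vector) and `prob1` (class-1
#'   probability per row); `probs` holds the full two-column matrix.
#' @export
predict.trained_head <- function(object, table, ...) {
  stopifnot(inherits(table, "feature_table"))
  d_trained <- length(object$weights$gamma)
  if (ncol(table$features) != d_trained) {
    stop(sprintf("predict: table has %d features, head was trained on %d",
                 ncol(table$features), d_trained))
  }
  if (nrow(table$features) == 0L) {
    return(list(labels = integer(0), prob1 = numeric(0),
                probs = matrix(numeric(0), 0L, 2L)))
  }
  fw <- head_forward(object$weights, table$features, object$config,
                     training = FALSE)
  list(labels = max.col(fw$probs, ties.method = "first") - 1L,
       prob1 = fw$probs[, 2L], probs = fw$probs)
}

#' @export
print.trained_head <- function(x, ...) {
  lg <- x$training_log
  cat(sprintf(
    "trained_head: %d features -> %d units -> 2 classes; %d epochs, best val loss %.4f\n",
    length(x$weights$gamma), x$config$dense_units, nrow(lg), min(lg$val_loss)
  ))
  invisible(x)
}
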