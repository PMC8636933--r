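# The meta-classifier: a three-layer neural network that maps a compound's
# model-level representation (the probability vector emitted by the
# selected base classifiers) to a carcinogenicity probability. The network
# is deliberately tiny -- one hidden layer of 10 rectified units with batch
# normalization and dropout 0.5, a sigmoid output, binary cross-entropy
# loss and plain stochastic gradient descent with momentum -- and is
# implemented directly in R with explicit forward/backward passes.

#' Meta-network configuration
#'
#' @param input_dim Number of selected base classifiers feeding the network.
#' @param hidden_units Hidden-layer width (default 10).
#' @param dropout_rate Dropout probability applied after the hidden
#'   activation during training (default 0.5); inference never drops.
#' @param learning_rate,momentum SGD settings (defaults 0.01 / 0.9).
#' @param epochs Maximum training epochs (default 200).
#' @param batch_size Minibatch size (default 32).
#' @param patience Early-stopping patience, in epochs without improvement
#'   of the monitored loss (default 20).
#' @param seed Integer seed for weight initialization, shuffling and
#'   dropout masks.
#' @return A list of class `MetaNetworkConfig`.
#' @export
meta_config <- function(input_dim, hidden_units = 10L, dropout_rate = 0.5,
                        learning_rate = 0.01, momentum = 0.9, epochs = 200L,
                        batch_size = 32L, patience = 20L, seed = 1L) {
  stopifnot(input_dim >= 1L, hidden_units >= 1L,
            dropout_rate >= 0, dropout_rate < 1, epochs >= 1L)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_units = as.integer(hidden_units),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 momentum = momentum, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "MetaNetworkConfig")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

meta_forward_infer <- function(w, x) {
  z1 <- sweep(x %*% w$W1, 2L, w$b1, "+")
  xhat <- sweep(sweep(z1, 2L, w$run_mean, "-"), 2L,
                sqrt(w$run_var + w$eps), "/")
  a <- sweep(sweep(xhat, 2L, w$gamma, "*"), 2L, w$beta, "+")
  h <- pmax(a, 0)
  as.numeric(sigmoid(h %*% w$W2 + w$b2))
}

#' Train the meta-classifier
#'
#' Fits the network on a model-level representation (conventionally the
#' development set's, with the development labels). Training is fully
#' deterministic given `config$seed`. Batch normalization uses batch
#' statistics during training and exponentially-averaged running statistics
#' at inference; dropout is inverted (activations rescaled at train time)
#' and inactive at inference. Early stopping monitors the full-data
#' cross-entropy in inference mode and restores the best weights.
#'
#' @param config A [meta_config()]; its `input_dim` must equal the number
#'   of columns of `mlr`.
#' @param mlr A `ModelLevelRepresentation` (or plain probability matrix).
#' @param labels Binary 0/1 labels aligned with `mlr`'s rows.
#' @return A list of class `MetaClassifier` with the fitted weights, the
#'   per-epoch loss `history`, the `config` and the ordered
#'   `classifier_ids` the network expects.
#' @export
train_meta <- function(config, mlr, labels) {
  stopifnot(inherits(config, "MetaNetworkConfig"))
  x <- if (inherits(mlr, "ModelLevelRepresentation")) mlr$probs else as.matrix(mlr)
  cls_ids <- if (inherits(mlr, "ModelLevelRepresentation")) mlr$classifier_ids else colnames(x)
  if (nrow(x) != length(labels)) stop("labels do not align with representation rows")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L) stop("both classes must be present to train")
  if (ncol(x) != config$input_dim) {
    stop("input_dim mismatch: config expects ", config$input_dim,
         " but representation has ", ncol(x), " columns")
  }
  n <- nrow(x); d <- ncol(x); hsz <- config$hidden_units
  set.seed(config$seed)
  w <- list(
    W1 = matrix(stats::rnorm(d * hsz, sd = sqrt(2 / d)), d, hsz),
    b1 = rep(0, hsz),
    gamma = rep(1, hsz), beta = rep(0, hsz),
    W2 = matrix(stats::rnorm(hsz, sd = sqrt(2 / hsz)), hsz, 1L),
    b2 = 0,
    run_mean = rep(0, hsz), run_var = rep(1, hsz), eps = 1e-5)
  vel <- list(W1 = w$W1 * 0, b1 = w$b1 * 0, gamma = w$gamma * 0,
              beta = w$beta * 0, W2 = w$W2 * 0, b2 = 0)
  bn_momentum <- 0.9
  lr <- config$learning_rate; mom <- config$momentum
  keep_p <- 1 - config$dropout_rate
  history <- numeric(0)
  best_loss <- Inf; best_w <- w; stall <- 0L
  y <- as.numeric(labels)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    for (s in starts) {
      rows <- ord[s:min(s + config$batch_size - 1L, n)]
      xb <- x[rows, , drop = FALSE]; yb <- y[rows]; B <- length(rows)
      # forward
      z1 <- sweep(xb %*% w$W1, 2L, w$b1, "+")
      mu <- colMeans(z1)
      va <- colMeans(sweep(z1, 2L, mu, "-")^2)
      inv_sd <- 1 / sqrt(va + w$eps)
      z1hat <- sweep(sweep(z1, 2L, mu, "-"), 2L, inv_sd, "*")
      a <- sweep(sweep(z1hat, 2L, w$gamma, "*"), 2L, w$beta, "+")
      h <- pmax(a, 0)
      mask <- if (keep_p < 1) {
        matrix(stats::rbinom(B * hsz, 1L, keep_p), B, hsz) / keep_p
      } else {
        matrix(1, B, hsz)
      }
      hd <- h * mask
      p <- as.numeric(sigmoid(hd %*% w$W2 + w$b2))
      # backward (BCE + sigmoid)
      dz2 <- matrix((p - yb) / B, B, 1L)
      gW2 <- crossprod(hd, dz2); gb2 <- sum(dz2)
      dhd <- dz2 %*% t(w$W2)
      dh <- dhd * mask
      da <- dh * (a > 0)
      ggamma <- colSums(da * z1hat); gbeta <- colSums(da)
      dz1hat <- sweep(da, 2L, w$gamma, "*")
      dz1 <- sweep(
        B * dz1hat -
          matrix(colSums(dz1hat), B, hsz, byrow = TRUE) -
          sweep(z1hat, 2L, colSums(dz1hat * z1hat), "*"),
        2L, inv_sd / B, "*")
      gW1 <- crossprod(xb, dz1); gb1 <- colSums(dz1)
      # running batch-norm statistics (unbiased variance for inference)
      var_unb <- if (B > 1) va * B / (B - 1) else va
      w$run_mean <- bn_momentum * w$run_mean + (1 - bn_momentum) * mu
      w$run_var <- bn_momentum * w$run_var + (1 - bn_momentum) * var_unb
      # SGD with momentum
      vel$W1 <- mom * vel$W1 - lr * gW1;       w$W1 <- w$W1 + vel$W1
      vel$b1 <- mom * vel$b1 - lr * gb1;       w$b1 <- w$b1 + vel$b1
      vel$gamma <- mom * vel$gamma - lr * ggamma; w$gamma <- w$gamma + vel$gamma
      vel$beta <- mom * vel$beta - lr * gbeta;   w$beta <- w$beta + vel$beta
      vel$W2 <- mom * vel$W2 - lr * gW2;       w$W2 <- w$W2 + vel$W2
      vel$b2 <- mom * vel$b2 - lr * gb2;       w$b2 <- w$b2 + vel$b2
    }
    p_all <- meta_forward_infer(w, x)
    p_all <- pmin(pmax(p_all, 1e-12), 1 - 1e-12)
    loss <- -mean(y * log(p_all) + (1 - y) * log(1 - p_all))
    history <- c(history, loss)
    if (loss < best_loss - 1e-8) {
      best_loss <- loss; best_w <- w; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  structure(list(weights = best_w, config = config, history = history,
                 classifier_ids = cls_ids),
            class = "MetaClassifier")
}

#' Predict carcinogenicity probabilities with a trained meta-classifier
#'
#' Deterministic inference: batch normalization uses the stored running
#' statistics and dropout is inactive, so repeated calls (and row-by-row
#' calls) give identical results.
#'
#' @param model A [train_meta()] result.
#' @param mlr A `ModelLevelRepresentation` (or matrix) whose columns match
#'   the training columns in number and order.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_meta <- function(model, mlr) {
  stopifnot(inherits(model, "MetaClassifier"))
  x <- if (inherits(mlr, "ModelLevelRepresentation")) mlr$probs else as.matrix(mlr)
  if (ncol(x) != model$config$input_dim) {
    stop("column mismatch: model expects ", model$config$input_dim,
         " classifiers, got ", ncol(x))
  }
  if (!is.null(model$classifier_ids) && !is.null(colnames(x)) &&
      !identical(colnames(x), model$classifier_ids)) {
    stop("classifier column order does not match the order used in training")
  }
  meta_forward_infer(model$weights, x)
}

#' @export
print.MetaClassifier <- function(x, ...) {
  cat("<MetaClassifier> ", x$config$input_dim, " -> ",
      x$config$hidden_units, " (batch-norm, ReLU, dropout ",
      x$config$dropout_rate, ") -> sigmoid; trained ",
      length(x$history), " epochs\n", sep = "")
  invisible(x)
}
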