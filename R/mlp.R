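# One-hidden-layer perceptron with sigmoid hidden units and a 2-unit
# softmax output, trained by online (per-sample) back-propagation on the
# cross-entropy loss.

.sigmoid <- function(z) 1 / (1 + exp(-z))

.softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Train a multilayer perceptron classifier
#'
#' Feed-forward network with one sigmoid hidden layer and a softmax output
#' over the two classes (output unit 1 = class `+1`), trained by stochastic
#' back-propagation: one gradient step per sample, in fixed data order, for
#' `epochs` passes. Weight initialization and training are deterministic
#' given `seed`. Features are standardized to training mean/sd by default.
#'
#' @param x `n x p` numeric feature matrix.
#' @param y Length-`n` labels in `{-1, +1}`; both classes must be present.
#' @param hidden_units Number of hidden units; default `ceiling((p + 2)/2)`.
#' @param lr Learning rate.
#' @param epochs Training epochs (full passes over the data).
#' @param standardize Standardize features to train mean/sd first.
#' @param seed Seed for weight initialization.
#' @return An object of class `mlp_model` (weights `W1`, `b1`, `W2`, `b2`,
#'   standardization, hyperparameters, final mean cross-entropy `loss`).
#' @export
train_mlp <- function(x, y, hidden_units = NULL, lr = 0.01, epochs = 500L,
                      standardize = TRUE, seed = 1L) {
  x <- as.matrix(x); y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(-1, 1)))
  if (length(unique(y)) < 2L)
    stop("degenerate training set: both classes must be present")
  p <- ncol(x)
  if (is.null(hidden_units)) hidden_units <- ceiling((p + 2) / 2)
  stopifnot(hidden_units >= 1L)
  std <- if (standardize) .standardize_fit(x) else NULL
  xs <- if (standardize) .standardize_apply(x, std) else x
  n <- nrow(xs)
  # one-hot targets, class order (+1, -1)
  Tg <- cbind(as.numeric(y == 1), as.numeric(y == -1))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  W1 <- matrix(stats::runif(hidden_units * p, -0.5, 0.5) / sqrt(p), hidden_units, p)
  b1 <- numeric(hidden_units)
  W2 <- matrix(stats::runif(2 * hidden_units, -0.5, 0.5) / sqrt(hidden_units),
               2, hidden_units)
  b2 <- numeric(2)
  for (ep in seq_len(epochs)) {
    for (i in seq_len(n)) {
      xi <- xs[i, ]
      a1 <- .sigmoid(drop(W1 %*% xi) + b1)
      pr <- .softmax(drop(W2 %*% a1) + b2)
      d2 <- pr - Tg[i, ]                      # softmax + cross-entropy
      d1 <- drop(crossprod(W2, d2)) * a1 * (1 - a1)
      W2 <- W2 - lr * tcrossprod(d2, a1)
      b2 <- b2 - lr * d2
      W1 <- W1 - lr * tcrossprod(d1, xi)
      b1 <- b1 - lr * d1
    }
    if (!all(is.finite(W1)) || !all(is.finite(W2)))
      stop("MLP training diverged (non-finite weights); try a smaller lr")
  }
  # final mean cross-entropy over the training set
  A1 <- .sigmoid(xs %*% t(W1) + matrix(b1, n, length(b1), byrow = TRUE))
  Z2 <- A1 %*% t(W2) + matrix(b2, n, 2, byrow = TRUE)
  P <- t(apply(Z2, 1, .softmax))
  loss <- -mean(log(pmax(P[cbind(seq_len(n), ifelse(y == 1, 1, 2))], 1e-300)))
  if (!is.finite(loss))
    stop("MLP training diverged (non-finite loss); try a smaller lr")
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, std = std,
                 standardize = standardize, hidden_units = hidden_units,
                 lr = lr, epochs = epochs, seed = seed, loss = loss,
                 n_features = p),
            class = "mlp_model")
}

#' @rdname train_mlp
#' @param object A trained `mlp_model`.
#' @param newdata Feature vector or matrix to classify.
#' @param type `"class"` for `{-1, +1}` labels (softmax argmax, ties to
#'   `+1`) or `"prob"` for the two softmax probabilities (columns `+1`,
#'   `-1`).
#' @param ... Unused.
#' @export
predict.mlp_model <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  x <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(x) != object$n_features)
    stop("feature length mismatch: model expects ", object$n_features)
  if (object$standardize) x <- .standardize_apply(x, object$std)
  n <- nrow(x)
  A1 <- .sigmoid(x %*% t(object$W1) +
                   matrix(object$b1, n, object$hidden_units, byrow = TRUE))
  Z2 <- A1 %*% t(object$W2) + matrix(object$b2, n, 2, byrow = TRUE)
  P <- t(apply(Z2, 1, .softmax))
  colnames(P) <- c("+1", "-1")
  if (type == "prob") P else unname(ifelse(P[, 1] >= P[, 2], 1, -1))
}
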