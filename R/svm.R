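# Support vector machine with polynomial kernel, trained by sequential
# minimal optimization (SMO) on the dual problem.

.poly_kernel <- function(A, B, degree, coef) {
  (tcrossprod(A, B) + coef)^degree
}

.standardize_fit <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

.standardize_apply <- function(x, std) {
  sweep(sweep(x, 2, std$center), 2, std$scale, "/")
}

#' Train a polynomial-kernel SVM by SMO
#'
#' Solves the soft-margin dual with pairwise coordinate updates (simplified
#' SMO): sweeps all multipliers, and for each KKT violator picks the partner
#' with maximal `|E_i - E_j|`; converges when `max_passes` consecutive full
#' sweeps change nothing. The decision value is
#' `f(x) = sum_i y_i alpha_i k(x_i, x) + b` with
#' `k(x, z) = (x . z + coef)^degree`.
#'
#' Features are standardized to training mean/sd by default (the kernel is
#' scale sensitive); the transform is stored in the model and applied at
#' prediction time.
#'
#' @param x `n x p` numeric feature matrix.
#' @param y Length-`n` labels in `{-1, +1}`; both classes must be present.
#' @param C Box constraint (regularization).
#' @param degree,coef Polynomial kernel degree and additive constant.
#' @param tol KKT violation tolerance.
#' @param max_passes Consecutive no-change sweeps required for convergence.
#' @param max_iter Hard cap on total sweeps; hitting it keeps the best
#'   iterate and warns.
#' @param standardize Standardize features to train mean/sd first.
#' @param seed Recorded for provenance; SMO as implemented is fully deterministic.
#' @return An object of class `svm_model` (multipliers `alpha`, bias `b`,
#'   stored training data, kernel hyperparameters, standardization).
#' @export
train_svm <- function(x, y, C = 1, degree = 1, coef = 1, tol = 1e-3,
                      max_passes = 5L, max_iter = 200L, standardize = TRUE,
                      seed = 1L) {
  x <- as.matrix(x); y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(-1, 1)))
  if (length(unique(y)) < 2L)
    stop("degenerate training set: both classes must be present")
  std <- if (standardize) .standardize_fit(x) else NULL
  xs <- if (standardize) .standardize_apply(x, std) else x
  n <- nrow(xs)
  K <- .poly_kernel(xs, xs, degree, coef)
  alpha <- numeric(n)
  b <- 0
  passes <- 0L
  iter <- 0L
  fcache <- function() drop(K %*% (alpha * y)) + b
  while (passes < max_passes && iter < max_iter) {
    iter <- iter + 1L
    changed <- 0L
    E <- fcache() - y
    for (i in seq_len(n)) {
      Ei <- sum(alpha * y * K[, i]) + b - y[i]
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        E <- drop(K %*% (alpha * y)) + b - y
        # try partners by decreasing |E_i - E_j| until one makes progress
        for (j in order(-abs(E - Ei))) {
          if (j == i) next
          Ej <- E[j]
          ai_old <- alpha[i]; aj_old <- alpha[j]
          if (y[i] != y[j]) {
            L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
          } else {
            L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
          }
          if (L >= H) next
          eta <- 2 * K[i, j] - K[i, i] - K[j, j]
          if (eta >= 0) next
          aj <- aj_old - y[j] * (Ei - Ej) / eta
          aj <- min(H, max(L, aj))
          if (abs(aj - aj_old) < 1e-12) next
          ai <- ai_old + y[i] * y[j] * (aj_old - aj)
          b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] -
            y[j] * (aj - aj_old) * K[i, j]
          b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] -
            y[j] * (aj - aj_old) * K[j, j]
          b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2
               else (b1 + b2) / 2
          alpha[i] <- ai; alpha[j] <- aj
          changed <- changed + 1L
          break
        }
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
  }
  if (iter >= max_iter && passes < max_passes)
    warning("SMO hit the iteration cap; returning best iterate")
  structure(list(alpha = alpha, b = b, x = xs, y = y, C = C, degree = degree,
                 coef = coef, tol = tol, standardize = standardize, std = std,
                 seed = seed, n_features = ncol(x), sweeps = iter),
            class = "svm_model")
}

#' Decision values of a trained SVM
#'
#' @param object A trained `svm_model`.
#' @param newdata Feature vector or matrix.
#' @return Numeric decision values `f(x)`.
#' @export
decision_values <- function(object, newdata) {
  stopifnot(inherits(object, "svm_model"))
  x <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(x) != object$n_features)
    stop("feature length mismatch: model expects ", object$n_features)
  if (object$standardize) x <- .standardize_apply(x, object$std)
  drop(.poly_kernel(x, object$x, object$degree, object$coef) %*%
         (object$alpha * object$y)) + object$b
}

#' @rdname train_svm
#' @param object A trained `svm_model`.
#' @param newdata Feature vector or matrix to classify.
#' @param type `"class"` for `{-1, +1}` labels (zero decision value maps to
#'   `+1`) or `"decision"` for raw decision values.
#' @param ... Unused.
#' @export
predict.svm_model <- function(object, newdata, type = c("class", "decision"),
                              ...) {
  type <- match.arg(type)
  f <- decision_values(object, newdata)
  if (type == "decision") f else ifelse(f >= 0, 1, -1)
}
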