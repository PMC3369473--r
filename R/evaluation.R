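# Evaluation metrics and stratified cross-validation.
#
# Class +1 is C1 (positive); classification accuracy is a percentage;
# the weighted F-measure weights each class's F by its population size.

#' Confusion counts for binary predictions
#'
#' Class `+1` is treated as positive (C1).
#'
#' @param predicted,truth Equal-length label vectors in `{-1, +1}`.
#' @return Named integer vector `c(tp, tn, fp, fn)`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) < 1L)
    stop("predicted and truth must have equal length >= 1")
  c(tp = sum(predicted == 1 & truth == 1),
    tn = sum(predicted == -1 & truth == -1),
    fp = sum(predicted == 1 & truth == -1),
    fn = sum(predicted == -1 & truth == 1))
}

#' Per-class F-measure
#'
#' `F = 2 * Recall * Precision / (Recall + Precision)` with
#' `Precision = TP/(TP+FP)` and `Recall = TP/(TP+FN)`; any 0/0 is defined
#' as 0.
#'
#' @param tp,fp,fn True-positive, false-positive, false-negative counts.
#' @return F-measure in `[0, 1]`.
#' @export
f_measure <- function(tp, fp, fn) {
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (precision + recall == 0) 0 else 2 * recall * precision / (recall + precision)
}

#' Population-weighted average F-measure
#'
#' `(|C1| F(C1) + |C2| F(C2)) / (|C1| + |C2|)`, where `F(C2)` is computed
#' with C2 as the positive class.
#'
#' @param f_c1,f_c2 Per-class F-measures.
#' @param n_c1,n_c2 Class population sizes.
#' @return Weighted F-measure in `[0, 1]`.
#' @export
weighted_f_measure <- function(f_c1, f_c2, n_c1, n_c2) {
  if (n_c1 + n_c2 < 1) stop("at least one instance required")
  (n_c1 * f_c1 + n_c2 * f_c2) / (n_c1 + n_c2)
}

#' Stratified fold assignment
#'
#' Shuffles each class separately under the seed and deals samples
#' round-robin, so fold class proportions track the data.
#'
#' @param y Label vector in `{-1, +1}`.
#' @param k Number of folds.
#' @param seed RNG seed; folds are reproducible given `(y, k, seed)`.
#' @return Integer vector of fold ids in `1..k`, one per sample.
#' @export
make_folds <- function(y, k = 3L, seed = 1L) {
  if (any(table(y) < k))
    stop("stratification error: every class needs at least ", k, " members")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# full metric set from pooled or per-fold confusion counts
.report_from_counts <- function(cc, n_c1, n_c2) {
  f1 <- f_measure(cc["tp"], cc["fp"], cc["fn"])
  # C2 as positive: its TP are the TN of C1, etc.
  f2 <- f_measure(cc["tn"], cc["fn"], cc["fp"])
  n <- sum(cc)
  list(tp = unname(cc["tp"]), tn = unname(cc["tn"]),
       fp = unname(cc["fp"]), fn = unname(cc["fn"]),
       f_c1 = unname(f1), f_c2 = unname(f2),
       weighted_f = unname(weighted_f_measure(f1, f2, n_c1, n_c2)),
       ca = unname(100 * (cc["tp"] + cc["tn"]) / n))
}

#' Cross-validate a classifier
#'
#' Stratified k-fold (default 3) cross-validation: each fold is tested once
#' with the remaining folds as training data. Per-fold confusion counts are
#' pooled before applying the F-measure formulas (each sample is tested
#' exactly once, so pooled CA equals the fold-size-weighted average
#' accuracy); per-fold metrics are also reported.
#'
#' @param x `n x p` feature matrix.
#' @param y Labels in `{-1, +1}`, at least `k` per class.
#' @param trainer Function `(x_train, y_train) -> model` whose result
#'   supports `predict(model, x_test)` returning `{-1, +1}` labels.
#' @param k Number of folds.
#' @param seed Seed controlling the fold assignment.
#' @return An object of class `evaluation_report`: pooled confusion counts,
#'   per-class F, `weighted_f`, `ca` (percent), class sizes, fold ids and a
#'   `per_fold` list of per-fold reports.
#' @export
cross_validate <- function(x, y, trainer, k = 3L, seed = 1L) {
  x <- as.matrix(x); y <- as.numeric(y)
  folds <- make_folds(y, k, seed)
  n_c1 <- sum(y == 1); n_c2 <- sum(y == -1)
  pooled <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds == f
    model <- trainer(x[!test, , drop = FALSE], y[!test])
    pred <- predict(model, x[test, , drop = FALSE])
    cc <- confusion_counts(pred, y[test])
    per_fold[[f]] <- .report_from_counts(cc, sum(y[test] == 1), sum(y[test] == -1))
    pooled <- pooled + cc
  }
  rep <- .report_from_counts(pooled, n_c1, n_c2)
  structure(c(rep, list(n_c1 = n_c1, n_c2 = n_c2, k = k, seed = seed,
                        folds = folds, per_fold = per_fold)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report: %d-fold CV, n = %d (%d/%d)>\n  weighted F = %.3f, CA = %.2f%%\n",
    x$k, x$n_c1 + x$n_c2, x$n_c1, x$n_c2, x$weighted_f, x$ca))
  invisible(x)
}
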