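# Metrics and stratified cross-validation.

test_that("confusion counts match frozen cases and an enumeration oracle", {
  expect_equal(confusion_counts(c(1, 1, 1, -1, -1), c(1, 1, 1, -1, -1)),
               c(tp = 3, tn = 2, fp = 0, fn = 0))
  expect_equal(confusion_counts(rep(1, 4), rep(-1, 4)),
               c(tp = 0, tn = 0, fp = 4, fn = 0))
  set.seed(17)
  pred <- sample(c(-1, 1), 50, TRUE); truth <- sample(c(-1, 1), 50, TRUE)
  tally <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (i in 1:50) {
    k <- if (truth[i] == 1) { if (pred[i] == 1) "tp" else "fn" }
         else { if (pred[i] == 1) "fp" else "tn" }
    tally[k] <- tally[k] + 1
  }
  expect_equal(confusion_counts(pred, truth), tally)
  expect_error(confusion_counts(1, c(1, -1)), "equal length")
})

test_that("F-measure follows the precision/recall formula with 0/0 -> 0", {
  expect_equal(f_measure(5, 0, 0), 1)
  expect_equal(f_measure(3, 1, 2), 2 * 0.6 * 0.75 / (0.6 + 0.75))
  expect_equal(f_measure(3, 1, 2), 2 / 3)
  expect_equal(f_measure(0, 3, 0), 0)
  expect_equal(f_measure(0, 0, 0), 0)
})

test_that("weighted F-measure is the population-weighted average", {
  expect_equal(weighted_f_measure(0.8, 0.8, 10, 10), 0.8)
  expect_equal(weighted_f_measure(1.0, 0.0, 3, 1), 0.75)
  expect_equal(weighted_f_measure(0.0, 0.6, 0, 7), 0.6)
  # invariant to swapping the class-name convention
  expect_equal(weighted_f_measure(0.7, 0.4, 9, 4),
               weighted_f_measure(0.4, 0.7, 4, 9))
})

test_that("stratified folds cover every sample exactly once, reproducibly", {
  y <- rep(c(1, -1), c(6, 3))
  f1 <- make_folds(y, 3, seed = 42)
  f2 <- make_folds(y, 3, seed = 42)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1)), 1:3)
  expect_equal(as.integer(table(f1)), rep(3L, 3)) # 9 samples -> (3,3,3)
  for (k in 1:3) expect_equal(sum(y[f1 == k] == 1), 2)  # stratification
  expect_error(make_folds(c(1, 1, 1, -1, -1), 3), "stratification")
})

test_that("cross_validate reports perfect and majority classifiers correctly", {
  # perfect classifier: an oracle that memorizes the labels through x
  x <- matrix(rep(c(1, -1), c(6, 3)), ncol = 1)
  y <- rep(c(1, -1), c(6, 3))
  registerS3method("predict", "sign_model",
                   function(object, newdata, ...) sign(newdata[, 1]),
                   envir = globalenv())
  registerS3method("predict", "const_model",
                   function(object, newdata, ...) rep(1, nrow(newdata)),
                   envir = globalenv())
  oracle_trainer <- function(x, y) structure(list(), class = "sign_model")
  rep1 <- cross_validate(x, y, oracle_trainer, k = 3, seed = 1)
  expect_equal(rep1$ca, 100)
  expect_equal(rep1$weighted_f, 1)
  expect_equal(length(rep1$per_fold), 3L)
  expect_equal(rep1$tp + rep1$tn + rep1$fp + rep1$fn, 9)
  # majority-constant classifier on the (6,3) split
  maj_trainer <- function(x, y) structure(list(), class = "const_model")
  rep2 <- cross_validate(x, y, maj_trainer, k = 3, seed = 1)
  expect_equal(rep2$ca, 100 * 6 / 9)
  # F(C1) = 2*(2/3)/(1 + 2/3) = 0.8, F(C2) = 0 -> weighted F = 6/9*0.8
  expect_equal(rep2$weighted_f, (6 * 0.8 + 3 * 0) / 9)
  expect_lt(rep2$weighted_f, rep2$ca / 100)
  # CA identity from pooled counts
  expect_equal(rep2$ca, 100 * (rep2$tp + rep2$tn) / 9)
})

test_that("pooled report is invariant to swapping the class convention", {
  # swapping C1 <-> C2 swaps tp<->tn, fp<->fn and the class sizes
  cc <- c(tp = 11, tn = 6, fp = 4, fn = 2)
  swapped <- c(tp = 6, tn = 11, fp = 2, fn = 4)
  r1 <- tonguecolor:::.report_from_counts(cc, 13, 10)
  r2 <- tonguecolor:::.report_from_counts(swapped, 10, 13)
  expect_equal(r1$weighted_f, r2$weighted_f, tolerance = 1e-12)
  expect_equal(r1$ca, r2$ca, tolerance = 1e-12)
  expect_equal(r1$f_c1, r2$f_c2)
})
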