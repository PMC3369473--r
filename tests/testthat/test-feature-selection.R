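# Information-gain ranking and best-first subset selection.

test_that("a label-identical feature scores the maximal 1 bit", {
  set.seed(31)
  y <- rep(c(1, -1), each = 20)
  x <- cbind(perfect = as.numeric(y == 1) + rnorm(40, 0, 1e-6),
             noise = rnorm(40))
  rk <- information_gain_rank(x, y)
  expect_equal(unname(rk$scores["perfect"]), 1, tolerance = 1e-9)
  expect_equal(rk$order[1], 1L)
})

test_that("constant features and constant labels score zero", {
  y <- rep(c(1, -1), each = 10)
  x <- cbind(const = rep(1, 20), other = rnorm(20))
  rk <- information_gain_rank(x, y)
  expect_equal(unname(rk$scores["const"]), 0)
  expect_warning(rk0 <- information_gain_rank(x, rep(1, 20)), "constant labels")
  expect_equal(unname(rk0$scores), c(0, 0))
})

test_that("the informative feature outranks noise (brute-force IG check)", {
  set.seed(32)
  y <- rep(c(1, -1), each = 25)
  informative <- ifelse(y == 1, rnorm(50, 3), rnorm(50, 0))
  x <- cbind(n1 = rnorm(50), inf = informative, n2 = rnorm(50))
  rk <- information_gain_rank(x, y)
  expect_equal(rk$order[1], 2L)
  # brute-force single-split IG over all cut points bounds the MDL score
  best_split_ig <- function(v, y) {
    n <- length(v); ord <- order(v); vs <- v[ord]; ys <- y[ord]
    ent <- function(z) { p <- table(z) / length(z); p <- p[p > 0]; -sum(p * log2(p)) }
    cands <- which(diff(vs) > 0)
    max(vapply(cands, function(k)
      ent(ys) - k / n * ent(ys[1:k]) - (n - k) / n * ent(ys[(k + 1):n]),
      numeric(1)))
  }
  expect_gte(rk$scores["inf"] + 1e-9, 0)
  expect_lte(rk$scores["n1"], best_split_ig(x[, "n1"], y) + 1e-9)
})

test_that("IG is invariant to strictly monotone feature transforms", {
  set.seed(33)
  y <- rep(c(1, -1), each = 15)
  v <- ifelse(y == 1, rnorm(30, 1.5), rnorm(30))
  x1 <- cbind(v = v)
  x2 <- cbind(v = exp(v))           # strictly monotone
  x3 <- cbind(v = 2 * v - 7)
  s1 <- information_gain_rank(x1, y)$scores
  expect_equal(s1, information_gain_rank(x2, y)$scores, tolerance = 1e-12)
  expect_equal(s1, information_gain_rank(x3, y)$scores, tolerance = 1e-12)
})

test_that("best-first matches exhaustive search on small problems", {
  set.seed(34)
  n <- 40; p <- 6
  y <- rep(c(1, -1), each = n / 2)
  x <- matrix(rnorm(n * p), n, p)
  x[, 2] <- x[, 2] + y            # informative
  x[, 5] <- x[, 5] + 0.5 * y      # weakly informative
  sel <- best_first_select(x, y, stale_limit = 10)
  # exhaustive oracle over all non-empty subsets
  best_merit <- 0
  for (m in 1:p) {
    combos <- utils::combn(p, m)
    for (j in seq_len(ncol(combos)))
      best_merit <- max(best_merit, cfs_merit(x, y, combos[, j]))
  }
  expect_equal(sel$merit, best_merit, tolerance = 1e-10)
})

test_that("a perfectly separating feature is always selected", {
  set.seed(35)
  y <- rep(c(1, -1), each = 12)
  x <- cbind(rnorm(24), y + rnorm(24, 0, 0.01), rnorm(24))
  sel <- best_first_select(x, y)
  expect_true(2L %in% sel$indices)
  # selected merit dominates every singleton
  singles <- vapply(1:3, function(j) cfs_merit(x, y, j), numeric(1))
  expect_gte(sel$merit + 1e-12, max(singles))
})

test_that("stale_limit 0 reduces to greedy forward selection", {
  set.seed(36)
  n <- 30; p <- 5
  y <- rep(c(1, -1), each = n / 2)
  x <- matrix(rnorm(n * p), n, p); x[, 3] <- x[, 3] + y
  sel <- best_first_select(x, y, stale_limit = 0)
  # greedy oracle: grow the single best chain until no improvement
  cur <- integer(0); cur_m <- 0
  repeat {
    cand <- setdiff(1:p, cur)
    ms <- vapply(cand, function(f) cfs_merit(x, y, c(cur, f)), numeric(1))
    if (max(ms) <= cur_m + 1e-12) break
    cur <- c(cur, cand[which.max(ms)]); cur_m <- max(ms)
  }
  expect_equal(sort(sel$indices), sort(cur))
  expect_equal(sel$merit, cur_m, tolerance = 1e-12)
})
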