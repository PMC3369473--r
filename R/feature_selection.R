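# Information-gain feature ranking (with MDL-based discretization) and
# best-first subset selection with a correlation-based merit.

.entropy <- function(y) {
  p <- table(y) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Fayyad-Irani MDL recursive binary discretization: returns accepted cut
# points (possibly none) for one continuous feature against the labels.
.mdl_cuts <- function(x, y) {
  n <- length(x)
  if (n < 2L || length(unique(y)) < 2L) return(numeric(0))
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  # candidate cuts: midpoints between distinct adjacent values
  cand <- which(diff(xs) > 0)
  if (length(cand) == 0L) return(numeric(0))
  ent_all <- .entropy(ys)
  best_gain <- -Inf; best_k <- NA_integer_
  for (k in cand) {
    e1 <- .entropy(ys[1:k]); e2 <- .entropy(ys[(k + 1):n])
    gain <- ent_all - (k / n) * e1 - ((n - k) / n) * e2
    if (gain > best_gain) { best_gain <- gain; best_k <- k }
  }
  k <- best_k
  y1 <- ys[1:k]; y2 <- ys[(k + 1):n]
  k_all <- length(unique(ys)); k1 <- length(unique(y1)); k2 <- length(unique(y2))
  delta <- log2(3^k_all - 2) -
    (k_all * ent_all - k1 * .entropy(y1) - k2 * .entropy(y2))
  if (best_gain <= (log2(n - 1) + delta) / n) return(numeric(0))
  cut <- (xs[k] + xs[k + 1]) / 2
  c(.mdl_cuts(xs[1:k], y1), cut, .mdl_cuts(xs[(k + 1):n], y2))
}

# information gain of one feature after MDL discretization; 0 when the
# discretization collapses to a single bin
.feature_ig <- function(x, y) {
  cuts <- .mdl_cuts(x, y)
  if (length(cuts) == 0L) return(0)
  bins <- findInterval(x, sort(cuts))
  cond <- 0
  for (b in unique(bins)) {
    sel <- bins == b
    cond <- cond + mean(sel) * .entropy(y[sel])
  }
  max(0, .entropy(y) - cond)
}

#' Rank features by information gain
#'
#' Each continuous feature is discretized by supervised MDL-based recursive
#' binary splitting (Fayyad-Irani); its score is the entropy reduction
#' `H(Y) - H(Y | bins)`. Features whose discretization collapses to one bin
#' score 0.
#'
#' @param x `n x p` feature matrix.
#' @param y Labels in `{-1, +1}`.
#' @return An object of class `feature_ranking`: `scores` (per feature, in
#'   bits) and `order` (feature indices by descending score, ties by index).
#' @export
information_gain_rank <- function(x, y) {
  x <- as.matrix(x); y <- as.numeric(y)
  stopifnot(nrow(x) == length(y))
  if (length(unique(y)) < 2L) {
    warning("constant labels: all information-gain scores are zero")
    scores <- numeric(ncol(x))
  } else {
    scores <- apply(x, 2, .feature_ig, y = y)
  }
  names(scores) <- colnames(x)
  structure(list(scores = scores, order = order(-scores)),
            class = "feature_ranking")
}

#' Correlation-based subset merit
#'
#' CFS-style merit `k * mean(r_cf) / sqrt(k + k(k-1) * mean(r_ff))`, where
#' `r_cf` are absolute Pearson correlations between the subset's features
#' and the numeric label and `r_ff` the absolute pairwise feature
#' correlations. Constant features contribute 0 correlation.
#'
#' @param x `n x p` feature matrix.
#' @param y Labels in `{-1, +1}`.
#' @param subset Integer vector of feature indices.
#' @return The subset merit (0 for an empty subset).
#' @export
cfs_merit <- function(x, y, subset) {
  k <- length(subset)
  if (k == 0L) return(0)
  xs <- x[, subset, drop = FALSE]
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    abs(stats::cor(a, b))
  }
  rcf <- mean(vapply(seq_len(k), function(j) safe_cor(xs[, j], y), numeric(1)))
  if (k == 1L) return(rcf)
  pairs <- utils::combn(k, 2)
  rff <- mean(vapply(seq_len(ncol(pairs)), function(m)
    safe_cor(xs[, pairs[1, m]], xs[, pairs[2, m]]), numeric(1)))
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' Best-first forward feature-subset selection
#'
#' Greedy hill climbing with backtracking: keeps a priority list of scored
#' subsets, repeatedly expands the best unexpanded subset by single-feature
#' additions, and stops after `stale_limit` consecutive expansions that do
#' not improve the best merit seen (`stale_limit = 0` reduces to pure greedy
#' forward selection).
#'
#' @param x `n x p` feature matrix with `p >= 2`.
#' @param y Labels in `{-1, +1}`.
#' @param evaluator Subset-scoring function `(x, y, subset) -> merit`;
#'   defaults to [cfs_merit()]. A wrapper evaluator (e.g. CV weighted F of a
#'   classifier) can be supplied instead.
#' @param stale_limit Consecutive non-improving expansions tolerated.
#' @return An object of class `selected_subset`: `indices` (ascending),
#'   `merit`, and a `trace` data frame of visited subsets and merits.
#' @export
best_first_select <- function(x, y, evaluator = cfs_merit, stale_limit = 5L) {
  x <- as.matrix(x); y <- as.numeric(y)
  p <- ncol(x)
  stopifnot(p >= 2L)
  key <- function(s) paste0("s:", paste(sort(s), collapse = ","))
  visited <- new.env(parent = emptyenv())
  open_sets <- list(integer(0))
  open_merits <- 0
  expanded <- character(0)
  assign(key(integer(0)), TRUE, visited)
  best_set <- integer(0); best_merit <- 0
  stale <- 0L
  trace <- list()
  while (length(open_sets) > 0L && stale <= stale_limit) {
    i <- which.max(open_merits)
    cur <- open_sets[[i]]
    open_sets[[i]] <- NULL
    open_merits <- open_merits[-i]
    improved <- FALSE
    for (f in setdiff(seq_len(p), cur)) {
      child <- c(cur, f)
      k <- key(child)
      if (exists(k, visited, inherits = FALSE)) next
      assign(k, TRUE, visited)
      m <- evaluator(x, y, child)
      trace[[length(trace) + 1L]] <- data.frame(subset = k, merit = m)
      open_sets[[length(open_sets) + 1L]] <- child
      open_merits <- c(open_merits, m)
      if (m > best_merit + 1e-12) {
        best_merit <- m; best_set <- child; improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  structure(list(indices = sort(best_set), merit = best_merit,
                 trace = if (length(trace)) do.call(rbind, trace)
                         else data.frame(subset = character(0), merit = numeric(0))),
            class = "selected_subset")
}
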