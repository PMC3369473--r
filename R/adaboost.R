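# AdaBoost with depth-limited decision-tree weak learners.

# Best weighted decision stump on (x, y, w): returns feature, threshold,
# polarity (label predicted when x[, feature] <= threshold) and weighted
# error. Thresholds are midpoints between consecutive distinct sorted values
# plus the two outer sentinels (constant predictions).
.fit_stump <- function(x, y, w) {
  best <- list(err = Inf)
  for (j in seq_len(ncol(x))) {
    ord <- order(x[, j])
    xv <- x[ord, j]; yv <- y[ord]; wv <- w[ord]
    # cum_pos[k] = weight of positives among first k, etc.
    cum_pos <- cumsum(wv * (yv == 1))
    cum_neg <- cumsum(wv * (yv == -1))
    tot_pos <- cum_pos[length(cum_pos)]
    tot_neg <- cum_neg[length(cum_neg)]
    # candidate split after position k; interior cuts only (a constant
    # prediction is the tree's majority-leaf fallback, and interior cuts
    # keep ties splittable for deeper trees)
    ks <- which(diff(xv) > 0)
    if (length(ks) == 0L) next
    cp <- cum_pos[ks]
    cn <- cum_neg[ks]
    # polarity +1: left predicted +1, right -1 -> errors: left negs + right pos
    err_p <- cn + (tot_pos - cp)
    # polarity -1: mirror
    err_m <- cp + (tot_neg - cn)
    errs <- pmin(err_p, err_m)
    bi <- which.min(errs)
    k <- ks[bi]
    thr <- (xv[k] + xv[k + 1L]) / 2
    e_p <- err_p[bi]; e_m <- err_m[bi]
    pol <- if (e_p <= e_m) 1 else -1
    err <- min(e_p, e_m)
    if (err < best$err)
      best <- list(feature = j, threshold = thr, polarity = pol, err = err)
  }
  if (!is.finite(best$err)) return(NULL)   # all features constant
  best
}

# Recursive weighted decision tree of maximum depth `depth` (1 = stump).
.fit_tree <- function(x, y, w, depth) {
  maj <- if (sum(w[y == 1]) >= sum(w[y == -1])) 1 else -1
  if (depth < 1L || length(unique(y)) == 1L || nrow(x) < 2L)
    return(list(leaf = TRUE, label = maj))
  s <- .fit_stump(x, y, w)
  if (is.null(s)) return(list(leaf = TRUE, label = maj))
  left <- x[, s$feature] <= s$threshold
  if (!any(left) || all(left)) return(list(leaf = TRUE, label = maj))
  if (depth == 1L) {
    return(list(leaf = FALSE, feature = s$feature, threshold = s$threshold,
                left = list(leaf = TRUE, label = s$polarity),
                right = list(leaf = TRUE, label = -s$polarity)))
  }
  list(leaf = FALSE, feature = s$feature, threshold = s$threshold,
       left = .fit_tree(x[left, , drop = FALSE], y[left], w[left], depth - 1L),
       right = .fit_tree(x[!left, , drop = FALSE], y[!left], w[!left], depth - 1L))
}

.predict_tree <- function(tree, x) {
  if (tree$leaf) return(rep(tree$label, nrow(x)))
  left <- x[, tree$feature] <= tree$threshold
  out <- numeric(nrow(x))
  if (any(left)) out[left] <- .predict_tree(tree$left, x[left, , drop = FALSE])
  if (any(!left)) out[!left] <- .predict_tree(tree$right, x[!left, , drop = FALSE])
  out
}

#' Train an AdaBoost ensemble
#'
#' Discrete AdaBoost over depth-limited decision-tree weak learners.
#' Sample weights start uniform (`D_1(i) = 1/n`); each round fits a tree on
#' the current distribution, computes the weighted error `eps_t`, stops
#' without storing the round if `eps_t >= 1/2`, otherwise stores
#' `alpha_t = 0.5 * log((1 - eps_t)/eps_t)` and reweights
#' `D_{t+1}(i) = D_t(i)/Z_t * exp(-/+ alpha_t)`. A perfect round
#' (`eps_t = 0`) is stored with `eps` clamped to `1e-10` and training stops.
#'
#' @param x `n x p` numeric feature matrix.
#' @param y Length-`n` labels in `{-1, +1}`; both classes must be present.
#' @param n_rounds Maximum boosting rounds `T`.
#' @param depth Weak-learner tree depth (1 = decision stump).
#' @param seed Recorded for provenance; training itself is deterministic.
#' @return An object of class `adaboost_model` with elements `rounds`
#'   (list of `(tree, alpha)`), and a `history` data frame of per-round
#'   `eps`, `alpha`, `Z` (normalizer) and `dist_sum` (post-update weight sum).
#' @export
train_adaboost <- function(x, y, n_rounds = 50L, depth = 1L, seed = 1L) {
  x <- as.matrix(x); y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(-1, 1)), n_rounds >= 1L)
  if (length(unique(y)) < 2L)
    stop("degenerate training set: both classes must be present")
  n <- nrow(x)
  D <- rep(1 / n, n)
  rounds <- list()
  hist <- list()
  for (t in seq_len(n_rounds)) {
    tree <- .fit_tree(x, y, D, depth)
    h <- .predict_tree(tree, x)
    eps <- sum(D[h != y])
    if (eps >= 0.5) break
    perfect <- eps == 0
    eps_c <- max(eps, 1e-10)
    alpha <- 0.5 * log((1 - eps_c) / eps_c)
    rounds[[length(rounds) + 1L]] <- list(tree = tree, alpha = alpha)
    Dnew <- D * exp(-alpha * y * h)
    Z <- sum(Dnew)
    D <- Dnew / Z
    hist[[length(hist) + 1L]] <-
      data.frame(round = t, eps = eps, alpha = alpha, Z = Z, dist_sum = sum(D))
    if (perfect) break
  }
  structure(list(rounds = rounds, n_rounds = n_rounds, depth = depth,
                 seed = seed, n_features = ncol(x),
                 history = do.call(rbind, hist)),
            class = "adaboost_model")
}

#' @rdname train_adaboost
#' @param object A trained `adaboost_model`.
#' @param newdata Feature vector or matrix to classify.
#' @param type `"class"` for `{-1, +1}` labels (zero score maps to `+1`) or
#'   `"score"` for the raw weighted vote `sum_t alpha_t h_t(x)`.
#' @param ... Unused.
#' @export
predict.adaboost_model <- function(object, newdata, type = c("class", "score"),
                                   ...) {
  type <- match.arg(type)
  x <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(x) != object$n_features)
    stop("feature length mismatch: model expects ", object$n_features)
  score <- numeric(nrow(x))
  for (r in object$rounds) score <- score + r$alpha * .predict_tree(r$tree, x)
  if (type == "score") score else ifelse(score >= 0, 1, -1)
}
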