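# Fixture builders shared across test files.

# two Gaussian blobs in d dimensions, class means +/- sep/2 on every axis
make_blobs <- function(n_per_class = 20, sep = 4, d = 2, sd = 1, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  y <- rep(c(1, -1), each = n_per_class)
  x <- matrix(rnorm(n * d, sd = sd), n, d) +
    outer(y, rep(sep / 2, d))
  list(x = x, y = y)
}

xor_data <- function() {
  list(x = rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0)),
       y = c(1, 1, -1, -1))
}

# small synthetic cohort; null = TRUE removes all class color differences
small_cohort <- function(n_pos = 9, n_neg = 9, size = 32, seed = 7,
                         null = FALSE, ...) {
  cfg <- cohort_config(n_per_class = c(pos = n_pos, neg = n_neg),
                       image_size = c(size, size), seed = seed, ...)
  if (null) {
    cfg$body_color_mean[2, ] <- cfg$body_color_mean[1, ]
    cfg$coating_color_mean[2, ] <- cfg$coating_color_mean[1, ]
  }
  generate_cohort(cfg)
}

# weighted F of a constant majority-class predictor: the no-information
# baseline used by the null-cohort checks
majority_baseline_wf <- function(n_c1, n_c2) {
  if (n_c1 >= n_c2) {
    p <- n_c1 / (n_c1 + n_c2)
    f1 <- 2 * p / (1 + p)
    weighted_f_measure(f1, 0, n_c1, n_c2)
  } else {
    p <- n_c2 / (n_c1 + n_c2)
    f2 <- 2 * p / (1 + p)
    weighted_f_measure(0, f2, n_c1, n_c2)
  }
}
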