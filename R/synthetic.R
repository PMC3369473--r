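# Synthetic tongue-image cohort generator.
#
# Emulates the statistical structure the analysis assumes: an elliptical
# tongue on a dark background, class-conditional body color (red vs
# pale-red), class-conditional coating color (yellow vs white) concentrated
# in the middle region as elliptical blobs, i.i.d. Gaussian channel noise,
# and a class imbalance shaped like the clinical cohort (132/68).

#' Configuration for a synthetic tongue cohort
#'
#' Defaults describe a Hot/Cold ZHENG cohort: 132 positive (Hot: red body,
#' yellowish coating) and 68 negative (Cold: pale-red body, whitish
#' coating) images. Class body/coating color means are separated by well
#' over 3 noise standard deviations per discriminating channel, the regime
#' in which the pipeline is expected to recover the labels.
#'
#' @param n_per_class Named counts `c(pos = , neg = )` (`pos` is label
#'   `+1`).
#' @param image_size `c(height, width)` in pixels.
#' @param body_color_mean 2 x 3 matrix (rows pos/neg) of mean body RGB.
#' @param body_color_spread Between-image SD of the per-image body color.
#' @param coating_color_mean 2 x 3 matrix (rows pos/neg) of mean coating
#'   RGB.
#' @param coating_color_spread Between-image SD of the per-image coating
#'   color.
#' @param coating_fraction Target fraction of the middle region covered by
#'   coating blobs (0 disables coating).
#' @param noise_sd Per-channel i.i.d. Gaussian pixel noise SD.
#' @param seed Master seed; per-sample seeds are derived from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_class = c(pos = 132L, neg = 68L),
                          image_size = c(64L, 64L),
                          body_color_mean = rbind(pos = c(170, 60, 60),
                                                  neg = c(205, 140, 140)),
                          body_color_spread = 8,
                          coating_color_mean = rbind(pos = c(200, 180, 100),
                                                     neg = c(225, 222, 205)),
                          coating_color_spread = 8,
                          coating_fraction = 0.4,
                          noise_sd = 8,
                          seed = 1L) {
  stopifnot(all(n_per_class >= 1), length(image_size) == 2,
            all(image_size >= 8),
            all(body_color_mean >= 0 & body_color_mean <= 255),
            all(coating_color_mean >= 0 & coating_color_mean <= 255),
            coating_fraction >= 0, coating_fraction <= 1, noise_sd >= 0)
  structure(list(n_per_class = n_per_class, image_size = as.integer(image_size),
                 body_color_mean = body_color_mean,
                 body_color_spread = body_color_spread,
                 coating_color_mean = coating_color_mean,
                 coating_color_spread = coating_color_spread,
                 coating_fraction = coating_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_config")
}

.BACKGROUND <- c(16, 16, 16)  # fixed, so mask = "not background" is exact

.with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  expr
}

# filled-ellipse indicator over an H x W grid
.ellipse_mask <- function(h, w, cy, cx, ry, rx) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((rows - cy) / ry)^2 + ((cols - cx) / rx)^2 <= 1
}

#' Generate one synthetic tongue image
#'
#' @param config A [cohort_config()].
#' @param class_label `+1` (positive class colors) or `-1`.
#' @param seed Per-image seed; the same seed yields a pixel-identical
#'   image.
#' @param id Sample identifier for the resulting [tongue_image()].
#' @return A [tongue_image()] with an exact foreground mask.
#' @export
generate_tongue <- function(config, class_label, seed, id = "sample") {
  stopifnot(inherits(config, "cohort_config"), class_label %in% c(-1, 1))
  h <- config$image_size[1]; w <- config$image_size[2]
  cls <- if (class_label == 1) 1L else 2L
  .with_seed(seed, {
    mask <- .ellipse_mask(h, w, (h + 1) / 2, (w + 1) / 2, 0.45 * h, 0.40 * w)
    if (!any(mask)) stop("degenerate ellipse: image size too small")
    body <- pmin(255, pmax(0, config$body_color_mean[cls, ] +
                             stats::rnorm(3, 0, config$body_color_spread)))
    img <- array(rep(.BACKGROUND, each = h * w), dim = c(h, w, 3))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- body[ch]
      img[, , ch] <- plane
    }
    # coating blobs inside the middle rectangle of the mask bounding box
    coat <- matrix(FALSE, h, w)
    if (config$coating_fraction > 0) {
      mid <- .region_mask(list(mask = mask), region_spec("middle"))
      target <- config$coating_fraction * sum(mid)
      coating <- pmin(255, pmax(0, config$coating_color_mean[cls, ] +
                                  stats::rnorm(3, 0, config$coating_color_spread)))
      bb <- bounding_box(mid)
      tries <- 0L
      while (sum(coat & mid) < target && tries < 200L) {
        tries <- tries + 1L
        cy <- stats::runif(1, bb[1] + 1, bb[2])
        cx <- stats::runif(1, bb[3] + 1, bb[4])
        ry <- stats::runif(1, 0.1, 0.3) * (bb[2] - bb[1])
        rx <- stats::runif(1, 0.1, 0.3) * (bb[4] - bb[3])
        coat <- coat | .ellipse_mask(h, w, cy, cx, ry, rx)
      }
      coat <- coat & mid
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[coat] <- coating[ch]
        img[, , ch] <- plane
      }
    }
    if (config$noise_sd > 0) {
      noise <- array(stats::rnorm(h * w * 3, 0, config$noise_sd), c(h, w, 3))
      fg <- array(rep(mask, 3), c(h, w, 3))
      img[fg] <- img[fg] + noise[fg]
    }
    img[] <- round(pmin(255, pmax(0, img)))
    # keep foreground off the background color so mask recovery stays exact
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask & plane == .BACKGROUND[ch]] <- .BACKGROUND[ch] + 1
      img[, , ch] <- plane
    }
    tongue_image(img, mask, id = id)
  })
}

#' Generate a labeled synthetic cohort
#'
#' @param config A [cohort_config()].
#' @param scheme Labeling-scheme name recorded in the manifest (e.g.
#'   `"zheng_hot_cold"`).
#' @return An object of class `tongue_cohort`: `images` (list of
#'   [tongue_image()]), `labels` (`+1`/`-1`), `scheme`, and a `manifest`
#'   data frame (sample_id, scheme, label, seed).
#' @export
generate_cohort <- function(config = cohort_config(),
                            scheme = "zheng_hot_cold") {
  labels <- rep(c(1, -1), times = config$n_per_class)
  n <- length(labels)
  seeds <- (as.numeric(config$seed) * 7919 + seq_len(n) * 104729) %% 2147483647
  ids <- sprintf("s%03d_%s", seq_len(n), ifelse(labels == 1, "pos", "neg"))
  images <- lapply(seq_len(n), function(i)
    generate_tongue(config, labels[i], seed = seeds[i], id = ids[i]))
  structure(list(images = images, labels = labels, scheme = scheme,
                 manifest = data.frame(sample_id = ids, scheme = scheme,
                                       label = labels, seed = seeds)),
            class = "tongue_cohort")
}

#' @export
print.tongue_cohort <- function(x, ...) {
  cat(sprintf("<tongue_cohort '%s': %d images (%d pos / %d neg)>\n",
              x$scheme, length(x$images), sum(x$labels == 1),
              sum(x$labels == -1)))
  invisible(x)
}
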