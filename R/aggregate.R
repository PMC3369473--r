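# Aggregation of per-pixel features into one composite vector per region.
#
# Five variants: mean, median, std (population standard deviation), and the
# two concatenations mean+std and median+std (50 components each,
# average-first).

.AGG_VARIANTS <- c("mean", "median", "std", "mean_std", "median_std")

.check_feature_matrix <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 1L) stop("empty region: no pixels to aggregate")
  features
}

#' Component-wise mean of per-pixel features
#'
#' @param features `N x 25` matrix of per-pixel feature vectors (one row per
#'   pixel), as returned by [extract_pixel_features()].
#' @return Numeric vector of 25 component means.
#' @export
aggregate_mean <- function(features) {
  colMeans(.check_feature_matrix(features))
}

#' Component-wise median of per-pixel features
#'
#' Odd pixel counts use the middle order statistic; even counts the mean of
#' the two central order statistics.
#'
#' @inheritParams aggregate_mean
#' @return Numeric vector of 25 component medians.
#' @export
aggregate_median <- function(features) {
  apply(.check_feature_matrix(features), 2, stats::median)
}

#' Component-wise population standard deviation of per-pixel features
#'
#' Uses the population normalization `sqrt(sum((f - mean)^2) / N)`.
#'
#' @inheritParams aggregate_mean
#' @return Numeric vector of 25 non-negative component spreads.
#' @export
aggregate_std <- function(features) {
  features <- .check_feature_matrix(features)
  mu <- colMeans(features)
  sqrt(colMeans(sweep(features, 2, mu)^2))
}

#' Build one composite feature vector for an image region
#'
#' Extracts per-pixel features over the requested region and collapses them
#' with one of the five aggregation variants. Concatenated variants are
#' average-first, then standard deviation.
#'
#' @param img A [tongue_image()].
#' @param spec A [region_spec()].
#' @param variant One of `"mean"`, `"median"`, `"std"`, `"mean_std"`,
#'   `"median_std"`.
#' @return Named numeric vector of length 25 (single variants) or 50
#'   (concatenated variants), with attributes `variant`, `region_kind` and
#'   `sample_id`. Names use the aggregate prefix, e.g. `sigma_F9_YIQ_Q`,
#'   `med_F12_YCbCr_Cr`.
#' @export
build_feature_vector <- function(img, spec = region_spec("entire"),
                                 variant = .AGG_VARIANTS) {
  variant <- match.arg(variant)
  features <- extract_pixel_features(region_pixels(img, spec))
  nm <- feature_names()
  values <- switch(variant,
    mean       = stats::setNames(aggregate_mean(features), paste0("mu_", nm)),
    median     = stats::setNames(aggregate_median(features), paste0("med_", nm)),
    std        = stats::setNames(aggregate_std(features), paste0("sigma_", nm)),
    mean_std   = c(stats::setNames(aggregate_mean(features), paste0("mu_", nm)),
                   stats::setNames(aggregate_std(features), paste0("sigma_", nm))),
    median_std = c(stats::setNames(aggregate_median(features), paste0("med_", nm)),
                   stats::setNames(aggregate_std(features), paste0("sigma_", nm))))
  structure(values, variant = variant, region_kind = spec$region_kind,
            sample_id = img$id)
}

#' Feature matrix for a list of images
#'
#' Applies [build_feature_vector()] to every image and stacks the results.
#'
#' @param images List of [tongue_image()] objects.
#' @inheritParams build_feature_vector
#' @return `n_images x 25` (or `x 50`) numeric matrix; row names are sample
#'   ids.
#' @export
cohort_features <- function(images, spec = region_spec("entire"),
                            variant = "median_std") {
  res <- t(vapply(images, function(im)
    as.numeric(build_feature_vector(im, spec, variant)),
    numeric(if (variant %in% c("mean_std", "median_std")) 50L else 25L)))
  colnames(res) <- names(build_feature_vector(images[[1]], spec, variant))
  rownames(res) <- vapply(images, function(im) im$id, character(1))
  res
}
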