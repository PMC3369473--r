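# Tongue image container and region geometry.

#' Construct a tongue image
#'
#' Bundles an 8-bit RGB raster with its binary foreground mask. The mask is
#' an input (or, for synthetic images, trivially "not background"); tongue
#' detection/segmentation is out of scope.
#'
#' @param pixels `H x W x 3` numeric array of 8-bit channel values.
#' @param mask `H x W` logical (or 0/1) matrix marking tongue foreground;
#'   must contain at least one foreground pixel.
#' @param id Opaque sample identifier.
#' @return An object of class `tongue_image`.
#' @export
tongue_image <- function(pixels, mask, id = "sample") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array")
  mask <- as.matrix(mask) > 0
  if (!identical(dim(mask), dim(pixels)[1:2]))
    stop("mask dimensions must match pixel dimensions")
  if (!any(mask)) stop("mask must contain at least one foreground pixel")
  structure(list(pixels = pixels, mask = mask, id = id),
            class = "tongue_image")
}

#' @export
print.tongue_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<tongue_image '%s': %d x %d, %d foreground pixels>\n",
              x$id, d[1], d[2], sum(x$mask)))
  invisible(x)
}

#' Specify an analysis region
#'
#' Either the entire tongue foreground or the middle rectangular sub-region
#' of the mask bounding box (the TCM stomach-correspondence area). The middle
#' rectangle is expressed as fractions of the bounding box; the defaults
#' (rows 0.35-0.65, columns 0.30-0.70) approximate the drawn central
#' rectangle and are fully configurable.
#'
#' @param region_kind `"entire"` or `"middle"`.
#' @param middle_fractions Numeric `c(row_lo, row_hi, col_lo, col_hi)`,
#'   each in `[0, 1]` with `lo < hi` on both axes.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(region_kind = c("entire", "middle"),
                        middle_fractions = c(0.35, 0.65, 0.30, 0.70)) {
  region_kind <- match.arg(region_kind)
  f <- as.numeric(middle_fractions)
  if (length(f) != 4L || any(f < 0) || any(f > 1) ||
      f[1] >= f[2] || f[3] >= f[4])
    stop("middle_fractions must satisfy 0 <= lo < hi <= 1 on both axes")
  structure(list(region_kind = region_kind, middle_fractions = f),
            class = "region_spec")
}

#' Tight bounding box of a binary mask
#'
#' @param mask Logical (or 0/1) matrix.
#' @return Integer vector `c(row_min, row_max, col_min, col_max)` using
#'   0-based, half-open indexing (the max side is one past the last
#'   foreground row/column).
#' @export
bounding_box <- function(mask) {
  mask <- as.matrix(mask) > 0
  if (!any(mask)) stop("empty region: mask has no foreground pixels")
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  c(row_min = min(rows) - 1L, row_max = max(rows),
    col_min = min(cols) - 1L, col_max = max(cols))
}

# 0-based half-open index range for one axis of the middle rectangle
.middle_range <- function(lo_frac, hi_frac, box_lo, box_hi) {
  extent <- box_hi - box_lo
  c(box_lo + floor(lo_frac * extent), box_lo + floor(hi_frac * extent))
}

# logical H x W matrix selecting the region's pixels
.region_mask <- function(img, spec) {
  if (spec$region_kind == "entire") return(img$mask)
  bb <- bounding_box(img$mask)
  f <- spec$middle_fractions
  rr <- .middle_range(f[1], f[2], bb[1], bb[2])
  cc <- .middle_range(f[3], f[4], bb[3], bb[4])
  sel <- matrix(FALSE, nrow(img$mask), ncol(img$mask))
  sel[(rr[1] + 1):rr[2], (cc[1] + 1):cc[2]] <- TRUE
  sel & img$mask
}

#' Pixels of an analysis region
#'
#' @param img A [tongue_image()].
#' @param spec A [region_spec()].
#' @return An `N x 3` matrix of raw RGB values, one row per region pixel
#'   (row-major over the image grid).
#' @export
region_pixels <- function(img, spec = region_spec("entire")) {
  stopifnot(inherits(img, "tongue_image"), inherits(spec, "region_spec"))
  sel <- .region_mask(img, spec)
  if (!any(sel))
    stop("empty region: middle rectangle does not intersect the mask")
  idx <- which(sel)
  n <- nrow(img$mask) * ncol(img$mask)
  cbind(R = img$pixels[idx],
        G = img$pixels[idx + n],
        B = img$pixels[idx + 2 * n])
}
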