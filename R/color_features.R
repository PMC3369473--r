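# Per-pixel color-space feature extraction.
#
# All operations accept either a single pixel (length-3 numeric of raw 8-bit
# R,G,B) or an N x 3 matrix of pixels, and are fully vectorized over rows.
# Raw channels are validated to be whole numbers in [0, 255]; all arithmetic
# is double precision; normalization onto [0,1] happens only at output.

.as_pixel_matrix <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) != 3L) stop("a pixel must have exactly 3 channels (R, G, B)")
    p <- matrix(as.numeric(p), nrow = 1L)
  } else {
    p <- as.matrix(p)
    if (ncol(p) != 3L) stop("pixel matrix must have 3 columns (R, G, B)")
    storage.mode(p) <- "double"
  }
  if (anyNA(p) || any(!is.finite(p))) stop("pixel channels must be finite")
  if (any(p < 0 | p > 255)) stop("pixel channels must lie in [0, 255]")
  if (any(p != round(p))) stop("pixel channels must be 8-bit integers")
  p
}

.drop_if_vec <- function(res, p) if (is.null(dim(p))) drop(res) else res

# raw (un-normalized) components of the linear/nonlinear spaces; used by the
# extractor and by the bound-verification oracle in the tests
.raw_yiq <- function(rgb01) rgb01 %*% t(.M_YIQ)
.raw_ycbcr <- function(rgb255) rgb255 %*% t(.M_YCBCR)

.gamma_correct <- function(t) {
  ifelse(t <= 0.04045, t / 12.92, ((t + .GAMMA_A) / (1 + .GAMMA_A))^2.4)
}

.lab_phi <- function(t) {
  ifelse(t > (6 / 29)^3, t^(1 / 3), (1 / 3) * (29 / 6)^2 * t + 4 / 29)
}

.raw_xyz <- function(rgb01) .gamma_correct(rgb01) %*% t(.M_XYZ)

.raw_lab <- function(xyz) {
  fx <- .lab_phi(xyz[, 1] / .D65[1])
  fy <- .lab_phi(xyz[, 2] / .D65[2])
  fz <- .lab_phi(xyz[, 3] / .D65[3])
  cbind(L = 116 * fy - 16, A = 500 * (fx - fy), B = 200 * (fy - fz))
}

.raw_luv <- function(xyz) {
  X <- xyz[, 1]; Y2 <- xyz[, 2]; Z <- xyz[, 3]
  yr <- Y2 / .D65[2]
  L2 <- ifelse(yr <= (6 / 29)^3, (29 / 3)^3 * yr, 116 * yr^(1 / 3) - 16)
  den <- X + 15 * Y2 + 3 * Z
  # L'' = 0 at black forces U = V = 0; also guards the 0/0 chromaticity term
  U <- ifelse(den == 0, 0, 13 * L2 * (4 * X / den - .LUV_K1))
  V <- ifelse(den == 0, 0, 13 * L2 * (9 * Y2 / den - .LUV_K2))
  cbind(L = L2, U = U, V = V)
}

#' RGB features (f1-f3)
#'
#' Normalized channel intensities `r = R/255`, `g = G/255`, `b = B/255`.
#'
#' @param p A length-3 numeric `c(R, G, B)` with 8-bit channels, or an
#'   `N x 3` matrix of such pixels.
#' @return Three values per pixel, each in `[0, 1]`.
#' @export
rgb_features <- function(p) {
  m <- .as_pixel_matrix(p)
  res <- m / 255
  colnames(res) <- c("r", "g", "b")
  .drop_if_vec(res, p)
}

#' HSV features (f4-f6)
#'
#' Hue, saturation and value from normalized RGB. `V` is the channel maximum;
#' `S = (max-min)/max` (0 at black); `H` follows the max-attaining channel
#' with ties broken in R, G, B order, and negative hues from the red branch
#' are wrapped by +1 so `H` lies in `[0, 1)`.
#'
#' @inheritParams rgb_features
#' @return Three values `(H, S, V)` per pixel, each in `[0, 1]`.
#' @export
hsv_features <- function(p) {
  m <- .as_pixel_matrix(p) / 255
  r <- m[, 1]; g <- m[, 2]; b <- m[, 3]
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- mx - mn
  S <- ifelse(mx == 0, 0, d / mx)
  H <- numeric(length(r))
  nz <- d > 0
  red <- nz & (mx == r)
  grn <- nz & !red & (mx == g)
  blu <- nz & !red & !grn
  H[red] <- (g[red] - b[red]) / (6 * d[red])
  H[grn] <- ((b[grn] - r[grn]) / d[grn] + 2) / 6
  H[blu] <- ((r[blu] - g[blu]) / d[blu] + 4) / 6
  H[H < 0] <- H[H < 0] + 1
  res <- cbind(H = H, S = S, V = mx)
  .drop_if_vec(res, p)
}

#' YIQ features (f7-f9)
#'
#' Linear transform of normalized RGB into NTSC luma/chroma; `I` and `Q` are
#' mapped onto `[0, 1]` by their analytic extrema over the RGB cube
#' (`I` in \[-0.596, 0.596\], `Q` in \[-0.523, 0.523\]).
#'
#' @inheritParams rgb_features
#' @return Three normalized values `(y, i, q)` per pixel.
#' @export
yiq_features <- function(p) {
  m <- .as_pixel_matrix(p) / 255
  raw <- .raw_yiq(m)
  bd <- color_bounds()
  res <- cbind(y = .norm_bound(raw[, 1], c(0, 1)),
               i = .norm_bound(raw[, 2], bd$I),
               q = .norm_bound(raw[, 3], bd$Q))
  .drop_if_vec(res, p)
}

#' Y'CbCr features (f10-f12)
#'
#' Linear transform of the raw (unnormalized) 8-bit RGB channels; the printed
#' matrix centers Cb/Cr at 0 (no +128 offset), so both are mapped from
#' \[-127.5, 127.5\] onto `[0, 1]` and Y' from \[0, 255\].
#'
#' @inheritParams rgb_features
#' @return Three normalized values `(y', cb, cr)` per pixel.
#' @export
ycbcr_features <- function(p) {
  m <- .as_pixel_matrix(p)
  raw <- .raw_ycbcr(m)
  bd <- color_bounds()
  res <- cbind(yp = .norm_bound(raw[, 1], bd$Yp),
               cb = .norm_bound(raw[, 2], bd$Cb),
               cr = .norm_bound(raw[, 3], bd$Cr))
  .drop_if_vec(res, p)
}

#' XYZ features (f13-f15)
#'
#' sRGB-style gamma correction (threshold 0.04045, a = 0.055, exponent 2.4)
#' of normalized RGB followed by the CIE XYZ matrix; components mapped onto
#' `[0, 1]` by their row-sum maxima (0.9505, 1, 1.0890).
#'
#' @inheritParams rgb_features
#' @return Three normalized values `(x, y'', z)` per pixel.
#' @export
xyz_features <- function(p) {
  m <- .as_pixel_matrix(p) / 255
  raw <- .raw_xyz(m)
  bd <- color_bounds()
  res <- cbind(x = .norm_bound(raw[, 1], bd$X),
               y2 = .norm_bound(raw[, 2], bd$Y2),
               z = .norm_bound(raw[, 3], bd$Z))
  .drop_if_vec(res, p)
}

#' CIE L*a*b* features (f16-f18)
#'
#' Nonlinear transform of XYZ under the D65 white point
#' `{0.950456, 1, 1.088754}` with the cube-root/linear compression function.
#' `L*` is mapped from \[0, 100\]; `a*`/`b*` by their frozen full-cube
#' extrema (see [color_bounds()]).
#'
#' @inheritParams rgb_features
#' @return Three normalized values `(l*, a, b)` per pixel.
#' @export
lab_features <- function(p) {
  m <- .as_pixel_matrix(p) / 255
  raw <- .raw_lab(.raw_xyz(m))
  bd <- color_bounds()
  res <- cbind(l = .norm_bound(raw[, 1], bd$L_lab),
               a = .norm_bound(raw[, 2], bd$A),
               b = .norm_bound(raw[, 3], bd$B))
  .drop_if_vec(res, p)
}

#' CIE Luv features (f19-f21)
#'
#' Lightness plus the u/v chroma terms computed with the printed constants
#' `k1 = 0.2009`, `k2 = 0.4610` against the D65 white point. At black
#' (`L'' = 0`, denominator 0) u and v are defined as 0.
#'
#' @inheritParams rgb_features
#' @return Three normalized values `(l'', u, v)` per pixel.
#' @export
luv_features <- function(p) {
  m <- .as_pixel_matrix(p) / 255
  raw <- .raw_luv(.raw_xyz(m))
  bd <- color_bounds()
  res <- cbind(l = .norm_bound(raw[, 1], bd$L_luv),
               u = .norm_bound(raw[, 2], bd$U),
               v = .norm_bound(raw[, 3], bd$V))
  .drop_if_vec(res, p)
}

#' CMYK features (f22-f25)
#'
#' Subtractive ink components from normalized RGB: `K = 1 - max(r,g,b)` and
#' `C,M,Y = (max - channel)/max`. At black (`max = 0`) the ink ratios are
#' 0/0 and are defined as `C = M = Y = 0`, `K = 1`.
#'
#' @inheritParams rgb_features
#' @return Four values `(C, M, Y, K)` per pixel, each in `[0, 1]`.
#' @export
cmyk_features <- function(p) {
  m <- .as_pixel_matrix(p) / 255
  mx <- pmax(m[, 1], m[, 2], m[, 3])
  safe <- ifelse(mx == 0, 1, mx)
  C <- ifelse(mx == 0, 0, (mx - m[, 1]) / safe)
  M <- ifelse(mx == 0, 0, (mx - m[, 2]) / safe)
  Y <- ifelse(mx == 0, 0, (mx - m[, 3]) / safe)
  res <- cbind(C = C, M = M, Y = Y, K = 1 - mx)
  .drop_if_vec(res, p)
}

#' Extract the full 25-component per-pixel feature vector
#'
#' Concatenates the eight color-space feature groups in the fixed order
#' RGB, HSV, YIQ, Y'CbCr, XYZ, L*a*b*, Luv, CMYK.
#'
#' @inheritParams rgb_features
#' @return For a single pixel, a named numeric vector of length 25; for an
#'   `N x 3` matrix, an `N x 25` matrix. All values lie in `[0, 1]`.
#'   Columns are named as in [feature_names()].
#' @examples
#' extract_pixel_features(c(200, 150, 100))
#' @export
extract_pixel_features <- function(p) {
  m <- .as_pixel_matrix(p)
  res <- cbind(rgb_features(m), hsv_features(m), yiq_features(m),
               ycbcr_features(m), xyz_features(m), lab_features(m),
               luv_features(m), cmyk_features(m))
  colnames(res) <- feature_names()
  .drop_if_vec(res, p)
}
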