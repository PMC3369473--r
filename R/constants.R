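# Color-space transform constants and normalization bounds.
#
# The signed/linear components are mapped onto [0,1] by fixed affine bounds:
# components with analytic extrema over the 8-bit RGB cube use those extrema;
# the Lab a/b and Luv u/v channels have no closed-form extrema under the
# gamma-corrected transform, so their bounds were computed once by an
# exhaustive scan of the full 8-bit RGB cube and frozen here.  All eight
# extrema are attained on cube edges (two channels pinned at 0 or 255), which
# is what the test-suite oracle re-verifies with an edge-only scan.

.GAMMA_A <- 0.055
.D65 <- c(0.950456, 1.0, 1.088754)
.LUV_K1 <- 0.2009
.LUV_K2 <- 0.4610

.M_YIQ <- matrix(c(
  0.299,  0.587,  0.114,
  0.596, -0.274, -0.322,
  0.211, -0.523,  0.312), nrow = 3, byrow = TRUE)

.M_YCBCR <- matrix(c(
   0.299,  0.587,  0.114,
  -0.169, -0.331,  0.500,
   0.500, -0.419, -0.081), nrow = 3, byrow = TRUE)

.M_XYZ <- matrix(c(
  0.4124, 0.3576, 0.1805,
  0.2126, 0.7152, 0.0722,
  0.0193, 0.1192, 0.9505), nrow = 3, byrow = TRUE)

# Frozen full-cube extrema of Lab A/B and Luv U/V (see header note).
.LAB_A_MIN <- -86.182864231233609
.LAB_A_MAX <-  98.256316290866451
.LAB_B_MIN <- -107.86812851616394
.LAB_B_MAX <-  94.480145106044361
.LUV_U_MIN <- -86.570130928346074
.LUV_U_MAX <-  172.93531047065727
.LUV_V_MIN <- -130.42581779862346
.LUV_V_MAX <-  116.05338398788038

#' Normalization bounds for the raw color-space components
#'
#' Per-component `(min, max)` pairs used to map raw color-space values onto
#' `[0, 1]` via `(x - min) / (max - min)`, clamped.  Components that are
#' already in `[0, 1]` by construction (RGB, HSV, CMYK, the YIQ/XYZ luminance
#' rows) have trivial bounds; signed chroma components use their extrema over
#' the 8-bit RGB cube.
#'
#' @return A named list; each element is `c(min, max)` for one raw component,
#'   named by the component it bounds (`I`, `Q`, `Yp`, `Cb`, `Cr`, `X`,
#'   `Y2`, `Z`, `L_lab`, `A`, `B`, `L_luv`, `U`, `V`).
#' @export
color_bounds <- function() {
  list(
    I     = c(-0.596, 0.596),
    Q     = c(-0.523, 0.523),
    Yp    = c(0, 255),
    Cb    = c(-127.5, 127.5),
    Cr    = c(-127.5, 127.5),
    X     = c(0, 0.9505),
    Y2    = c(0, 1),
    Z     = c(0, 1.0890),
    L_lab = c(0, 100),
    A     = c(.LAB_A_MIN, .LAB_A_MAX),
    B     = c(.LAB_B_MIN, .LAB_B_MAX),
    L_luv = c(0, 100),
    U     = c(.LUV_U_MIN, .LUV_U_MAX),
    V     = c(.LUV_V_MIN, .LUV_V_MAX)
  )
}

#' Descriptive names for the 25 per-pixel features
#'
#' @return Character vector of length 25, e.g. `"F9_YIQ_Q"`, in the fixed
#'   feature order: RGB (1-3), HSV (4-6), YIQ (7-9), Y'CbCr (10-12),
#'   XYZ (13-15), L*a*b* (16-18), Luv (19-21), CMYK (22-25).
#' @export
feature_names <- function() {
  comp <- c("R", "G", "B",
            "H", "S", "V",
            "Y", "I", "Q",
            "Yp", "Cb", "Cr",
            "X", "Y", "Z",
            "L", "a", "b",
            "L", "u", "v",
            "C", "M", "Y", "K")
  space <- rep(c("RGB", "HSV", "YIQ", "YCbCr", "XYZ", "Lab", "Luv", "CMYK"),
               times = c(3, 3, 3, 3, 3, 3, 3, 4))
  sprintf("F%d_%s_%s", seq_len(25), space, comp)
}

# map a raw component vector onto [0,1] by its named bound, clamped
.norm_bound <- function(x, bound) {
  pmin(1, pmax(0, (x - bound[1]) / (bound[2] - bound[1])))
}
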