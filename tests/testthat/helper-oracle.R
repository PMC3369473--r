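# Independent, deliberately literal scalar transcription of the color-space
# formulas, kept free of the package's vectorized code path. Used as the
# double-transcription oracle and (raw components) for the normalization
# bound scan.

oracle_gamma <- function(t) if (t <= 0.04045) t / 12.92 else ((t + 0.055) / 1.055)^2.4
oracle_phi <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else (1 / 3) * (29 / 6)^2 * t + 4 / 29

# raw (un-normalized) components of every space for one pixel
oracle_raw <- function(R, G, B) {
  r <- R / 255; g <- G / 255; b <- B / 255
  mx <- max(r, g, b); mn <- min(r, g, b); dl <- mx - mn
  V <- mx
  S <- if (mx == 0) 0 else dl / mx
  H <- if (dl == 0) 0 else if (mx == r) (g - b) / (6 * dl) else
    if (mx == g) ((b - r) / dl + 2) / 6 else ((r - g) / dl + 4) / 6
  if (H < 0) H <- H + 1
  Y <- 0.299 * r + 0.587 * g + 0.114 * b
  I <- 0.596 * r - 0.274 * g - 0.322 * b
  Q <- 0.211 * r - 0.523 * g + 0.312 * b
  Yp <- 0.299 * R + 0.587 * G + 0.114 * B
  Cb <- -0.169 * R - 0.331 * G + 0.500 * B
  Cr <- 0.500 * R - 0.419 * G - 0.081 * B
  gr <- oracle_gamma(r); gg <- oracle_gamma(g); gb <- oracle_gamma(b)
  X <- 0.4124 * gr + 0.3576 * gg + 0.1805 * gb
  Y2 <- 0.2126 * gr + 0.7152 * gg + 0.0722 * gb
  Z <- 0.0193 * gr + 0.1192 * gg + 0.9505 * gb
  d65 <- c(0.950456, 1.0, 1.088754)
  L <- 116 * oracle_phi(Y2 / d65[2]) - 16
  A <- 500 * (oracle_phi(X / d65[1]) - oracle_phi(Y2 / d65[2]))
  Bb <- 200 * (oracle_phi(Y2 / d65[2]) - oracle_phi(Z / d65[3]))
  yr <- Y2 / d65[2]
  L2 <- if (yr <= (6 / 29)^3) (29 / 3)^3 * yr else 116 * yr^(1 / 3) - 16
  den <- X + 15 * Y2 + 3 * Z
  U <- if (den == 0) 0 else 13 * L2 * (4 * X / den - 0.2009)
  Vl <- if (den == 0) 0 else 13 * L2 * (9 * Y2 / den - 0.4610)
  K <- 1 - mx
  if (mx == 0) { C <- 0; M <- 0; Ys <- 0 } else {
    C <- (mx - r) / mx; M <- (mx - g) / mx; Ys <- (mx - b) / mx
  }
  list(r = r, g = g, b = b, H = H, S = S, V = V,
       Y = Y, I = I, Q = Q, Yp = Yp, Cb = Cb, Cr = Cr,
       X = X, Y2 = Y2, Z = Z, L = L, A = A, Bb = Bb,
       L2 = L2, U = U, Vl = Vl, C = C, M = M, Ys = Ys, K = K)
}

# the 25 normalized features for one pixel, sharing only the frozen bound
# constants with the package
oracle_features <- function(R, G, B) {
  w <- oracle_raw(R, G, B)
  bd <- tonguecolor::color_bounds()
  nb <- function(x, bound) min(1, max(0, (x - bound[1]) / (bound[2] - bound[1])))
  c(w$r, w$g, w$b, w$H, w$S, w$V,
    nb(w$Y, c(0, 1)), nb(w$I, bd$I), nb(w$Q, bd$Q),
    nb(w$Yp, bd$Yp), nb(w$Cb, bd$Cb), nb(w$Cr, bd$Cr),
    nb(w$X, bd$X), nb(w$Y2, bd$Y2), nb(w$Z, bd$Z),
    nb(w$L, bd$L_lab), nb(w$A, bd$A), nb(w$Bb, bd$B),
    nb(w$L2, bd$L_luv), nb(w$U, bd$U), nb(w$Vl, bd$V),
    w$C, w$M, w$Ys, w$K)
}
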