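# Per-pixel color-space features: frozen examples, invariants, and the
# double-transcription oracle.

test_that("RGB, HSV and CMYK features match hand-evaluated examples", {
  expect_equal(rgb_features(c(255, 0, 0)), c(r = 1, g = 0, b = 0))
  expect_equal(rgb_features(c(0, 0, 0)), c(r = 0, g = 0, b = 0))
  expect_equal(rgb_features(c(128, 64, 32)),
               c(r = 128 / 255, g = 64 / 255, b = 32 / 255))

  expect_equal(hsv_features(c(255, 0, 0)), c(H = 0, S = 1, V = 1))
  expect_equal(hsv_features(c(128, 128, 128)),
               c(H = 0, S = 0, V = 128 / 255))
  # green branch: H = ((b - r)/delta + 2)/6 = 2/6
  expect_equal(hsv_features(c(0, 255, 0)), c(H = 2 / 6, S = 1, V = 1))
  # red branch with g < b wraps into [0, 1)
  h <- hsv_features(c(255, 0, 100))[["H"]]
  expect_gte(h, 0.5)
  expect_lt(h, 1)

  expect_equal(cmyk_features(c(255, 255, 255)), c(C = 0, M = 0, Y = 0, K = 0))
  expect_equal(cmyk_features(c(0, 0, 0)), c(C = 0, M = 0, Y = 0, K = 1))
  expect_equal(cmyk_features(c(255, 0, 0)), c(C = 0, M = 1, Y = 1, K = 0))
})

test_that("linear-space features match examples and bound midpoints", {
  # white: YIQ row sums (1, 0, 0); zero chroma maps to bound midpoints
  expect_equal(yiq_features(c(255, 255, 255)), c(y = 1, i = 0.5, q = 0.5))
  expect_equal(yiq_features(c(0, 0, 0)), c(y = 0, i = 0.5, q = 0.5))
  # pure red: raw (Y, I, Q) = first matrix column
  raw <- tonguecolor:::.raw_yiq(matrix(c(1, 0, 0), 1))
  expect_equal(drop(raw), c(0.299, 0.596, 0.211))

  expect_equal(ycbcr_features(c(255, 255, 255)), c(yp = 1, cb = 0.5, cr = 0.5))
  expect_equal(ycbcr_features(c(0, 0, 0)), c(yp = 0, cb = 0.5, cr = 0.5))
  # pure blue: raw Cb = 0.5 * 255 = 127.5 -> normalized 1
  expect_equal(ycbcr_features(c(0, 0, 255))[["cb"]], 1)
  expect_equal(tonguecolor:::.raw_ycbcr(matrix(c(0, 0, 255), 1))[1, 2], 127.5)

  # white: raw XYZ = matrix row sums
  rawx <- tonguecolor:::.raw_xyz(matrix(c(1, 1, 1), 1))
  expect_equal(drop(rawx), c(0.9505, 1.0000, 1.0890), tolerance = 1e-12)
})

test_that("Lab and Luv behave at black and white", {
  # black: L* = 116 * phi(0) - 16 = 0 exactly
  rawlab <- tonguecolor:::.raw_lab(matrix(0, 1, 3))
  expect_equal(unname(rawlab[1, "L"]), 0)
  # white: ratios ~ 1 but not exactly (row sums != D65), so L* near 100
  xyz_w <- tonguecolor:::.raw_xyz(matrix(1, 1, 3))
  rawlab_w <- tonguecolor:::.raw_lab(xyz_w)
  expect_equal(unname(rawlab_w[1, "L"]), 100, tolerance = 0.05)
  expect_lt(abs(rawlab_w[1, "A"]), 0.5)
  expect_lt(abs(rawlab_w[1, "B"]), 0.5)

  rawluv_b <- tonguecolor:::.raw_luv(matrix(0, 1, 3))
  expect_equal(unname(rawluv_b[1, ]), c(0, 0, 0))
  # white-point evaluation of the printed Luv formula
  rawluv_w <- tonguecolor:::.raw_luv(xyz_w)
  X <- xyz_w[1, 1]; Y2 <- xyz_w[1, 2]; Z <- xyz_w[1, 3]
  L <- 116 * (Y2 / 1.0)^(1 / 3) - 16
  den <- X + 15 * Y2 + 3 * Z
  expect_equal(unname(rawluv_w[1, "U"]), 13 * L * (4 * X / den - 0.2009), tolerance = 1e-12)
  expect_equal(unname(rawluv_w[1, "V"]), 13 * L * (9 * Y2 / den - 0.4610), tolerance = 1e-12)
})

test_that("gamma and phi are continuous at their thresholds", {
  # phi is exactly continuous at (6/29)^3 by algebra
  t0 <- (6 / 29)^3
  expect_equal(t0^(1 / 3), (1 / 3) * (29 / 6)^2 * t0 + 4 / 29, tolerance = 1e-12)
  expect_equal(tonguecolor:::.lab_phi(t0 - 1e-15),
               tonguecolor:::.lab_phi(t0 + 1e-15), tolerance = 1e-12)
  # gamma's printed constants leave an intrinsic ~2.3e-9 kink at 0.04045
  # (the exactly-continuous threshold would be ~0.0392857), so continuity
  # holds at 1e-8, not tighter
  g <- tonguecolor:::.gamma_correct
  expect_lt(abs(g(0.04045) - g(0.04045 + 1e-15)), 1e-8)
  expect_equal(g(0.04045), 0.04045 / 12.92, tolerance = 1e-15)
})

test_that("all 25 features lie in [0,1] over a 17^3 RGB grid", {
  lv <- round(seq(0, 255, length.out = 17))
  grid <- as.matrix(expand.grid(R = lv, G = lv, B = lv))
  f <- extract_pixel_features(grid)
  expect_identical(dim(f), c(nrow(grid), 25L))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("achromatic pixels have zero chroma in every space", {
  grays <- cbind(0:255, 0:255, 0:255)
  f <- extract_pixel_features(grays)
  expect_true(all(f[, 4] == 0))                # H
  expect_true(all(f[, 5] == 0))                # S
  expect_true(all(f[, 22:24] == 0))            # C, M, Y
  # raw I, Q, Cb, Cr are 0 -> normalized to the 0.5 midpoint
  expect_equal(unname(f[, 8]), rep(0.5, 256))
  expect_equal(unname(f[, 9]), rep(0.5, 256))
  expect_equal(unname(f[, 11]), rep(0.5, 256), tolerance = 1e-12)
  expect_equal(unname(f[, 12]), rep(0.5, 256), tolerance = 1e-12)
})

test_that("double-transcription oracle agrees to 1e-12 on 10,000 random pixels", {
  set.seed(101)
  pix <- matrix(sample(0:255, 30000, replace = TRUE), ncol = 3)
  f_pkg <- extract_pixel_features(pix)
  f_orc <- t(apply(pix, 1, function(p) oracle_features(p[1], p[2], p[3])))
  expect_lt(max(abs(f_pkg - f_orc)), 1e-12)
})

test_that("frozen normalization bounds match the raw-extrema scan oracle", {
  # every extremum of A, B, U, V over the full 8-bit cube is attained on a
  # cube edge (two channels pinned at 0 or 255); scan all 12 edges
  edges <- list()
  for (e1 in c(0, 255)) for (e2 in c(0, 255)) {
    edges[[length(edges) + 1L]] <- cbind(0:255, e1, e2)
    edges[[length(edges) + 1L]] <- cbind(e1, 0:255, e2)
    edges[[length(edges) + 1L]] <- cbind(e1, e2, 0:255)
  }
  pts <- do.call(rbind, edges)
  raw <- t(apply(pts, 1, function(p) {
    w <- oracle_raw(p[1], p[2], p[3])
    c(A = w$A, B = w$Bb, U = w$U, V = w$Vl, I = w$I, Q = w$Q,
      Cb = w$Cb, Cr = w$Cr)
  }))
  bd <- color_bounds()
  expect_equal(range(raw[, "A"]), bd$A, tolerance = 1e-6)
  expect_equal(range(raw[, "B"]), bd$B, tolerance = 1e-6)
  expect_equal(range(raw[, "U"]), bd$U, tolerance = 1e-6)
  expect_equal(range(raw[, "V"]), bd$V, tolerance = 1e-6)
  expect_equal(range(raw[, "I"]), bd$I, tolerance = 1e-6)
  expect_equal(range(raw[, "Q"]), bd$Q, tolerance = 1e-6)
  expect_equal(range(raw[, "Cb"]), bd$Cb, tolerance = 1e-6)
  expect_equal(range(raw[, "Cr"]), bd$Cr, tolerance = 1e-6)
})

test_that("invalid pixels raise input-domain errors", {
  expect_error(extract_pixel_features(c(-1, 0, 0)), "\\[0, 255\\]")
  expect_error(extract_pixel_features(c(0, 0, 256)), "\\[0, 255\\]")
  expect_error(extract_pixel_features(c(0.5, 0, 0)), "8-bit")
  expect_error(extract_pixel_features(c(NA, 0, 0)), "finite")
  expect_error(rgb_features(c(1, 2)), "3 channels")
})

test_that("single-pixel and matrix paths agree and order is fixed", {
  f <- extract_pixel_features(c(200, 150, 100))
  expect_length(f, 25L)
  expect_identical(names(f), feature_names())
  fm <- extract_pixel_features(rbind(c(200, 150, 100), c(1, 2, 3)))
  expect_equal(unname(fm[1, ]), unname(f))
})
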