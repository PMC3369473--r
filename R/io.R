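# Plain-text raster and manifest I/O.
#
# Images are stored as ASCII netpbm (PPM P3 for RGB, PGM P2 for masks):
# no binary image codec is assumed to be available, and the text formats
# keep fixtures human-readable. Masks use 0 = background, 255 = foreground.

#' Write an RGB image as ASCII PPM (P3)
#'
#' @param pixels `H x W x 3` array of 8-bit values.
#' @param path Output file path.
#' @export
write_ppm <- function(pixels, path) {
  d <- dim(pixels)
  stopifnot(length(d) == 3L, d[3] == 3L)
  # interleave channels row-major: R G B per pixel
  vals <- as.integer(aperm(pixels, c(3, 2, 1)))
  writeLines(c("P3", paste(d[2], d[1]), "255",
               paste(vals, collapse = " ")), path)
  invisible(path)
}

#' Read an ASCII PPM (P3) image
#'
#' @param path File path.
#' @return `H x W x 3` numeric array.
#' @export
read_ppm <- function(path) {
  tok <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (tok[1] != "P3") stop("not an ASCII PPM (P3) file: ", path)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  vals <- as.numeric(tok[-(1:4)])
  stopifnot(length(vals) == h * w * 3)
  aperm(array(vals, dim = c(3, w, h)), c(3, 2, 1))
}

#' Write a binary mask as ASCII PGM (P2)
#'
#' @param mask Logical or 0/1 matrix; foreground is written as 255.
#' @param path Output file path.
#' @export
write_pgm <- function(mask, path) {
  m <- (as.matrix(mask) > 0) * 255L
  writeLines(c("P2", paste(ncol(m), nrow(m)), "255",
               paste(as.integer(t(m)), collapse = " ")), path)
  invisible(path)
}

#' Read an ASCII PGM (P2) mask
#'
#' @param path File path.
#' @return Logical matrix (TRUE = foreground, i.e. value > 0).
#' @export
read_pgm <- function(path) {
  tok <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (tok[1] != "P2") stop("not an ASCII PGM (P2) file: ", path)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  vals <- as.numeric(tok[-(1:4)])
  stopifnot(length(vals) == h * w)
  matrix(vals, nrow = h, byrow = TRUE) > 0
}

#' Write a cohort to disk
#'
#' Writes one PPM image and one PGM mask per sample plus a
#' `manifest.csv` (sample_id, scheme, label, seed, image, mask).
#'
#' @param cohort A `tongue_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tongue_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$image <- paste0(man$sample_id, ".ppm")
  man$mask <- paste0(man$sample_id, "_mask.pgm")
  for (i in seq_along(cohort$images)) {
    write_ppm(cohort$images[[i]]$pixels, file.path(dir, man$image[i]))
    write_pgm(cohort$images[[i]]$mask, file.path(dir, man$mask[i]))
  }
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort from a manifest directory
#'
#' @param dir Directory containing `manifest.csv` and the rasters written
#'   by [write_cohort()].
#' @return A `tongue_cohort`.
#' @export
read_cohort <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  images <- lapply(seq_len(nrow(man)), function(i)
    tongue_image(read_ppm(file.path(dir, man$image[i])),
                 read_pgm(file.path(dir, man$mask[i])),
                 id = man$sample_id[i]))
  structure(list(images = images, labels = man$label,
                 scheme = man$scheme[1], manifest = man),
            class = "tongue_cohort")
}

#' Write aggregate feature vectors as CSV
#'
#' One row per (sample, region, variant): `sample_id`, `region`, `variant`,
#' then the named feature columns in fixed order.
#'
#' @param features Matrix from [cohort_features()].
#' @param region_kind,variant Metadata columns.
#' @param path Output CSV path.
#' @export
write_features_csv <- function(features, region_kind, variant, path) {
  df <- data.frame(sample_id = rownames(features), region = region_kind,
                   variant = variant, features, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
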