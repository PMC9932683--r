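# Collagen-content statistic from brightfield + dual-PLM histology.

#' Histology triplet container
#'
#' One picrosirius-red section imaged three ways: brightfield (tissue bright
#' on dark background, after any polarity inversion on load) and two
#' polarized-light (PLM) images acquired 90 degrees apart, spatially
#' registered and of identical shape. Birefringent collagen appears bright
#' in at least one of the two PLM angles.
#'
#' @param brightfield,plm_0,plm_90 2D numeric matrices of identical shape.
#' @param pixel_size Pixel size, micrometres.
#' @param sample_id,section_id Identifiers.
#' @return An object of class `histology_triplet`.
#' @export
histology_triplet <- function(brightfield, plm_0, plm_90, pixel_size = 6,
                              sample_id = "sample", section_id = "sec1") {
  for (nm in c("brightfield", "plm_0", "plm_90")) {
    img <- get(nm)
    if (!is.matrix(img) || !is.numeric(img)) {
      abort_input(sprintf("`%s` must be a numeric matrix", nm))
    }
  }
  if (!identical(dim(brightfield), dim(plm_0)) ||
      !identical(dim(brightfield), dim(plm_90))) {
    abort_input("the three images must have identical shape")
  }
  check_scalar_number(pixel_size, "pixel_size", positive = TRUE)
  structure(
    list(brightfield = brightfield, plm_0 = plm_0, plm_90 = plm_90,
         pixel_size = pixel_size, sample_id = as.character(sample_id),
         section_id = as.character(section_id)),
    class = "histology_triplet"
  )
}

#' @export
print.histology_triplet <- function(x, ...) {
  d <- dim(x$brightfield)
  cat(sprintf("<histology_triplet '%s'/'%s'> %d x %d px, %g um/px\n",
              x$sample_id, x$section_id, d[1], d[2], x$pixel_size))
  invisible(x)
}

#' Combine the two PLM images
#'
#' Pixelwise maximum of the 0-degree and 90-degree polarized-light images:
#' a birefringent fibre extinguished at one polarizer angle is bright at the
#' other, so the maximum keeps every collagen pixel visible.
#'
#' @param plm_0,plm_90 2D numeric matrices of identical shape.
#' @return A matrix of the same shape.
#' @export
combine_plm <- function(plm_0, plm_90) {
  if (!identical(dim(plm_0), dim(plm_90))) {
    abort_input("PLM images must have identical shape")
  }
  pmax(plm_0, plm_90)
}

#' Otsu threshold of a grayscale image
#'
#' Exhaustive sweep over the image's distinct intensities for the threshold
#' maximizing the between-class variance `w0 * w1 * (mu0 - mu1)^2`, where
#' the classes are `{x < t}` and `{x >= t}`. Exact for any intensity set (no
#' histogram binning).
#'
#' @param image 2D numeric matrix.
#' @return The threshold `t`; foreground is `image >= t`.
#' @export
otsu_threshold <- function(image) {
  vals <- sort(unique(as.vector(image)))
  if (length(vals) < 2L) {
    abort("image has a single intensity; Otsu is undefined - use a fixed threshold",
          class = "arteryct_degenerate_histogram_error")
  }
  counts <- as.numeric(table(factor(as.vector(image), levels = vals)))
  n <- sum(counts)
  csum <- cumsum(counts)
  cmean <- cumsum(counts * vals)
  total_mean <- cmean[length(vals)] / n
  # class 0 = intensities strictly below candidate vals[i+1]
  w0 <- csum[-length(vals)] / n
  mu0 <- cmean[-length(vals)] / csum[-length(vals)]
  w1 <- 1 - w0
  mu1 <- (cmean[length(vals)] - cmean[-length(vals)]) /
    (n - csum[-length(vals)])
  between <- w0 * w1 * (mu0 - mu1)^2
  vals[which.max(between) + 1L]
}

#' Binarize a grayscale image
#'
#' @param image 2D numeric matrix.
#' @param method `"otsu"` (parameter-free, the default) or `"fixed"`.
#' @param threshold Threshold for `method = "fixed"`; foreground is
#'   `image >= threshold`.
#' @return A logical matrix, `TRUE` = white/foreground.
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  if (length(image) == 0L) abort_input("`image` must be non-empty")
  t <- switch(method,
              otsu = otsu_threshold(image),
              fixed = {
                if (is.null(threshold)) {
                  abort_input("`threshold` is required for method = 'fixed'")
                }
                threshold
              })
  image >= t
}

#' Collagen content of a histology triplet
#'
#' The collagen-content statistic: the white-pixel count of the binarized
#' combined PLM image, intersected with the binarized brightfield tissue
#' mask, divided by the white-pixel count of the binarized brightfield image
#' — both restricted to a region of interest. Restricting the numerator to
#' tissue guarantees the ratio lies in `[0, 1]`.
#'
#' @param triplet A [histology_triplet()].
#' @param roi Logical matrix selecting the region of interest; `NULL` means
#'   the full image.
#' @param method,threshold Binarization method, see [binarize()].
#' @param roi_description Free-text label stored with the measurement.
#' @return A one-row tibble with `sample_id`, `section_id`, `roi`,
#'   `collagen_content`, `n_tissue_pixels` and `n_collagen_pixels`.
#' @export
collagen_content <- function(triplet, roi = NULL, method = "otsu",
                             threshold = NULL, roi_description = "full") {
  stopifnot(inherits(triplet, "histology_triplet"))
  shape <- dim(triplet$brightfield)
  if (is.null(roi)) roi <- matrix(TRUE, shape[1], shape[2])
  if (!is.logical(roi) || !identical(dim(roi), shape)) {
    abort_input("`roi` must be a logical matrix matching the image shape")
  }
  tissue <- binarize(triplet$brightfield, method = method,
                     threshold = threshold)
  combined <- binarize(combine_plm(triplet$plm_0, triplet$plm_90),
                       method = method, threshold = threshold)
  n_tissue <- sum(tissue & roi)
  if (n_tissue == 0L) {
    abort("no tissue pixels inside the ROI; collagen content is undefined",
          class = "arteryct_measurement_error")
  }
  n_collagen <- sum(combined & tissue & roi)
  tibble(sample_id = triplet$sample_id, section_id = triplet$section_id,
         roi = roi_description,
         collagen_content = n_collagen / n_tissue,
         n_tissue_pixels = n_tissue, n_collagen_pixels = n_collagen)
}

read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                abort_input(sprintf("unsupported image format '%s'", ext)))
  if (length(dim(img)) == 3L) img <- img[, , 1]  # first channel of RGB(A)
  img * 255
}

write_gray_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  m <- pmin(pmax(img / 255, 0), 1)
  switch(ext,
         png = png::writePNG(m, path),
         tif = ,
         tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L),
         abort_input(sprintf("unsupported image format '%s'", ext)))
  invisible(path)
}

#' Write / read a histology triplet with a JSON manifest
#'
#' Stores the three images as 8-bit grayscale PNG or TIFF plus a
#' `manifest.json` naming the files and recording the pixel size and the
#' brightfield polarity. The collagen statistic presumes tissue = white;
#' slides scanned with dark tissue on a bright background set
#' `invert_brightfield = TRUE` in the manifest and are inverted on load.
#'
#' @param triplet A [histology_triplet()].
#' @param dir Output directory (created if needed).
#' @param format `"png"` or `"tiff"`.
#' @param invert_brightfield Polarity flag recorded in the manifest; when
#'   `TRUE` the brightfield image is stored inverted and re-inverted on
#'   load.
#' @return `write_histology_triplet()` returns the manifest path invisibly;
#'   `read_histology_triplet()` returns a [histology_triplet()].
#' @export
write_histology_triplet <- function(triplet, dir, format = c("png", "tiff"),
                                    invert_brightfield = FALSE) {
  stopifnot(inherits(triplet, "histology_triplet"))
  format <- match.arg(format)
  ext <- if (format == "png") "png" else "tiff"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bf <- if (invert_brightfield) 255 - triplet$brightfield else triplet$brightfield
  files <- c(brightfield = sprintf("brightfield.%s", ext),
             plm_0 = sprintf("plm_000.%s", ext),
             plm_90 = sprintf("plm_090.%s", ext))
  write_gray_image(bf, file.path(dir, files[["brightfield"]]))
  write_gray_image(triplet$plm_0, file.path(dir, files[["plm_0"]]))
  write_gray_image(triplet$plm_90, file.path(dir, files[["plm_90"]]))
  manifest <- list(brightfield = files[["brightfield"]],
                   plm_0 = files[["plm_0"]],
                   plm_90 = files[["plm_90"]],
                   pixel_size_um = triplet$pixel_size,
                   invert_brightfield = invert_brightfield,
                   sample_id = triplet$sample_id,
                   section_id = triplet$section_id)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_histology_triplet
#' @param manifest Path to a `manifest.json`.
#' @export
read_histology_triplet <- function(manifest) {
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  bf <- read_gray_image(file.path(dir, m$brightfield))
  if (isTRUE(m$invert_brightfield)) bf <- 255 - bf
  histology_triplet(bf,
                    read_gray_image(file.path(dir, m$plm_0)),
                    read_gray_image(file.path(dir, m$plm_90)),
                    pixel_size = m$pixel_size_um %||% 6,
                    sample_id = m$sample_id %||% "sample",
                    section_id = m$section_id %||% "sec1")
}
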