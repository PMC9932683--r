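# ROI-based media measurements, line profiles and the display
# window/level transform.

#' Build a disc ROI specification
#'
#' A circular region of interest on one slice, described by its centre (in
#' pixel coordinates, row/column) and radius in pixels. Pixel membership is
#' by pixel-centre distance strictly less than the radius — a fixed
#' rasterization rule so measurements are bit-reproducible.
#'
#' @param slice 1-based slice index.
#' @param row,col ROI centre in pixel coordinates.
#' @param radius Radius in pixels, `>= 1`.
#' @param region Region tag, typically `"internal_media"` or
#'   `"external_media"`.
#' @return A one-row tibble; rows from several calls can be bound into an
#'   ROI table for [media_roi_panel()].
#' @export
roi_disc <- function(slice, row, col, radius, region = NA_character_) {
  check_scalar_number(radius, "radius")
  if (radius < 1) abort_config("`radius` must be >= 1", field = "radius")
  tibble(slice = as.integer(slice), row = as.numeric(row),
         col = as.numeric(col), radius = as.numeric(radius),
         region = as.character(region))
}

disc_pixels <- function(d_slice, row, col, radius) {
  n_row <- d_slice[1]; n_col <- d_slice[2]
  if (row - radius < 0.5 || row + radius > n_row + 0.5 ||
      col - radius < 0.5 || col + radius > n_col + 0.5) {
    abort_input("ROI disc is not fully inside the slice")
  }
  rows <- max(1L, floor(row - radius)):min(n_row, ceiling(row + radius))
  cols <- max(1L, floor(col - radius)):min(n_col, ceiling(col + radius))
  inside <- outer((rows - row)^2, (cols - col)^2, `+`) < radius^2
  list(rows = rows, cols = cols, inside = inside)
}

#' Mean HU inside a disc ROI
#'
#' Arithmetic mean of the HU values of all pixels whose centre lies strictly
#' within `radius` of the ROI centre.
#'
#' @param hu An [hu_volume()].
#' @param slice 1-based slice index.
#' @param center Numeric pair (row, column), pixel coordinates.
#' @param radius Radius in pixels.
#' @return The mean HU (a single number).
#' @export
roi_mean_hu <- function(hu, slice, center, radius) {
  stopifnot(inherits(hu, "hu_volume"))
  d <- dim(hu$hu)
  if (slice < 1 || slice > d[1]) abort_input("`slice` outside the volume")
  px <- disc_pixels(d[2:3], center[1], center[2], radius)
  sl <- hu$hu[slice, px$rows, px$cols, drop = FALSE]
  dim(sl) <- c(length(px$rows), length(px$cols))
  mean(sl[px$inside])
}

#' Internal/external media ROI panel
#'
#' Implements the media sampling protocol: by default three internal-media
#' and three external-media disc ROIs on each of three distinct slices. The
#' grand mean per region is the mean of the contributing ROI means
#' (3 ROIs x 3 slices = 9 by default); every raw ROI mean is retained for
#' audit.
#'
#' @param hu An [hu_volume()].
#' @param rois A tibble of disc ROIs ([roi_disc()] rows) with `region`
#'   values `"internal_media"` and `"external_media"`.
#' @param n_slices,n_per_region Protocol counts; deviations raise a
#'   protocol error listing what is missing.
#' @return An object of class `media_roi_panel`: list with `rois` (per-ROI
#'   tibble including `mean_hu` and `n_pixels`) and `summary` (per-region
#'   tibble with `grand_mean_hu`).
#' @export
media_roi_panel <- function(hu, rois, n_slices = 3L, n_per_region = 3L) {
  stopifnot(inherits(hu, "hu_volume"), is.data.frame(rois))
  regions <- c("internal_media", "external_media")
  problems <- character(0)
  for (reg in regions) {
    sub <- rois[rois$region == reg, , drop = FALSE]
    per_slice <- table(sub$slice)
    if (length(per_slice) != n_slices) {
      problems <- c(problems, sprintf(
        "%s: ROIs on %d distinct slices, protocol requires %d",
        reg, length(per_slice), n_slices))
    }
    bad <- per_slice[per_slice != n_per_region]
    if (length(bad) > 0) {
      problems <- c(problems, sprintf(
        "%s: slice %s has %s ROIs, protocol requires %d",
        reg, names(bad), as.integer(bad), n_per_region))
    }
  }
  if (length(problems) > 0) {
    abort(c("ROI protocol not satisfied:", problems),
          class = "arteryct_protocol_error")
  }
  measured <- rois
  measured$mean_hu <- NA_real_
  measured$n_pixels <- NA_integer_
  for (i in seq_len(nrow(rois))) {
    px <- disc_pixels(dim(hu$hu)[2:3], rois$row[i], rois$col[i],
                      rois$radius[i])
    measured$n_pixels[i] <- sum(px$inside)
    measured$mean_hu[i] <- roi_mean_hu(hu, rois$slice[i],
                                       c(rois$row[i], rois$col[i]),
                                       rois$radius[i])
  }
  summary <- dplyr::summarise(
    dplyr::group_by(measured, .data$region),
    grand_mean_hu = mean(.data$mean_hu),
    n_rois = dplyr::n(),
    n_pixels = sum(.data$n_pixels),
    .groups = "drop"
  )
  structure(list(rois = as_tibble(measured), summary = summary,
                 sample_id = hu$sample_id),
            class = "media_roi_panel")
}

#' @export
print.media_roi_panel <- function(x, ...) {
  cat(sprintf("<media_roi_panel '%s'>\n", x$sample_id))
  print(x$summary)
  invisible(x)
}

#' Automatic placement of internal/external media ROIs
#'
#' Places disc ROIs inside the media label band of each requested slice:
#' internal ROIs at the radial midpoint of the inner third of the band,
#' external ROIs at the midpoint of the outer third, spread in angle (with a
#' seeded random angular offset) and constrained so every disc lies fully
#' within media-labelled pixels. A deterministic, unattended counterpart of
#' drawing the ROIs by hand.
#'
#' @param labels A [layer_labels()] volume.
#' @param slices Slice indices to sample (default three mid-volume slices).
#' @param n_per_region Discs per region per slice.
#' @param radius Disc radius in pixels.
#' @param seed Integer seed for the angular offset.
#' @return A tibble of ROIs suitable for [media_roi_panel()].
#' @export
auto_place_media_rois <- function(labels, slices = NULL, n_per_region = 3L,
                                  radius = 2, seed = 1L) {
  stopifnot(inherits(labels, "layer_labels"))
  d <- dim(labels$labels)
  if (is.null(slices)) {
    mid <- ceiling(d[1] / 2)
    slices <- unique(pmin(pmax(mid + c(-1L, 0L, 1L), 1L), d[1]))
  }
  offset <- with_seed(seed, runif(1, 0, 2 * pi))
  out <- list()
  for (s in slices) {
    media <- labels$labels[s, , ] == 3L
    dim(media) <- d[2:3]
    if (!any(media)) {
      abort(sprintf("no media labels on slice %d", s),
            class = "arteryct_placement_error")
    }
    idx <- which(media, arr.ind = TRUE)
    cr <- mean(idx[, 1]); cc <- mean(idx[, 2])
    rad <- sqrt((idx[, 1] - cr)^2 + (idx[, 2] - cc)^2)
    r_in <- min(rad); r_out <- max(rad)
    thickness <- r_out - r_in
    targets <- c(internal_media = r_in + thickness / 6,
                 external_media = r_in + 5 * thickness / 6)
    for (reg in names(targets)) {
      for (j in seq_len(n_per_region)) {
        base <- offset + 2 * pi * (j - 1) / n_per_region +
          if (reg == "external_media") pi / n_per_region else 0
        placed <- FALSE
        for (delta in seq(0, 2 * pi, by = 2 * pi / 180)) {
          for (sgn in if (delta == 0) 1 else c(1, -1)) {
            a <- base + sgn * delta
            ctr <- round(c(cr + targets[[reg]] * cos(a),
                           cc + targets[[reg]] * sin(a)))
            ok <- tryCatch({
              px <- disc_pixels(d[2:3], ctr[1], ctr[2], radius)
              sl <- media[px$rows, px$cols, drop = FALSE]
              all(sl[px$inside])
            }, arteryct_input_error = function(e) FALSE)
            if (ok) {
              out[[length(out) + 1L]] <-
                roi_disc(s, ctr[1], ctr[2], radius, reg)
              placed <- TRUE
              break
            }
          }
          if (placed) break
        }
        if (!placed) {
          abort(sprintf(
            "could not fit a radius-%g disc inside the %s band on slice %d; try a smaller radius",
            radius, reg, s), class = "arteryct_placement_error")
        }
      }
    }
  }
  dplyr::bind_rows(out)
}

#' HU line profile across a slice
#'
#' Samples the HU field at `n_samples` equally spaced points along the
#' segment from `start` to `end` (pixel coordinates) by bilinear
#' interpolation, reporting positions in micrometres.
#'
#' @param hu An [hu_volume()].
#' @param slice_index 1-based slice index.
#' @param start,end Numeric pairs (row, column) inside the slice.
#' @param n_samples Number of samples, `>= 2`.
#' @return A tibble (class `line_profile`) with columns `position_um` and
#'   `hu`.
#' @export
line_profile <- function(hu, slice_index, start, end, n_samples = 100L) {
  stopifnot(inherits(hu, "hu_volume"))
  d <- dim(hu$hu)
  if (slice_index < 1 || slice_index > d[1]) {
    abort_input("`slice_index` outside the volume")
  }
  for (p in list(start, end)) {
    if (p[1] < 1 || p[1] > d[2] || p[2] < 1 || p[2] > d[3]) {
      abort_input("profile endpoints must lie inside the slice")
    }
  }
  if (n_samples < 2L) abort_input("`n_samples` must be >= 2")
  if (all(start == end)) abort_input("`start` and `end` must differ")
  rows <- seq(start[1], end[1], length.out = n_samples)
  cols <- seq(start[2], end[2], length.out = n_samples)
  sl <- hu$hu[slice_index, , ]
  dim(sl) <- d[2:3]
  vals <- pracma::interp2(x = seq_len(d[3]), y = seq_len(d[2]), Z = sl,
                          xp = cols, yp = rows, method = "linear")
  len_um <- sqrt(((end[1] - start[1]) * hu$voxel_size[["row"]])^2 +
                 ((end[2] - start[2]) * hu$voxel_size[["col"]])^2)
  structure(tibble(position_um = seq(0, len_um, length.out = n_samples),
                   hu = vals),
            class = c("line_profile", class(tibble())))
}

#' Display window/level transform
#'
#' Maps HU onto 8-bit display intensities:
#' `round(clamp((hu - (level - width/2)) / width, 0, 1) * 255)` with
#' round-half-up, so `hu = level` maps to 128 and values at or beyond the
#' window edges clamp to 0 and 255. This is a display mapping only; all
#' quantification runs on HU.
#'
#' @param hu An [hu_volume()] or a numeric array.
#' @param level Window centre, HU.
#' @param width Window width, HU, `> 0`.
#' @return An integer array of display values in `0:255`, same shape.
#' @export
window_level <- function(hu, level, width) {
  if (!is.numeric(width) || length(width) != 1L || width <= 0) {
    abort("`width` must be a single number > 0",
          class = "arteryct_parameter_error")
  }
  x <- if (inherits(hu, "hu_volume")) hu$hu else hu
  d <- pmin(pmax((x - (level - width / 2)) / width, 0), 1)
  out <- as.integer(floor(d * 255 + 0.5))
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}
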