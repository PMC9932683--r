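#' CT volume container
#'
#' A `ct_volume` holds the scanner-side representation of a reconstructed CT
#' scan: the stored (raw) pixel values plus the linear rescale metadata that
#' maps them to Hounsfield Units, and the voxel spacing. The array uses index
#' order (slice, row, column).
#'
#' @param stored_pixels 3D integer array of stored pixel values,
#'   dim = (slices, rows, columns).
#' @param rescale_slope,rescale_intercept Linear rescale metadata:
#'   `HU = stored * slope + intercept`. Slope must be non-zero.
#' @param voxel_size Voxel spacing in micrometres, either a single number
#'   (isotropic) or a length-3 vector ordered (slice, row, column).
#' @param sample_id Free-text sample identifier.
#'
#' @return An object of class `ct_volume`.
#' @seealso [to_hounsfield()], [read_dicom_series()], [write_dicom_series()]
#' @export
ct_volume <- function(stored_pixels, rescale_slope = 1, rescale_intercept = 0,
                      voxel_size = 6, sample_id = "sample") {
  if (!is.array(stored_pixels) || length(dim(stored_pixels)) != 3L ||
      any(dim(stored_pixels) == 0L)) {
    abort_input("`stored_pixels` must be a non-empty 3D array")
  }
  check_scalar_number(rescale_slope, "rescale_slope")
  if (rescale_slope == 0) {
    abort("`rescale_slope` must be non-zero", class = "arteryct_metadata_error")
  }
  check_scalar_number(rescale_intercept, "rescale_intercept")
  voxel_size <- expand_voxel_size(voxel_size)
  structure(
    list(stored_pixels = stored_pixels,
         rescale_slope = rescale_slope,
         rescale_intercept = rescale_intercept,
         voxel_size = voxel_size,
         sample_id = as.character(sample_id)),
    class = "ct_volume"
  )
}

expand_voxel_size <- function(voxel_size) {
  if (!is.numeric(voxel_size) || !length(voxel_size) %in% c(1L, 3L) ||
      any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    abort_config("`voxel_size` must be 1 or 3 positive micrometre values",
                 field = "voxel_size")
  }
  vs <- if (length(voxel_size) == 1L) rep(voxel_size, 3L) else voxel_size
  names(vs) <- c("slice", "row", "col")
  vs
}

#' Hounsfield-unit volume container
#'
#' @param hu 3D numeric array of Hounsfield Units, dim = (slices, rows,
#'   columns); all values must be finite.
#' @inheritParams ct_volume
#' @return An object of class `hu_volume`.
#' @export
hu_volume <- function(hu, voxel_size = 6, sample_id = "sample") {
  if (!is.array(hu) || length(dim(hu)) != 3L || any(dim(hu) == 0L)) {
    abort_input("`hu` must be a non-empty 3D array")
  }
  if (any(!is.finite(hu))) {
    abort_input("`hu` must contain only finite values")
  }
  structure(
    list(hu = hu, voxel_size = expand_voxel_size(voxel_size),
         sample_id = as.character(sample_id)),
    class = "hu_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$stored_pixels)
  cat(sprintf("<ct_volume '%s'> %d x %d x %d stored pixels, slope %g, intercept %g, voxel %s um\n",
              x$sample_id, d[1], d[2], d[3], x$rescale_slope,
              x$rescale_intercept, paste(x$voxel_size, collapse = " x ")))
  invisible(x)
}

#' @export
print.hu_volume <- function(x, ...) {
  d <- dim(x$hu)
  cat(sprintf("<hu_volume '%s'> %d x %d x %d, HU range [%.1f, %.1f], voxel %s um\n",
              x$sample_id, d[1], d[2], d[3], min(x$hu), max(x$hu),
              paste(x$voxel_size, collapse = " x ")))
  invisible(x)
}

#' Convert stored pixel values to Hounsfield Units
#'
#' Applies the affine rescale defined by the volume's metadata,
#' `HU = stored_pixels * rescale_slope + rescale_intercept`, elementwise.
#' Shape and voxel spacing are preserved. The transform is invertible given
#' the metadata, so stored pixels can be recovered exactly (before any
#' re-quantization).
#'
#' @param vol A [ct_volume()].
#' @return An [hu_volume()] of the same shape.
#' @examples
#' vol <- ct_volume(array(1500L, c(2, 4, 4)), rescale_slope = 1,
#'                  rescale_intercept = -1000)
#' range(to_hounsfield(vol)$hu)  # 500 500
#' @export
to_hounsfield <- function(vol) {
  stopifnot(inherits(vol, "ct_volume"))
  if (vol$rescale_slope == 0) {
    abort("rescale slope of 0 cannot be inverted",
          class = "arteryct_metadata_error")
  }
  hu_volume(vol$stored_pixels * vol$rescale_slope + vol$rescale_intercept,
            voxel_size = vol$voxel_size, sample_id = vol$sample_id)
}

#' Write / read a CT volume as a raw file plus JSON sidecar
#'
#' A minimal container used as a test- and interchange-friendly fallback to a
#' DICOM series: stored pixels as little-endian unsigned 16-bit raw data plus
#' a JSON sidecar holding the shape, rescale metadata, spacing and sample id.
#'
#' @param vol A [ct_volume()]; stored pixels must lie in `[0, 65535]`.
#' @param prefix File path prefix; writes `<prefix>.raw` and `<prefix>.json`.
#' @return `write_ct_sidecar()` returns `prefix` invisibly;
#'   `read_ct_sidecar()` returns a [ct_volume()].
#' @export
write_ct_sidecar <- function(vol, prefix) {
  stopifnot(inherits(vol, "ct_volume"))
  px <- as.integer(vol$stored_pixels)
  if (any(px < 0L) || any(px > 65535L)) {
    abort_input("stored pixels must be in [0, 65535] for 16-bit raw output")
  }
  writeBin(uint16_le(px), paste0(prefix, ".raw"))
  meta <- list(shape = dim(vol$stored_pixels),
               rescale_slope = vol$rescale_slope,
               rescale_intercept = vol$rescale_intercept,
               voxel_size_um = unname(vol$voxel_size),
               sample_id = vol$sample_id,
               dtype = "uint16le")
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_ct_sidecar
#' @export
read_ct_sidecar <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- prod(meta$shape)
  raw <- readBin(paste0(prefix, ".raw"), "raw", n = 2L * n)
  px <- readBin(raw, "integer", n = n, size = 2L, signed = FALSE,
                endian = "little")
  ct_volume(array(px, dim = meta$shape),
            rescale_slope = meta$rescale_slope,
            rescale_intercept = meta$rescale_intercept,
            voxel_size = meta$voxel_size_um,
            sample_id = meta$sample_id)
}

# Pack integers in [0, 65535] as little-endian uint16 raw bytes.
uint16_le <- function(x) {
  as.raw(rbind(x %% 256L, x %/% 256L))
}
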