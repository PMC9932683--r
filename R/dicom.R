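# Minimal single-frame DICOM series I/O (Explicit VR Little Endian,
# uncompressed, one CT slice per file). Covers exactly the subset of the
# standard this pipeline needs: 16-bit unsigned monochrome pixel data plus
# the geometry and rescale tags quantification depends on. Multi-frame
# objects and compressed transfer syntaxes are out of scope.

TRANSFER_SYNTAX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_CLASS_CT <- "1.2.840.10008.5.1.4.1.1.2"
IMPLEMENTATION_UID <- "1.2.826.0.1.3680043.9590.1"

raw_u16 <- function(x) as.raw(c(x %% 256L, (x %/% 256L) %% 256L))
raw_u32 <- function(x) {
  as.raw(c(x %% 256L, (x %/% 256L) %% 256L,
           (x %/% 65536L) %% 256L, (x %/% 16777216L) %% 256L))
}

# VRs that use the 4-byte "long" length form in explicit VR encoding.
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_element <- function(group, elem, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(value)
    if (length(value) %% 2L == 1L) {
      pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
      value <- c(value, pad)
    }
  }
  stopifnot(length(value) %% 2L == 0L)
  head_ <- c(raw_u16(group), raw_u16(elem), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(head_, as.raw(c(0L, 0L)), raw_u32(length(value)), value)
  } else {
    c(head_, raw_u16(length(value)), value)
  }
}

dcm_ds <- function(x) paste(vapply(x, function(v) sprintf("%.10g", v),
                                   character(1)), collapse = "\\")

#' Write a CT volume as a DICOM series
#'
#' Writes one single-frame, uncompressed, Explicit VR Little Endian CT slice
#' per file (`slice_0001.dcm`, ...), populating Rows/Columns, PixelSpacing and
#' SliceThickness (converted from micrometres to the millimetres DICOM
#' expects), ImagePositionPatient, InstanceNumber, RescaleSlope and
#' RescaleIntercept, and 16-bit unsigned pixel data.
#'
#' @param vol A [ct_volume()]; stored pixels must lie in `[0, 65535]`.
#' @param dir Output directory (created if needed).
#' @param series_number Integer series number written to the headers.
#' @return The vector of file paths written, invisibly.
#' @seealso [read_dicom_series()]
#' @export
write_dicom_series <- function(vol, dir, series_number = 1L) {
  stopifnot(inherits(vol, "ct_volume"))
  px <- vol$stored_pixels
  if (any(px < 0) || any(px > 65535) || any(px != round(px))) {
    abort_input("stored pixels must be integers in [0, 65535]")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(px)
  n_slices <- d[1]; n_rows <- d[2]; n_cols <- d[3]
  spacing_mm <- vol$voxel_size / 1000
  paths <- character(n_slices)
  for (k in seq_len(n_slices)) {
    z_mm <- (k - 1L) * spacing_mm[["slice"]]
    sop_instance <- sprintf("%s.%d.%d", IMPLEMENTATION_UID, series_number, k)
    # image pixel data, row-major as DICOM requires
    slice <- px[k, , , drop = TRUE]
    pix_raw <- uint16_le(as.integer(t(slice)))
    body <- c(
      dcm_element(0x0008L, 0x0016L, "UI", SOP_CLASS_CT),
      dcm_element(0x0008L, 0x0018L, "UI", sop_instance),
      dcm_element(0x0008L, 0x0060L, "CS", "CT"),
      dcm_element(0x0010L, 0x0020L, "LO", vol$sample_id),
      dcm_element(0x0018L, 0x0050L, "DS", dcm_ds(spacing_mm[["slice"]])),
      dcm_element(0x0020L, 0x0011L, "IS", as.character(series_number)),
      dcm_element(0x0020L, 0x0013L, "IS", as.character(k)),
      dcm_element(0x0020L, 0x0032L, "DS", dcm_ds(c(0, 0, z_mm))),
      dcm_element(0x0020L, 0x1041L, "DS", dcm_ds(z_mm)),
      dcm_element(0x0028L, 0x0002L, "US", raw_u16(1L)),
      dcm_element(0x0028L, 0x0004L, "CS", "MONOCHROME2"),
      dcm_element(0x0028L, 0x0010L, "US", raw_u16(n_rows)),
      dcm_element(0x0028L, 0x0011L, "US", raw_u16(n_cols)),
      dcm_element(0x0028L, 0x0030L, "DS",
                  dcm_ds(c(spacing_mm[["row"]], spacing_mm[["col"]]))),
      dcm_element(0x0028L, 0x0100L, "US", raw_u16(16L)),
      dcm_element(0x0028L, 0x0101L, "US", raw_u16(16L)),
      dcm_element(0x0028L, 0x0102L, "US", raw_u16(15L)),
      dcm_element(0x0028L, 0x0103L, "US", raw_u16(0L)),
      dcm_element(0x0028L, 0x1052L, "DS", dcm_ds(vol$rescale_intercept)),
      dcm_element(0x0028L, 0x1053L, "DS", dcm_ds(vol$rescale_slope)),
      dcm_element(0x7FE0L, 0x0010L, "OW", pix_raw)
    )
    meta <- c(
      dcm_element(0x0002L, 0x0001L, "OB", as.raw(c(0L, 1L))),
      dcm_element(0x0002L, 0x0002L, "UI", SOP_CLASS_CT),
      dcm_element(0x0002L, 0x0003L, "UI", sop_instance),
      dcm_element(0x0002L, 0x0010L, "UI", TRANSFER_SYNTAX_EXPLICIT_LE),
      dcm_element(0x0002L, 0x0012L, "UI", IMPLEMENTATION_UID)
    )
    meta <- c(dcm_element(0x0002L, 0x0000L, "UL", raw_u32(length(meta))), meta)
    path <- file.path(dir, sprintf("slice_%04d.dcm", k))
    con <- file(path, "wb")
    writeBin(c(as.raw(rep(0L, 128L)), charToRaw("DICM"), meta, body), con)
    close(con)
    paths[k] <- path
  }
  invisible(paths)
}

read_u16 <- function(bytes, at) {
  as.integer(bytes[at]) + 256L * as.integer(bytes[at + 1L])
}
read_u32 <- function(bytes, at) {
  as.integer(bytes[at]) + 256 * as.integer(bytes[at + 1L]) +
    65536 * as.integer(bytes[at + 2L]) + 16777216 * as.integer(bytes[at + 3L])
}

# Parse one Explicit VR Little Endian file into a named list of the tags the
# pipeline uses; unknown tags are skipped by their declared length.
parse_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 140L ||
      rawToChar(bytes[129:132]) != "DICM") {
    abort(sprintf("'%s' is not a DICOM part-10 file", path),
          class = "arteryct_format_error")
  }
  pos <- 133L
  out <- list(path = path)
  n <- length(bytes)
  while (pos + 8L <= n + 1L) {
    group <- read_u16(bytes, pos)
    elem <- read_u16(bytes, pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% LONG_VRS) {
      len <- read_u32(bytes, pos + 8L)
      val_at <- pos + 12L
    } else {
      len <- read_u16(bytes, pos + 6L)
      val_at <- pos + 8L
    }
    val <- if (len > 0L) bytes[val_at:(val_at + len - 1L)] else raw(0)
    key <- sprintf("%04X%04X", group, elem)
    str_val <- function() trimws(rawToChar(val[val != as.raw(0L)]))
    ds_val <- function() as.numeric(strsplit(str_val(), "\\\\")[[1]])
    if (key == "00280010") out$rows <- read_u16(val, 1L)
    else if (key == "00280011") out$cols <- read_u16(val, 1L)
    else if (key == "00280100") out$bits_allocated <- read_u16(val, 1L)
    else if (key == "00280103") out$pixel_representation <- read_u16(val, 1L)
    else if (key == "00280030") out$pixel_spacing_mm <- ds_val()
    else if (key == "00180050") out$slice_thickness_mm <- ds_val()[1]
    else if (key == "00200032") out$image_position_mm <- ds_val()
    else if (key == "00201041") out$slice_location_mm <- ds_val()[1]
    else if (key == "00200013") out$instance_number <- as.integer(str_val())
    else if (key == "00281052") out$rescale_intercept <- ds_val()[1]
    else if (key == "00281053") out$rescale_slope <- ds_val()[1]
    else if (key == "00100020") out$patient_id <- str_val()
    else if (key == "7FE00010") out$pixel_bytes <- val
    pos <- val_at + len
  }
  if (is.null(out$rows) || is.null(out$cols) || is.null(out$pixel_bytes)) {
    abort(sprintf("'%s' lacks image pixel data", path),
          class = "arteryct_format_error")
  }
  out
}

#' Read a DICOM series into a CT volume
#'
#' Reads every single-frame slice in a directory, orders slices by the z
#' component of ImagePositionPatient (falling back to SliceLocation, then
#' InstanceNumber, so the on-disk file order is irrelevant), stacks them into
#' a (slice, row, column) array and carries the rescale metadata along.
#' Missing RescaleSlope/RescaleIntercept default to 1 and 0 with a warning.
#'
#' @param dir Directory containing `.dcm` files (one slice each).
#' @return A [ct_volume()]. Voxel spacing is derived from PixelSpacing and
#'   the inter-slice position step (SliceThickness for a single slice),
#'   converted to micrometres.
#' @export
read_dicom_series <- function(dir) {
  if (!dir.exists(dir)) abort_input(sprintf("no such directory: '%s'", dir))
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0L) files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) {
    abort_input(sprintf("no DICOM slices found in '%s'", dir))
  }
  slices <- lapply(files, parse_dicom_file)
  shapes <- vapply(slices, function(s) c(s$rows, s$cols), integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1])) {
    abort("slices in the series have inconsistent image sizes",
          class = "arteryct_format_error")
  }
  key <- vapply(slices, function(s) {
    if (!is.null(s$image_position_mm)) s$image_position_mm[3]
    else if (!is.null(s$slice_location_mm)) s$slice_location_mm
    else if (!is.null(s$instance_number)) as.numeric(s$instance_number)
    else NA_real_
  }, numeric(1))
  if (any(is.na(key))) {
    abort("slices lack position and instance-number tags; cannot order them",
          class = "arteryct_format_error")
  }
  slices <- slices[order(key)]
  key <- sort(key)

  first <- slices[[1]]
  slope <- first$rescale_slope
  intercept <- first$rescale_intercept
  if (is.null(slope) || is.null(intercept)) {
    warn("rescale metadata missing; defaulting to slope 1, intercept 0")
    slope <- slope %||% 1
    intercept <- intercept %||% 0
  }
  spacing_mm <- first$pixel_spacing_mm %||% c(1, 1)
  slice_step_mm <- if (length(slices) > 1L &&
                       !is.null(first$image_position_mm)) {
    stats::median(diff(key))
  } else {
    first$slice_thickness_mm %||% 1
  }

  n_rows <- first$rows; n_cols <- first$cols
  vol <- array(0L, dim = c(length(slices), n_rows, n_cols))
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    px <- readBin(s$pixel_bytes, "integer", n = n_rows * n_cols, size = 2L,
                  signed = FALSE, endian = "little")
    vol[k, , ] <- matrix(px, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  }
  ct_volume(vol, rescale_slope = slope, rescale_intercept = intercept,
            voxel_size = c(slice_step_mm * 1000, spacing_mm[1] * 1000,
                           spacing_mm[2] * 1000),
            sample_id = first$patient_id %||% "sample")
}
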