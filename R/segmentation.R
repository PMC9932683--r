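# HU-interval segmentation of the vessel wall and seeded region growing.

#' Layer label volume
#'
#' Per-voxel categorical labels over background, lumen, intima, media and
#' adventitia, stored as an integer array (0 = background ... 4 =
#' adventitia) with the voxel spacing attached.
#'
#' @param labels 3D integer array with values in `0:4`, or a character array
#'   of layer names.
#' @param voxel_size Voxel spacing in micrometres (scalar or length 3).
#' @return An object of class `layer_labels`.
#' @export
layer_labels <- function(labels, voxel_size = 6) {
  if (is.character(labels)) {
    idx <- match(labels, LAYERS) - 1L
    if (any(is.na(idx))) abort_input("unknown layer name in `labels`")
    labels <- array(idx, dim = dim(labels))
  }
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    abort_input("`labels` must be a 3D array")
  }
  if (any(!labels %in% 0:4)) {
    abort_input("`labels` must take values in 0:4 (background..adventitia)")
  }
  structure(list(labels = labels, voxel_size = expand_voxel_size(voxel_size)),
            class = "layer_labels")
}

#' @export
print.layer_labels <- function(x, ...) {
  d <- dim(x$labels)
  counts <- tabulate(x$labels + 1L, nbins = 5L)
  cat(sprintf("<layer_labels> %d x %d x %d\n", d[1], d[2], d[3]))
  print(stats::setNames(counts, LAYERS))
  invisible(x)
}

#' Per-layer HU intervals
#'
#' Half-open HU intervals `[low, high)` for each wall layer. A voxel whose
#' HU falls in no interval is background; where intervals overlap, the later
#' layer in `priority` wins (default: denser-staining layers take
#' precedence, adventitia > media > intima > lumen). A value exactly at the
#' shared boundary of two adjacent intervals belongs to the upper interval
#' by the half-open convention.
#'
#' @param lumen,intima,media,adventitia Length-2 numeric `(low, high)` HU
#'   intervals with `low < high`.
#' @return An object of class `layer_thresholds`.
#' @seealso [default_layer_thresholds()]
#' @export
layer_thresholds <- function(lumen, intima, media, adventitia) {
  iv <- list(lumen = lumen, intima = intima, media = media,
             adventitia = adventitia)
  for (nm in names(iv)) {
    v <- iv[[nm]]
    if (!is.numeric(v) || length(v) != 2L || any(!is.finite(v)) ||
        v[1] >= v[2]) {
      abort_config(sprintf("`%s` must be (low, high) with low < high", nm),
                   field = nm)
    }
  }
  structure(iv, class = "layer_thresholds")
}

#' Uncalibrated default thresholds derived from a phantom specification
#'
#' Builds per-layer HU intervals at the midpoints between the HU bands a
#' [phantom_spec()] implies (the media band spans its collagen gradient).
#' These are *uncalibrated* defaults tied to the synthetic phantom's
#' attenuation model, not scanner-calibrated values: thresholds for real
#' acquisitions are configuration that must be established per staining and
#' imaging protocol.
#'
#' @param spec A [phantom_spec()].
#' @return A [layer_thresholds()].
#' @export
default_layer_thresholds <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  m <- spec$layer_mean_hu
  g <- sort(spec$media_collagen_gradient)
  media_band <- m[["media"]] + spec$hu_per_collagen * g
  bands <- rbind(background = c(m[["background"]], m[["background"]]),
                 lumen = c(m[["lumen"]], m[["lumen"]]),
                 intima = c(m[["intima"]], m[["intima"]]),
                 media = media_band,
                 adventitia = c(m[["adventitia"]], m[["adventitia"]]))
  cuts <- vapply(1:4, function(i) mean(c(bands[i, 2], bands[i + 1, 1])),
                 numeric(1))
  top <- unname(bands[5, 2] + (bands[5, 2] - cuts[4]))
  layer_thresholds(lumen = unname(c(cuts[1], cuts[2])),
                   intima = unname(c(cuts[2], cuts[3])),
                   media = unname(c(cuts[3], cuts[4])),
                   adventitia = c(cuts[4], top))
}

#' Classify voxels into wall layers by HU intervals
#'
#' Assigns each voxel the layer whose half-open HU interval `[low, high)`
#' contains its value; voxels in no interval become background. Overlapping
#' intervals are resolved by a fixed priority order (last element of
#' `priority` wins).
#'
#' @param hu An [hu_volume()].
#' @param thresholds A [layer_thresholds()].
#' @param priority Character vector ordering the four wall layers from
#'   lowest to highest precedence.
#' @param majority_filter Apply the optional 3x3x3 majority-vote cleanup
#'   after classification (off by default; an explicit, automated stand-in
#'   for interactive cleanup).
#' @return A [layer_labels()] volume partitioning every voxel.
#' @export
classify_by_threshold <- function(hu, thresholds,
                                  priority = c("lumen", "intima", "media",
                                               "adventitia"),
                                  majority_filter = FALSE) {
  stopifnot(inherits(hu, "hu_volume"), inherits(thresholds, "layer_thresholds"))
  if (!setequal(priority, c("lumen", "intima", "media", "adventitia"))) {
    abort_config("`priority` must order exactly the four wall layers")
  }
  lab <- array(0L, dim = dim(hu$hu))
  for (layer in priority) {
    iv <- thresholds[[layer]]
    lab[hu$hu >= iv[1] & hu$hu < iv[2]] <- match(layer, LAYERS) - 1L
  }
  out <- layer_labels(lab, voxel_size = hu$voxel_size)
  if (majority_filter) out <- majority_filter(out)
  out
}

#' 3x3x3 majority-vote label cleanup
#'
#' Replaces each voxel's label by the most frequent label in its (clipped)
#' 3x3x3 neighbourhood; ties keep the centre label when it is among the
#' modes. A deterministic, automated counterpart of the manual cleanup an
#' interactive segmentation workflow would apply.
#'
#' @param labels A [layer_labels()] volume.
#' @return A [layer_labels()] volume.
#' @export
majority_filter <- function(labels) {
  stopifnot(inherits(labels, "layer_labels"))
  filtered <- majority_filter3d(as.integer(labels$labels),
                                dim(labels$labels), 5L)
  layer_labels(array(filtered, dim = dim(labels$labels)),
               voxel_size = labels$voxel_size)
}

#' Seeded region growing on an HU volume
#'
#' Returns the connected component, under 6- or 26-connectivity, of the set
#' of voxels whose HU lies in the half-open interval `[low, high)`, that
#' contains the seed voxel — the automated equivalent of an interactive
#' "grow region of interest" tool.
#'
#' @param hu An [hu_volume()].
#' @param seed Integer triple (slice, row, column), 1-based, inside the
#'   volume; its HU must lie in `interval`.
#' @param interval Length-2 numeric `(low, high)` HU interval.
#' @param connectivity 6 (faces only, the conservative default) or 26.
#' @return A logical 3D mask, a subset of the thresholded voxel set.
#' @export
grow_region <- function(hu, seed, interval, connectivity = 6) {
  stopifnot(inherits(hu, "hu_volume"))
  d <- dim(hu$hu)
  if (!is.numeric(seed) || length(seed) != 3L || any(seed < 1) ||
      any(seed > d)) {
    abort_input("`seed` must be a (slice, row, column) triple inside the volume")
  }
  if (!is.numeric(interval) || length(interval) != 2L ||
      interval[1] >= interval[2]) {
    abort_input("`interval` must be (low, high) with low < high")
  }
  if (!connectivity %in% c(6, 26)) {
    abort_input("`connectivity` must be 6 or 26")
  }
  seed <- as.integer(seed)
  seed_hu <- hu$hu[seed[1], seed[2], seed[3]]
  if (seed_hu < interval[1] || seed_hu >= interval[2]) {
    abort(sprintf("seed HU (%.1f) lies outside the interval [%g, %g)",
                  seed_hu, interval[1], interval[2]),
          class = "arteryct_seed_error")
  }
  in_interval <- hu$hu >= interval[1] & hu$hu < interval[2]
  mask <- flood_fill3d(as.logical(in_interval), d, seed,
                       as.integer(connectivity))
  array(mask, dim = d)
}

#' Per-layer volumes in cubic millimetres
#'
#' @param labels A [layer_labels()] volume.
#' @return A tibble with columns `layer`, `n_voxels` and `volume_mm3`
#'   (voxel count times voxel volume). The wall tissue volume is the sum
#'   over intima, media and adventitia; see [tissue_volume()].
#' @export
layer_volumes <- function(labels) {
  stopifnot(inherits(labels, "layer_labels"))
  voxel_mm3 <- prod(labels$voxel_size) * 1e-9  # um^3 -> mm^3
  counts <- tabulate(labels$labels + 1L, nbins = 5L)
  tibble(layer = LAYERS, n_voxels = counts, volume_mm3 = counts * voxel_mm3)
}

#' @rdname layer_volumes
#' @export
tissue_volume <- function(labels) {
  vols <- if (inherits(labels, "layer_labels")) layer_volumes(labels) else labels
  sum(vols$volume_mm3[vols$layer %in% TISSUE_LAYERS])
}

#' Dice overlap coefficient between two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty. Used to validate segmentations against phantom ground truth.
#'
#' @param mask_a,mask_b Logical arrays of identical shape.
#' @return A number in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) {
    abort_input("masks must have identical shape")
  }
  na <- sum(mask_a); nb <- sum(mask_b)
  if (na + nb == 0) return(1)
  2 * sum(mask_a & mask_b) / (na + nb)
}

#' Per-layer Dice against a reference labelling
#'
#' @param labels,reference [layer_labels()] volumes of identical shape.
#' @param layers Which layers to score.
#' @return A tibble with columns `layer` and `dice`.
#' @export
layer_dice <- function(labels, reference, layers = LAYERS) {
  stopifnot(inherits(labels, "layer_labels"),
            inherits(reference, "layer_labels"))
  if (!identical(dim(labels$labels), dim(reference$labels))) {
    abort_input("label volumes must have identical shape")
  }
  tibble(
    layer = layers,
    dice = vapply(unname(layers), function(l) {
      code <- match(l, LAYERS) - 1L
      dice(labels$labels == code, reference$labels == code)
    }, numeric(1), USE.NAMES = FALSE)
  )
}

#' Read / write layer thresholds as JSON
#'
#' @param thresholds A [layer_thresholds()].
#' @param path JSON file path.
#' @return `write_layer_thresholds()` returns `path` invisibly;
#'   `read_layer_thresholds()` returns a [layer_thresholds()].
#' @export
write_layer_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "layer_thresholds"))
  jsonlite::write_json(unclass(thresholds), path, digits = NA)
  invisible(path)
}

#' @rdname write_layer_thresholds
#' @export
read_layer_thresholds <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  layer_thresholds(lumen = x$lumen, intima = x$intima, media = x$media,
                   adventitia = x$adventitia)
}
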