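# Synthetic CE-uCT vessel phantoms with known ground truth.
#
# The phantom is a layered cylinder (lumen / intima / media / adventitia on
# an ethanol background) whose media attenuation rises radially with a
# planted collagen-density field, mimicking a phosphotungstic-acid stain
# that binds preferentially to collagen. It is the test bed for every
# downstream stage: segmentation, ROI statistics and the imaging-histology
# correlation all have exact ground truth here.

PLM_BRIGHT <- 240
PLM_DARK <- 15
BF_TISSUE <- 230
BF_BACKGROUND <- 10

#' Specification of a synthetic vessel CT phantom
#'
#' Defines the geometry, attenuation model and acquisition surrogates for a
#' layered cylindrical vessel phantom. Per-voxel noiseless attenuation is
#' `layer_mean_hu[layer] + hu_per_collagen * collagen`, where the collagen
#' fraction interpolates linearly with radius across the media (from the
#' internal- to the external-media value of `media_collagen_gradient`) and is
#' zero elsewhere. Gaussian blur (a partial-volume surrogate) is applied
#' before additive Gaussian noise; stored pixels are
#' `round((HU - rescale_intercept) / rescale_slope)`, clipped to unsigned
#' 16-bit range.
#'
#' Default geometry is a vessel scaled to fit a small grid at the scanner's
#' 6 um isotropic voxel size; all radii are in micrometres and must be
#' strictly increasing, with the adventitia fitting inside the grid.
#'
#' @param grid_shape Integer triple (slices, rows, columns).
#' @param voxel_size Isotropic voxel size, micrometres.
#' @param lumen_radius,intima_outer_radius,media_outer_radius,adventitia_outer_radius
#'   Layer boundary radii, micrometres, strictly increasing.
#' @param layer_mean_hu Named HU means for background, lumen, intima, media,
#'   adventitia. The background default plays the role of the unstained
#'   ethanol bath, well below stained tissue.
#' @param media_collagen_gradient Length-2 vector: collagen fraction at the
#'   internal and external media boundary, each in `[0, 1]`.
#' @param hu_per_collagen HU added per unit collagen fraction (linear
#'   contrast model).
#' @param noise_sigma Additive Gaussian noise, HU.
#' @param blur_sigma Gaussian blur standard deviation, voxels.
#' @param rescale_slope,rescale_intercept Stored-pixel encoding metadata.
#' @param rng_seed Integer seed; identical specs give identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(16L, 96L, 96L),
                         voxel_size = 6,
                         lumen_radius = 60,
                         intima_outer_radius = 84,
                         media_outer_radius = 240,
                         adventitia_outer_radius = 264,
                         layer_mean_hu = c(background = 200, lumen = 1000,
                                           intima = 2500, media = 4000,
                                           adventitia = 9000),
                         media_collagen_gradient = c(0.2, 0.6),
                         hu_per_collagen = 5000,
                         noise_sigma = 80,
                         blur_sigma = 0.5,
                         rescale_slope = 0.25,
                         rescale_intercept = -1000,
                         rng_seed = 1L) {
  if (!is.numeric(grid_shape) || length(grid_shape) != 3L ||
      any(grid_shape < 1) || any(grid_shape != round(grid_shape))) {
    abort_config("`grid_shape` must be three positive integers",
                 field = "grid_shape")
  }
  check_scalar_number(voxel_size, "voxel_size", positive = TRUE)
  radii <- c(lumen_radius, intima_outer_radius, media_outer_radius,
             adventitia_outer_radius)
  radii_names <- c("lumen_radius", "intima_outer_radius",
                   "media_outer_radius", "adventitia_outer_radius")
  for (i in seq_along(radii)) {
    check_scalar_number(radii[i], radii_names[i], positive = TRUE)
  }
  if (any(diff(radii) <= 0)) {
    bad <- radii_names[which(diff(radii) <= 0)[1] + 1L]
    abort_config(sprintf("radii must be strictly increasing; `%s` violates this",
                         bad), field = bad)
  }
  max_fit <- (min(grid_shape[2:3]) / 2 - 1) * voxel_size
  if (adventitia_outer_radius > max_fit) {
    abort_config(sprintf(
      "`adventitia_outer_radius` (%g um) does not fit inside the grid (max %g um)",
      adventitia_outer_radius, max_fit), field = "adventitia_outer_radius")
  }
  if (!is.numeric(layer_mean_hu) || !all(LAYERS %in% names(layer_mean_hu))) {
    abort_config("`layer_mean_hu` must name all of background, lumen, intima, media, adventitia",
                 field = "layer_mean_hu")
  }
  if (!is.numeric(media_collagen_gradient) ||
      length(media_collagen_gradient) != 2L ||
      any(media_collagen_gradient < 0) || any(media_collagen_gradient > 1)) {
    abort_config("`media_collagen_gradient` must be two fractions in [0, 1]",
                 field = "media_collagen_gradient")
  }
  check_scalar_number(hu_per_collagen, "hu_per_collagen")
  check_scalar_number(noise_sigma, "noise_sigma", nonnegative = TRUE)
  check_scalar_number(blur_sigma, "blur_sigma", nonnegative = TRUE)
  check_scalar_number(rescale_slope, "rescale_slope")
  if (rescale_slope == 0) {
    abort_config("`rescale_slope` must be non-zero", field = "rescale_slope")
  }
  check_scalar_number(rescale_intercept, "rescale_intercept")
  structure(
    list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
         lumen_radius = lumen_radius,
         intima_outer_radius = intima_outer_radius,
         media_outer_radius = media_outer_radius,
         adventitia_outer_radius = adventitia_outer_radius,
         layer_mean_hu = layer_mean_hu[LAYERS],
         media_collagen_gradient = media_collagen_gradient,
         hu_per_collagen = hu_per_collagen,
         noise_sigma = noise_sigma, blur_sigma = blur_sigma,
         rescale_slope = rescale_slope,
         rescale_intercept = rescale_intercept,
         rng_seed = as.integer(rng_seed)),
    class = "phantom_spec"
  )
}

# Cross-sectional radius map (micrometres from the cylinder axis) and the
# derived per-pixel layer labels / collagen fractions. The phantom is
# translation-invariant along the slice axis, so everything 2D is computed
# once and replicated.
phantom_cross_section <- function(spec) {
  n_row <- spec$grid_shape[2]; n_col <- spec$grid_shape[3]
  cr <- (n_row + 1) / 2; cc <- (n_col + 1) / 2
  r <- sqrt(outer(((seq_len(n_row) - cr) * spec$voxel_size)^2,
                  ((seq_len(n_col) - cc) * spec$voxel_size)^2, `+`))
  lab <- matrix(0L, n_row, n_col)  # background
  lab[r < spec$adventitia_outer_radius] <- 4L
  lab[r < spec$media_outer_radius] <- 3L
  lab[r < spec$intima_outer_radius] <- 2L
  lab[r < spec$lumen_radius] <- 1L
  g <- spec$media_collagen_gradient
  t_med <- (r - spec$intima_outer_radius) /
    (spec$media_outer_radius - spec$intima_outer_radius)
  collagen <- matrix(0, n_row, n_col)
  in_media <- lab == 3L
  collagen[in_media] <- g[1] + (g[2] - g[1]) * pmin(pmax(t_med[in_media], 0), 1)
  list(radius = r, labels = lab, collagen = collagen)
}

# Separable 3D Gaussian blur with edge replication; sigma in voxels.
gaussian_blur_3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  blur_axis1 <- function(a) {
    n1 <- dim(a)[1]
    idx_pad <- c(rep(1L, half), seq_len(n1), rep(n1, half))
    ap <- a[idx_pad, , , drop = FALSE]
    out <- array(0, dim(a))
    for (j in seq_along(k)) {
      out <- out + k[j] * ap[j:(j + n1 - 1L), , , drop = FALSE]
    }
    out
  }
  arr <- blur_axis1(arr)
  arr <- aperm(blur_axis1(aperm(arr, c(2, 1, 3))), c(2, 1, 3))
  aperm(blur_axis1(aperm(arr, c(3, 2, 1))), c(3, 2, 1))
}

#' Generate a synthetic vessel CT phantom
#'
#' Builds the layered-cylinder phantom described by a [phantom_spec()] and
#' returns both the scanner-side [ct_volume()] and the ground truth needed to
#' validate downstream analysis: the per-voxel layer labels, the planted
#' collagen field, the noiseless HU volume and the per-layer true volumes.
#'
#' @param spec A [phantom_spec()].
#' @param sample_id Sample identifier propagated to the volume.
#' @return A list of class `ct_phantom` with elements `ct` ([ct_volume()])
#'   and `truth` (class `phantom_truth`: `label_volume`, `collagen_field`,
#'   `noiseless_hu`, `layer_volumes` tibble in mm^3).
#' @examples
#' ph <- generate_ct_phantom(phantom_spec(noise_sigma = 0, blur_sigma = 0))
#' ph$truth$layer_volumes
#' @export
generate_ct_phantom <- function(spec, sample_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  cs <- phantom_cross_section(spec)
  n_slice <- spec$grid_shape[1]

  rep3d <- function(m) {
    aperm(array(m, dim = c(dim(m), n_slice)), c(3, 1, 2))
  }
  labels3d <- rep3d(cs$labels)
  collagen3d <- rep3d(cs$collagen)
  hu2d <- unname(spec$layer_mean_hu[cs$labels + 1L]) +
    spec$hu_per_collagen * cs$collagen
  dim(hu2d) <- dim(cs$labels)
  noiseless <- rep3d(hu2d)

  hu <- gaussian_blur_3d(noiseless, spec$blur_sigma)
  if (spec$noise_sigma > 0) {
    hu <- hu + with_seed(spec$rng_seed,
                         array(rnorm(length(hu), 0, spec$noise_sigma),
                               dim = dim(hu)))
  }
  stored <- round((hu - spec$rescale_intercept) / spec$rescale_slope)
  stored <- array(as.integer(pmin(pmax(stored, 0), 65535)), dim = dim(hu))

  label_volume <- layer_labels(labels3d, voxel_size = spec$voxel_size)
  truth <- structure(
    list(label_volume = label_volume,
         collagen_field = collagen3d,
         noiseless_hu = noiseless,
         layer_volumes = layer_volumes(label_volume)),
    class = "phantom_truth"
  )
  structure(
    list(ct = ct_volume(stored, rescale_slope = spec$rescale_slope,
                        rescale_intercept = spec$rescale_intercept,
                        voxel_size = spec$voxel_size, sample_id = sample_id),
         truth = truth,
         spec = spec),
    class = "ct_phantom"
  )
}

#' Specification of a synthetic histology triplet
#'
#' Describes the paired synthetic picrosirius-red section: a brightfield
#' image showing tissue on a dark background, and two polarized-light (PLM)
#' images acquired 90 degrees apart in which birefringent (bright) pixels
#' mark collagen. Collagen pixels are drawn per pixel by seeded Bernoulli
#' sampling at the local `collagen_fraction_map` value and split between the
#' two PLM angles by `birefringence_split`, so the union of the two PLM
#' bright sets covers the planted fraction of the tissue.
#'
#' @param image_shape Integer pair (rows, columns).
#' @param collagen_fraction_map Either a single fraction applied across the
#'   tissue, or a matrix of per-pixel target fractions in `[0, 1]` that must
#'   be zero outside `tissue_mask`.
#' @param tissue_mask Logical matrix marking tissue pixels; default all
#'   tissue.
#' @param birefringence_split Probability that a collagen pixel lights up in
#'   the 0-degree rather than the 90-degree PLM image, in `[0, 1]`.
#' @param speckle_seed Integer seed for the Bernoulli sampling.
#' @return An object of class `histology_spec`.
#' @export
histology_spec <- function(image_shape = c(256L, 256L),
                           collagen_fraction_map = 0.3,
                           tissue_mask = NULL,
                           birefringence_split = 0.5,
                           speckle_seed = 1L) {
  if (!is.numeric(image_shape) || length(image_shape) != 2L ||
      any(image_shape < 1)) {
    abort_config("`image_shape` must be two positive integers",
                 field = "image_shape")
  }
  image_shape <- as.integer(image_shape)
  if (is.null(tissue_mask)) {
    tissue_mask <- matrix(TRUE, image_shape[1], image_shape[2])
  }
  if (!is.logical(tissue_mask) || !identical(dim(tissue_mask), image_shape)) {
    abort_config("`tissue_mask` must be a logical matrix of shape `image_shape`",
                 field = "tissue_mask")
  }
  if (length(collagen_fraction_map) == 1L) {
    collagen_fraction_map <- matrix(collagen_fraction_map, image_shape[1],
                                    image_shape[2]) * tissue_mask
  }
  if (!is.matrix(collagen_fraction_map) ||
      !identical(dim(collagen_fraction_map), image_shape)) {
    abort_config("`collagen_fraction_map` must be a scalar or a matrix of shape `image_shape`",
                 field = "collagen_fraction_map")
  }
  if (any(collagen_fraction_map < 0) || any(collagen_fraction_map > 1)) {
    abort_config("collagen fractions must lie in [0, 1]",
                 field = "collagen_fraction_map")
  }
  if (any(collagen_fraction_map[!tissue_mask] != 0)) {
    abort_config("`collagen_fraction_map` must be 0 outside `tissue_mask`",
                 field = "collagen_fraction_map")
  }
  if (!is.numeric(birefringence_split) || length(birefringence_split) != 1L ||
      birefringence_split < 0 || birefringence_split > 1) {
    abort_config("`birefringence_split` must be a fraction in [0, 1]",
                 field = "birefringence_split")
  }
  structure(
    list(image_shape = image_shape,
         collagen_fraction_map = collagen_fraction_map,
         tissue_mask = tissue_mask,
         birefringence_split = birefringence_split,
         speckle_seed = as.integer(speckle_seed)),
    class = "histology_spec"
  )
}

#' Generate a synthetic brightfield + dual-PLM histology triplet
#'
#' @param spec A [histology_spec()].
#' @param pixel_size Pixel size in micrometres.
#' @param sample_id,section_id Identifiers propagated to the triplet.
#' @return A [histology_triplet()] whose combined PLM bright-pixel fraction
#'   within tissue matches the planted collagen fraction up to Bernoulli
#'   sampling error.
#' @export
generate_histology_triplet <- function(spec, pixel_size = 6,
                                       sample_id = "sample",
                                       section_id = "sec1") {
  stopifnot(inherits(spec, "histology_spec"))
  shape <- spec$image_shape
  brightfield <- matrix(BF_BACKGROUND, shape[1], shape[2])
  brightfield[spec$tissue_mask] <- BF_TISSUE
  plm_0 <- matrix(PLM_DARK, shape[1], shape[2])
  plm_90 <- matrix(PLM_DARK, shape[1], shape[2])
  with_seed(spec$speckle_seed, {
    n <- length(brightfield)
    is_collagen <- runif(n) < spec$collagen_fraction_map & spec$tissue_mask
    to_0 <- runif(n) < spec$birefringence_split
    plm_0[is_collagen & to_0] <- PLM_BRIGHT
    plm_90[is_collagen & !to_0] <- PLM_BRIGHT
  })
  histology_triplet(brightfield, plm_0, plm_90, pixel_size = pixel_size,
                    sample_id = sample_id, section_id = section_id)
}

#' Generate a cohort of paired CT phantoms and histology triplets
#'
#' Emulates a small imaging study: `n_samples` vessels whose tissue volumes
#' are scaled by `volume_multipliers` (all radii and the imaged slab length
#' scale by the cube root of the multiplier, so the voxel-counted tissue
#' volume scales by the multiplier) and whose media collagen gradient
#' is centred on `collagen_levels[i]` (internal/external fractions at
#' `level -/+ collagen_halfwidth`, clipped to `[0, 1]`). The matching
#' histology triplet for each sample plants the same collagen level across
#' an annular tissue mask mirroring the vessel cross-section. Fully
#' deterministic under `seed`.
#'
#' @param n_samples Number of samples.
#' @param base_spec The [phantom_spec()] scaled per sample.
#' @param volume_multipliers Positive reals, length `n_samples`.
#' @param collagen_levels Fractions in `[0, 1]`, length `n_samples`.
#' @param seed Master integer seed.
#' @param collagen_halfwidth Half-width of the internal-to-external media
#'   collagen gradient around each level.
#' @return A list of `n_samples` lists, each with elements `ct`, `truth`,
#'   `histology`, `sample_id`, `volume_multiplier` and `collagen_level`.
#' @export
generate_cohort <- function(n_samples, base_spec = phantom_spec(),
                            volume_multipliers, collagen_levels, seed = 1L,
                            collagen_halfwidth = 0.1) {
  stopifnot(inherits(base_spec, "phantom_spec"))
  if (length(volume_multipliers) != n_samples ||
      length(collagen_levels) != n_samples) {
    abort_config(sprintf(
      "`volume_multipliers` and `collagen_levels` must have length n_samples = %d",
      n_samples))
  }
  if (any(volume_multipliers <= 0)) {
    abort_config("`volume_multipliers` must be > 0",
                 field = "volume_multipliers")
  }
  if (any(collagen_levels < 0) || any(collagen_levels > 1)) {
    abort_config("`collagen_levels` must lie in [0, 1]",
                 field = "collagen_levels")
  }
  lapply(seq_len(n_samples), function(i) {
    s <- volume_multipliers[i]^(1 / 3)
    grad <- pmin(pmax(collagen_levels[i] + c(-1, 1) * collagen_halfwidth, 0), 1)
    spec_i <- phantom_spec(
      grid_shape = c(max(1L, as.integer(round(base_spec$grid_shape[1] * s))),
                     base_spec$grid_shape[2:3]),
      voxel_size = base_spec$voxel_size,
      lumen_radius = base_spec$lumen_radius * s,
      intima_outer_radius = base_spec$intima_outer_radius * s,
      media_outer_radius = base_spec$media_outer_radius * s,
      adventitia_outer_radius = base_spec$adventitia_outer_radius * s,
      layer_mean_hu = base_spec$layer_mean_hu,
      media_collagen_gradient = grad,
      hu_per_collagen = base_spec$hu_per_collagen,
      noise_sigma = base_spec$noise_sigma,
      blur_sigma = base_spec$blur_sigma,
      rescale_slope = base_spec$rescale_slope,
      rescale_intercept = base_spec$rescale_intercept,
      rng_seed = as.integer(seed + 7919L * i)
    )
    sample_id <- sprintf("S%02d", i)
    ph <- generate_ct_phantom(spec_i, sample_id = sample_id)

    cs <- phantom_cross_section(spec_i)
    tissue <- cs$labels %in% 2:4
    dim(tissue) <- dim(cs$labels)
    hspec <- histology_spec(
      image_shape = dim(tissue),
      collagen_fraction_map = matrix(collagen_levels[i] * tissue,
                                     nrow(tissue), ncol(tissue)),
      tissue_mask = tissue,
      speckle_seed = as.integer(seed + 104729L + i)
    )
    hist_trip <- generate_histology_triplet(hspec,
                                            pixel_size = base_spec$voxel_size,
                                            sample_id = sample_id)
    list(ct = ph$ct, truth = ph$truth, histology = hist_trip,
         sample_id = sample_id,
         volume_multiplier = volume_multipliers[i],
         collagen_level = collagen_levels[i])
  })
}
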