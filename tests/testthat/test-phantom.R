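test_that("noiseless constant-layer phantom has exactly the layer mean HU", {
  sp <- tiny_spec(hu_per_collagen = 0)
  ph <- generate_ct_phantom(sp)
  hu <- to_hounsfield(ph$ct)
  media <- ph$truth$label_volume$labels == 3L
  expect_true(all(hu$hu[media] == 4000))
  lumen <- ph$truth$label_volume$labels == 1L
  expect_true(all(hu$hu[lumen] == 1000))
})

test_that("phantom spec invariants are enforced with the offending field named", {
  expect_error(tiny_spec(lumen_radius = 40),
               class = "arteryct_config_error")
  err <- rlang::catch_cnd(tiny_spec(lumen_radius = 40))
  expect_match(err$field, "intima_outer_radius")
  expect_error(tiny_spec(media_collagen_gradient = c(-0.1, 0.5)),
               class = "arteryct_config_error")
  expect_error(tiny_spec(noise_sigma = -1), class = "arteryct_config_error")
  expect_error(phantom_spec(adventitia_outer_radius = 600),
               class = "arteryct_config_error")
  expect_error(tiny_spec(rescale_slope = 0), class = "arteryct_config_error")
})

test_that("media HU difference across the band equals the planted gradient span", {
  sp <- tiny_spec(media_collagen_gradient = c(0.2, 0.6), hu_per_collagen = 5000)
  ph <- generate_ct_phantom(sp)
  hu <- to_hounsfield(ph$ct)
  cs <- arteryct:::phantom_cross_section(sp)
  media <- cs$labels == 3L
  r_med <- cs$radius[media]
  hu_slice <- hu$hu[1, , ]
  dim(hu_slice) <- dim(cs$labels)
  hu_med <- hu_slice[media]
  inner_hu <- hu_med[which.min(r_med)]
  outer_hu <- hu_med[which.max(r_med)]
  # one voxel of linear interpolation slack at each boundary
  slope_per_voxel <- 5000 * 0.4 /
    (sp$media_outer_radius - sp$intima_outer_radius) * sp$voxel_size
  expect_lt(abs((outer_hu - inner_hu) - 2000), 2 * slope_per_voxel)
})

test_that("noiseless HU matches per-voxel closed-form recomputation", {
  sp <- tiny_spec(media_collagen_gradient = c(0.1, 0.9), hu_per_collagen = 3000)
  ph <- generate_ct_phantom(sp)
  hu <- to_hounsfield(ph$ct)
  set.seed(42)
  for (n in 1:200) {
    i <- sample(sp$grid_shape[1], 1)
    j <- sample(sp$grid_shape[2], 1)
    k <- sample(sp$grid_shape[3], 1)
    model <- phantom_model_hu(sp, i, j, k)
    # stored-pixel rounding quantizes HU by one slope step
    expect_lt(abs(hu$hu[i, j, k] - model), sp$rescale_slope)
  }
})

test_that("identical specs and seeds give bit-identical phantoms", {
  sp <- tiny_spec(noise_sigma = 120, blur_sigma = 0.6, rng_seed = 7L)
  a <- generate_ct_phantom(sp)
  b <- generate_ct_phantom(sp)
  expect_identical(a$ct$stored_pixels, b$ct$stored_pixels)
  sp2 <- tiny_spec(noise_sigma = 120, blur_sigma = 0.6, rng_seed = 8L)
  expect_false(identical(generate_ct_phantom(sp2)$ct$stored_pixels,
                         a$ct$stored_pixels))
})

test_that("mean media HU increases strictly with the collagen contrast", {
  hus <- vapply(c(0, 2000, 5000, 9000), function(hpc) {
    ph <- generate_ct_phantom(tiny_spec(hu_per_collagen = hpc))
    hu <- to_hounsfield(ph$ct)
    mean(hu$hu[ph$truth$label_volume$labels == 3L])
  }, numeric(1))
  expect_true(all(diff(hus) > 0))
})

test_that("phantom truth volumes equal voxel counts times voxel volume", {
  ph <- generate_ct_phantom(tiny_spec())
  vols <- ph$truth$layer_volumes
  counts <- tabulate(ph$truth$label_volume$labels + 1L, nbins = 5L)
  expect_equal(vols$n_voxels, counts)
  expect_equal(vols$volume_mm3, counts * 6^3 * 1e-9)
  expect_true(all(ph$truth$collagen_field[
    ph$truth$label_volume$labels %in% c(0L, 1L)] == 0))
})

test_that("saturated and zero collagen fractions give the degenerate PLM images", {
  mask <- disc_mask(64, 24)
  trip1 <- generate_histology_triplet(
    histology_spec(c(64L, 64L), 1 * mask, tissue_mask = mask))
  combined <- combine_plm(trip1$plm_0, trip1$plm_90)
  expect_identical(combined >= 240, mask)
  trip0 <- generate_histology_triplet(
    histology_spec(c(64L, 64L), 0 * mask, tissue_mask = mask))
  expect_true(all(trip0$plm_0 < 240) && all(trip0$plm_90 < 240))
})

test_that("combined PLM white fraction concentrates on the planted fraction", {
  spec <- histology_spec(c(256L, 256L), 0.5, speckle_seed = 11L)
  trip <- generate_histology_triplet(spec)
  combined <- combine_plm(trip$plm_0, trip$plm_90)
  measured <- mean(combined >= 240)  # direct pixel count, full-tissue mask
  expect_lt(abs(measured - 0.5), 0.02)
  # exclusive split between angles: no pixel bright at both
  expect_false(any(trip$plm_0 >= 240 & trip$plm_90 >= 240))
})

test_that("histology spec rejects invalid collagen maps", {
  expect_error(histology_spec(c(8L, 8L), 1.2), class = "arteryct_config_error")
  mask <- matrix(FALSE, 8, 8)
  mask[3:6, 3:6] <- TRUE
  bad_map <- matrix(0.5, 8, 8)  # nonzero outside the mask
  expect_error(histology_spec(c(8L, 8L), bad_map, tissue_mask = mask),
               class = "arteryct_config_error")
  expect_error(histology_spec(c(8L, 8L), 0.5, birefringence_split = 2),
               class = "arteryct_config_error")
})

test_that("cohort scaling preserves and scales tissue volume as requested", {
  base <- phantom_spec(grid_shape = c(3L, 200L, 200L), lumen_radius = 60,
                       intima_outer_radius = 84, media_outer_radius = 150,
                       adventitia_outer_radius = 174, noise_sigma = 0,
                       blur_sigma = 0)
  coh <- generate_cohort(2, base, volume_multipliers = c(1, 8),
                         collagen_levels = c(0.3, 0.6), seed = 2)
  v <- vapply(coh, function(s) tissue_volume(s$truth$label_volume), numeric(1))
  expect_equal(v[1], tissue_volume(generate_ct_phantom(base)$truth$label_volume))
  expect_lt(abs(v[2] / v[1] - 8), 8 * 0.02)
})

test_that("cohort generation is deterministic and validates its inputs", {
  base <- tiny_spec(noise_sigma = 60)
  a <- generate_cohort(3, base, c(1, 1.06, 1.03), c(0.2, 0.5, 0.8), seed = 9)
  b <- generate_cohort(3, base, c(1, 1.06, 1.03), c(0.2, 0.5, 0.8), seed = 9)
  for (i in 1:3) {
    expect_identical(a[[i]]$ct$stored_pixels, b[[i]]$ct$stored_pixels)
    expect_identical(a[[i]]$histology$plm_0, b[[i]]$histology$plm_0)
  }
  expect_error(generate_cohort(3, base, c(1, 2), c(0.2, 0.5, 0.8)),
               class = "arteryct_config_error")
  expect_error(generate_cohort(2, base, c(1, -1), c(0.2, 0.5)),
               class = "arteryct_config_error")
})
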