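test_that("threshold classification recovers ground-truth labels on a noiseless phantom", {
  sp <- tiny_spec()
  ph <- generate_ct_phantom(sp)
  hu <- to_hounsfield(ph$ct)
  seg <- classify_by_threshold(hu, default_layer_thresholds(sp))
  expect_identical(seg$labels, ph$truth$label_volume$labels)
  d <- layer_dice(seg, ph$truth$label_volume)
  expect_equal(d$dice, rep(1, 5))
})

test_that("a volume whose HU falls in no interval is all background", {
  hu <- hu_volume(array(50, c(2, 4, 4)))
  th <- layer_thresholds(lumen = c(100, 200), intima = c(200, 300),
                         media = c(300, 400), adventitia = c(400, 500))
  seg <- classify_by_threshold(hu, th)
  expect_true(all(seg$labels == 0L))
})

test_that("a value at a shared interval boundary goes to the upper interval", {
  th <- layer_thresholds(lumen = c(100, 200), intima = c(200, 300),
                         media = c(300, 400), adventitia = c(400, 500))
  hu <- hu_volume(array(c(200, 300, 400, 199.999), c(1, 2, 2)))
  seg <- classify_by_threshold(hu, th)
  expect_equal(as.vector(seg$labels), c(2L, 3L, 4L, 1L))
})

test_that("overlapping intervals resolve by the configured priority", {
  th <- layer_thresholds(lumen = c(0, 1000), intima = c(0, 1000),
                         media = c(0, 1000), adventitia = c(900, 1000))
  hu <- hu_volume(array(c(500, 950), c(1, 1, 2)))
  seg <- classify_by_threshold(hu, th)
  # media beats intima beats lumen where all three overlap; adventitia wins on top
  expect_equal(as.vector(seg$labels), c(3L, 4L))
  seg2 <- classify_by_threshold(hu, th,
                                priority = c("media", "intima", "adventitia",
                                             "lumen"))
  expect_equal(as.vector(seg2$labels), c(1L, 1L))
})

test_that("segmentation is invariant under a common affine HU shift", {
  sp <- tiny_spec(noise_sigma = 60, rng_seed = 12L)
  ph <- generate_ct_phantom(sp)
  hu <- to_hounsfield(ph$ct)
  th <- default_layer_thresholds(sp)
  shift <- 1234.5
  hu2 <- hu_volume(hu$hu + shift, voxel_size = hu$voxel_size)
  th2 <- layer_thresholds(lumen = th$lumen + shift, intima = th$intima + shift,
                          media = th$media + shift,
                          adventitia = th$adventitia + shift)
  expect_identical(classify_by_threshold(hu, th)$labels,
                   classify_by_threshold(hu2, th2)$labels)
})

test_that("region growing equals the breadth-first oracle on random volumes", {
  set.seed(77)
  for (rep in 1:6) {
    vals <- array(runif(16^3), c(16, 16, 16))
    hu <- hu_volume(vals)
    interval <- c(0, 0.55)
    mask <- vals >= interval[1] & vals < interval[2]
    seed_idx <- which(mask, arr.ind = TRUE)[1, ]
    for (conn in c(6, 26)) {
      grown <- grow_region(hu, seed_idx, interval, connectivity = conn)
      oracle <- bfs_flood_fill(mask, seed_idx, conn)
      expect_identical(grown, oracle)
      # always a connected subset of the thresholded set
      expect_true(all(mask[grown]))
    }
  }
})

test_that("region growing stays inside the seeded component", {
  hu <- hu_volume(array(0, c(1, 9, 9)))
  hu$hu[1, 2:3, 2:3] <- 100  # blob A
  hu$hu[1, 7:8, 7:8] <- 100  # blob B, disjoint
  grown <- grow_region(hu, c(1, 2, 2), c(99, 101), connectivity = 26)
  expect_equal(sum(grown), 4)
  expect_true(all(which(grown, arr.ind = TRUE)[, 2] <= 3))
})

test_that("an interval covering only the seed yields a single voxel", {
  hu <- hu_volume(array(0, c(3, 3, 3)))
  hu$hu[2, 2, 2] <- 500
  grown <- grow_region(hu, c(2, 2, 2), c(499, 501))
  expect_equal(sum(grown), 1)
  expect_true(grown[2, 2, 2])
})

test_that("growing from a seed outside the interval is a seed error", {
  hu <- hu_volume(array(0, c(2, 2, 2)))
  expect_error(grow_region(hu, c(1, 1, 1), c(100, 200)),
               class = "arteryct_seed_error")
  expect_error(grow_region(hu, c(5, 1, 1), c(-1, 1)),
               class = "arteryct_input_error")
})

test_that("region growing recovers the analytic lumen cylinder", {
  sp <- tiny_spec()
  ph <- generate_ct_phantom(sp)
  hu <- to_hounsfield(ph$ct)
  lumen_hu <- sp$layer_mean_hu[["lumen"]]
  grown <- grow_region(hu, c(3, 20, 20), lumen_hu + c(-1, 1))
  expect_identical(grown, ph$truth$label_volume$labels == 1L)
})

test_that("layer volumes follow voxel count times voxel volume", {
  lab <- array(0L, c(2, 5, 10))
  lab[1, 1, 1:10] <- 3L  # 10 media voxels
  lv <- layer_volumes(layer_labels(lab, voxel_size = 6))
  expect_equal(lv$volume_mm3[lv$layer == "media"], 10 * 216e-9)
  expect_equal(lv$volume_mm3[lv$layer == "lumen"], 0)
  expect_equal(tissue_volume(layer_labels(lab, voxel_size = 6)), 10 * 216e-9)
})

test_that("dice handles identity, disjoint, partial and empty masks", {
  a <- array(FALSE, c(1, 4, 4)); a[1, 1, 1:4] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- array(FALSE, c(1, 4, 4)); b[1, 3, 1:4] <- TRUE
  expect_equal(dice(a, b), 0)
  ab <- a | b
  expect_equal(dice(a, ab), 2 * 4 / (4 + 8))
  e <- array(FALSE, c(1, 4, 4))
  expect_equal(dice(e, e), 1)
  expect_error(dice(a, array(FALSE, c(1, 2, 2))),
               class = "arteryct_input_error")
})

test_that("majority filtering removes isolated mislabeled voxels", {
  sp <- tiny_spec()
  ph <- generate_ct_phantom(sp)
  lab <- ph$truth$label_volume$labels
  # plant isolated salt voxels inside the media
  media_idx <- which(lab == 3L)
  set.seed(3)
  salt <- sample(media_idx, 5)
  lab[salt] <- 1L
  cleaned <- majority_filter(layer_labels(lab, voxel_size = 6))
  expect_true(all(cleaned$labels[salt] == 3L))
  d_before <- dice(lab == 3L, ph$truth$label_volume$labels == 3L)
  d_after <- dice(cleaned$labels == 3L, ph$truth$label_volume$labels == 3L)
  expect_gte(d_after, d_before)
})

test_that("thresholds round-trip through JSON", {
  th <- default_layer_thresholds(tiny_spec())
  path <- file.path(withr::local_tempdir(), "th.json")
  write_layer_thresholds(th, path)
  back <- read_layer_thresholds(path)
  expect_equal(unclass(back), unclass(th))
  expect_error(layer_thresholds(lumen = c(2, 1), intima = c(2, 3),
                                media = c(3, 4), adventitia = c(4, 5)),
               class = "arteryct_config_error")
  shipped <- read_layer_thresholds(
    system.file("extdata", "phantom_default_thresholds.json",
                package = "arteryct"))
  expect_equal(unclass(shipped),
               unclass(default_layer_thresholds(phantom_spec())))
})
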