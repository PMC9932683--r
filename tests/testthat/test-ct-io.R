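test_that("Hounsfield conversion applies the affine rescale", {
  vol <- ct_volume(array(1500L, c(1, 2, 2)), rescale_slope = 1,
                   rescale_intercept = -1000)
  expect_true(all(to_hounsfield(vol)$hu == 500))
  vol2 <- ct_volume(array(100L, c(1, 2, 2)), rescale_slope = 2,
                    rescale_intercept = 0)
  expect_true(all(to_hounsfield(vol2)$hu == 200))
})

test_that("Hounsfield conversion matches an element-by-element scalar loop", {
  set.seed(101)
  for (rep in 1:10) {
    px <- array(sample.int(4000L, 8 * 8 * 8, replace = TRUE), c(8, 8, 8))
    slope <- runif(1, 0.1, 3)
    inter <- runif(1, -2000, 500)
    hu <- to_hounsfield(ct_volume(px, slope, inter))$hu
    for (idx in sample(length(px), 20)) {
      expect_identical(hu[idx], px[idx] * slope + inter)
    }
  }
})

test_that("the rescale is invertible given metadata", {
  set.seed(5)
  px <- array(sample.int(65535L, 4^3, replace = TRUE) - 1L, c(4, 4, 4))
  vol <- ct_volume(px, rescale_slope = 0.25, rescale_intercept = -1000)
  hu <- to_hounsfield(vol)
  expect_identical((hu$hu - vol$rescale_intercept) / vol$rescale_slope,
                   px + 0)
})

test_that("volume containers validate their invariants", {
  expect_error(ct_volume(matrix(1, 2, 2)), class = "arteryct_input_error")
  expect_error(ct_volume(array(1, c(2, 2, 2)), rescale_slope = 0),
               class = "arteryct_metadata_error")
  expect_error(ct_volume(array(1, c(2, 2, 2)), voxel_size = -6),
               class = "arteryct_config_error")
  expect_error(hu_volume(array(c(1, NA), c(1, 1, 2))),
               class = "arteryct_input_error")
})

test_that("raw + JSON sidecar round-trips a volume exactly", {
  ph <- generate_ct_phantom(tiny_spec(noise_sigma = 30))
  prefix <- file.path(withr::local_tempdir(), "vol")
  write_ct_sidecar(ph$ct, prefix)
  back <- read_ct_sidecar(prefix)
  expect_identical(back$stored_pixels, ph$ct$stored_pixels)
  expect_equal(back$rescale_slope, ph$ct$rescale_slope)
  expect_equal(back$voxel_size, ph$ct$voxel_size)
})

test_that("a DICOM series round-trips stored pixels and metadata", {
  ph <- generate_ct_phantom(tiny_spec(noise_sigma = 40, rng_seed = 3L))
  dir <- withr::local_tempdir()
  write_dicom_series(ph$ct, dir)
  back <- read_dicom_series(dir)
  expect_identical(back$stored_pixels, ph$ct$stored_pixels)
  expect_equal(back$rescale_slope, ph$ct$rescale_slope)
  expect_equal(back$rescale_intercept, ph$ct$rescale_intercept)
  expect_equal(unname(back$voxel_size), unname(ph$ct$voxel_size))
  expect_equal(back$sample_id, ph$ct$sample_id)
})

test_that("reading is invariant to on-disk file order", {
  ph <- generate_ct_phantom(tiny_spec(noise_sigma = 40, rng_seed = 4L))
  dir <- withr::local_tempdir()
  paths <- write_dicom_series(ph$ct, dir)
  # scramble names so lexicographic order reverses the acquisition order
  scrambled <- file.path(dir, sprintf("z_%s.dcm", rev(letters[seq_along(paths)])))
  file.rename(paths, scrambled)
  back <- read_dicom_series(dir)
  expect_identical(back$stored_pixels, ph$ct$stored_pixels)
})

test_that("inconsistent or empty series raise format and input errors", {
  dir <- withr::local_tempdir()
  expect_error(read_dicom_series(dir), class = "arteryct_input_error")
  a <- ct_volume(array(1L, c(1, 8, 8)))
  b <- ct_volume(array(1L, c(1, 4, 4)))
  write_dicom_series(a, dir, series_number = 1L)
  file.rename(file.path(dir, "slice_0001.dcm"), file.path(dir, "a.dcm"))
  write_dicom_series(b, dir, series_number = 2L)
  expect_error(read_dicom_series(dir), class = "arteryct_format_error")
})

test_that("missing rescale metadata defaults to identity with a warning", {
  dir <- withr::local_tempdir()
  # hand-build a slice without rescale tags
  elem <- arteryct:::dcm_element
  px <- matrix(7L, 4, 4)
  body <- c(
    elem(0x0008L, 0x0060L, "CS", "CT"),
    elem(0x0020L, 0x0013L, "IS", "1"),
    elem(0x0028L, 0x0010L, "US", arteryct:::raw_u16(4L)),
    elem(0x0028L, 0x0011L, "US", arteryct:::raw_u16(4L)),
    elem(0x7FE0L, 0x0010L, "OW", arteryct:::uint16_le(as.integer(t(px))))
  )
  meta <- c(
    elem(0x0002L, 0x0010L, "UI", arteryct:::TRANSFER_SYNTAX_EXPLICIT_LE)
  )
  meta <- c(elem(0x0002L, 0x0000L, "UL", arteryct:::raw_u32(length(meta))), meta)
  con <- file(file.path(dir, "s1.dcm"), "wb")
  writeBin(c(as.raw(rep(0L, 128L)), charToRaw("DICM"), meta, body), con)
  close(con)
  expect_warning(vol <- read_dicom_series(dir), "rescale")
  expect_equal(vol$rescale_slope, 1)
  expect_equal(vol$rescale_intercept, 0)
  expect_true(all(vol$stored_pixels == 7L))
})

test_that("an independent DICOM reader agrees on pixels and metadata", {
  # pydicom, run out of process, is the cross-check for the writer
  ph <- generate_ct_phantom(tiny_spec(grid_shape = c(3L, 8L, 8L),
                                      lumen_radius = 6,
                                      intima_outer_radius = 9,
                                      media_outer_radius = 15,
                                      adventitia_outer_radius = 18,
                                      noise_sigma = 50, rng_seed = 6L))
  dir <- withr::local_tempdir()
  write_dicom_series(ph$ct, dir)
  script <- file.path(dir, "check.py")
  writeLines(c(
    "import pydicom, glob, json",
    "recs = []",
    sprintf("for f in sorted(glob.glob(r'%s/*.dcm')):", dir),
    "    ds = pydicom.dcmread(f)",
    "    recs.append((float(ds.ImagePositionPatient[2]), ds))",
    "recs.sort(key=lambda t: t[0])",
    "out = {'slope': [float(ds.RescaleSlope) for _, ds in recs],",
    "       'intercept': [float(ds.RescaleIntercept) for _, ds in recs],",
    "       'spacing': [float(x) for x in recs[0][1].PixelSpacing],",
    "       'px': [ds.pixel_array.astype(int).flatten().tolist()",
    "              for _, ds in recs]}",
    "print(json.dumps(out))"
  ), script)
  res <- system2("python", script, stdout = TRUE)
  parsed <- jsonlite::fromJSON(paste(res, collapse = ""))
  expect_equal(parsed$slope, rep(ph$ct$rescale_slope, 3))
  expect_equal(parsed$intercept, rep(ph$ct$rescale_intercept, 3))
  expect_equal(parsed$spacing, rep(6 / 1000, 2))
  for (k in 1:3) {
    # pydicom flattens row-major over (row, column)
    expect_identical(matrix(as.integer(parsed$px[k, ]), 8, 8, byrow = TRUE),
                     ph$ct$stored_pixels[k, , ])
  }
})
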