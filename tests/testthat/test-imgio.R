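test_that("containers enforce their invariants", {
  expect_error(image_volume(array(0, c(2, 2, 2, 2))), "2-D or 3-D")
  expect_error(image_volume(matrix(0, 2, 2), spacing_mm = c(-1, 1)), "positive")
  expect_error(segmentation_mask(matrix(c(0, 1, 2, 0), 2, 2)), "0/1")
  expect_error(ctnodule:::check_pair(image_volume(matrix(0, 3, 3)),
                                     segmentation_mask(matrix(0L, 2, 2))),
               "shapes differ")
})

test_that("16-bit PNG phantom export round-trips", {
  ph <- generate_phantom(simple_spec(noise_sigma = 0.2, seed = 2))
  d <- withr::local_tempdir()
  paths <- export_phantom(ph, d, "p1")
  img <- suppressWarnings(read_image(paths[["image"]]))
  meta <- jsonlite::read_json(paths[["sidecar"]], simplifyVector = TRUE)
  rng <- as.numeric(meta$intensity_range)
  rec <- img$voxels * (rng[2] - rng[1]) + rng[1]
  # exact to 16-bit quantization of the dynamic range
  expect_lt(max(abs(rec - ph$image$voxels)), diff(rng) / 65535)
  expect_warning(read_image(paths[["image"]]), "spacing")
})

test_that("mask round trips are exact and non-binary inputs are rejected", {
  ph <- generate_phantom(simple_spec())
  f <- withr::local_tempfile(fileext = ".png")
  write_mask(ph$mask, f)
  back <- read_mask(f, spacing_mm = ph$mask$spacing_mm)
  expect_identical(back$voxels, ph$mask$voxels)

  # empty mask round trip
  f2 <- withr::local_tempfile(fileext = ".png")
  write_mask(segmentation_mask(matrix(0L, 16, 16)), f2)
  expect_equal(sum(read_mask(f2)$voxels), 0)

  # a gray PNG is not a mask
  f3 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(128 / 255, 8, 8), f3)
  expect_error(read_mask(f3), "non-binary")
})

test_that("NIfTI 3-D round trip preserves voxels and spacing", {
  v <- image_volume(array(rnorm(6 * 8 * 10), c(6, 8, 10)),
                    spacing_mm = c(1, 0.664, 0.664))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_image(v, f)
  r <- read_image(f)
  expect_equal(r$voxels, v$voxels, tolerance = 1e-6)
  expect_equal(r$spacing_mm, c(1, 0.664, 0.664), tolerance = 1e-6)

  m <- segmentation_mask(array(rbinom(6 * 8 * 10, 1, 0.4), c(6, 8, 10)),
                         c(1, 0.664, 0.664))
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(m, f2)
  r2 <- read_mask(f2)
  expect_identical(r2$voxels, m$voxels)
})

test_that("missing files and unknown formats error with the path named", {
  expect_error(read_image("/no/such/file.png"), "no/such/file")
  odd <- withr::local_tempfile(fileext = ".xyz")
  writeLines("x", odd)
  expect_error(read_image(odd), "format")
})

test_that("synthetic DICOM reads back pixels, spacing and rescale", {
  px <- matrix(sample(0:400, 12 * 10, TRUE), 12, 10)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_synthetic_dicom(f, px, spacing = c(0.664, 0.7))
  v <- read_image(f)
  expect_equal(dim(v$voxels), c(12L, 10L))
  expect_equal(v$voxels, px + 0.0)
  expect_equal(v$spacing_mm, c(0.664, 0.7))
})

test_that("DICOM without PixelSpacing is a hard error", {
  f <- withr::local_tempfile(fileext = ".dcm")
  write_synthetic_dicom(f, matrix(0, 4, 4), omit_spacing = TRUE)
  expect_error(read_dicom_image(f), "PixelSpacing")
})

test_that("DICOM series assemble in InstanceNumber order", {
  d <- withr::local_tempdir()
  paths <- file.path(d, sprintf("s%d.dcm", 1:3))
  # write slices with shuffled instance numbers; values identify the slice
  write_synthetic_dicom(paths[1], matrix(30, 4, 4), instance = 3L, slice_thickness = 2)
  write_synthetic_dicom(paths[2], matrix(10, 4, 4), instance = 1L, slice_thickness = 2)
  write_synthetic_dicom(paths[3], matrix(20, 4, 4), instance = 2L, slice_thickness = 2)
  vol <- read_dicom_series(paths)
  expect_equal(dim(vol$voxels), c(3L, 4L, 4L))
  expect_equal(vol$voxels[, 1, 1], c(10, 20, 30))
  expect_equal(vol$spacing_mm[1], 2)
})
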