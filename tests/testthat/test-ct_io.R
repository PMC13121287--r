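test_that("NIfTI volume round trip preserves voxels and geometry", {
  case <- small_phantom_case()
  path <- file.path(withr::local_tempdir(), "vol.nii.gz")
  save_volume(case$volume, path)
  back <- load_volume(path, patient_id = case$volume$patient_id)
  expect_s3_class(back, "cac_volume")
  expect_equal(back$voxels, case$volume$voxels, tolerance = 1e-6)
  expect_equal(back$pixel_spacing, case$volume$pixel_spacing,
               tolerance = 1e-6)
  expect_equal(back$slice_thickness, case$volume$slice_thickness,
               tolerance = 1e-6)
  expect_identical(back$patient_id, case$volume$patient_id)
})

test_that("DICOM series round trip reproduces integer HU exactly", {
  set.seed(5)
  vox <- array(sample(-1000:1500, 3 * 16 * 16, replace = TRUE),
               c(3, 16, 16))
  vol <- cac_volume(vox, pixel_spacing = c(0.7, 0.7), slice_thickness = 2.5,
                    patient_id = "dcm_rt")
  dir <- withr::local_tempdir()
  write_dicom_series(vol, dir)
  back <- load_volume(dir, patient_id = "dcm_rt")
  expect_identical(dim(back$voxels), dim(vol$voxels))
  expect_equal(back$voxels, vol$voxels + 0)
  expect_equal(back$pixel_spacing, c(0.7, 0.7), tolerance = 1e-9)
  expect_equal(back$slice_thickness, 2.5, tolerance = 1e-9)
})

test_that("DICOM slices are ordered by position regardless of file names", {
  vox <- array(0, c(4, 8, 8))
  for (i in 1:4) vox[i, , ] <- i * 100   # slice signature
  vol <- cac_volume(vox, pixel_spacing = c(1, 1), slice_thickness = 3,
                    patient_id = "ord")
  dir <- withr::local_tempdir()
  write_dicom_series(vol, dir)
  files <- list.files(dir, full.names = TRUE)
  # shuffle the file names: ordering must come from the headers
  tmp <- file.path(dir, paste0("z_", rev(basename(files))))
  file.rename(files, tmp)
  back <- load_volume(dir, patient_id = "ord")
  expect_equal(back$voxels[, 1, 1], c(100, 200, 300, 400))
})

test_that("mask round trips through NIfTI and PNG stacks", {
  case <- small_phantom_case()
  d <- withr::local_tempdir()
  p1 <- file.path(d, "mask.nii.gz")
  save_mask(case$mask, p1)
  expect_identical(load_mask(p1)$labels, case$mask$labels)
  p2 <- file.path(d, "pngstack")
  save_mask(case$mask, p2, format = "png_stack")
  expect_identical(load_mask(p2)$labels, case$mask$labels)
})

test_that("normalization maps to [-1, 1], keeps order, retains raw HU", {
  set.seed(9)
  raw <- matrix(stats::runif(64, -1024, 2000), 8, 8)
  ns <- normalize_slice(raw, source_slice_index = 3L)
  expect_true(all(ns$values >= -1 & ns$values <= 1))
  # monotone: intensity order is preserved
  expect_identical(order(ns$values), order(raw))
  # extremes hit (up to the epsilon guard)
  expect_equal(min(ns$values), -1, tolerance = 1e-6)
  expect_equal(max(ns$values), 1, tolerance = 1e-6)
  expect_identical(ns$raw_hu, raw)
  expect_identical(ns$source_slice_index, 3L)
  # constant slice convention: all -1
  expect_true(all(normalize_slice(matrix(55, 4, 4))$values == -1))
})

test_that("volume loading fails loudly on bad inputs", {
  expect_error(load_volume(file.path(tempdir(), "nope.nii")), "no such file")
  expect_error(normalize_slice(matrix(c(1, NA, 3, 4), 2, 2)), "finite")
})
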