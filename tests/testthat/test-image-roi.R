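test_that("CT volumes round-trip through NIfTI with anisotropic spacing", {
  set.seed(5)
  vol <- ct_volume(array(rnorm(20 * 16 * 8, 0, 100), dim = c(20, 16, 8)),
                   spacing = c(0.7, 0.7, 2.5))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_ct_volume(vol, path)
  back <- load_ct_volume(path)
  expect_equal(back$data, vol$data, tolerance = 1e-6)
  expect_equal(back$spacing, c(0.7, 0.7, 2.5), tolerance = 1e-6)
})

test_that("loading rejects directories and missing files explicitly", {
  expect_error(load_ct_volume(withr::local_tempdir()),
               class = "tcmbmd_io_error")
  expect_error(load_ct_volume("no/such/file.nii"), class = "tcmbmd_io_error")
})

test_that("DICOM rescale maps stored values to HU and refuses missing tags", {
  expect_equal(hu_rescale(1024, slope = 1, intercept = -1024), 0)
  expect_equal(hu_rescale(c(0, 2048), 1, -1024), c(-1024, 1024))
  expect_error(hu_rescale(100, NULL, -1024), class = "tcmbmd_io_error")
  expect_error(hu_rescale(100, 1, NA), class = "tcmbmd_io_error")
})

test_that("the median cross-section follows the lower-middle tie rule", {
  expect_equal(median_cross_section(c(10, 20)), 15L)
  expect_equal(median_cross_section(c(10, 11)), 10L)
  expect_equal(median_cross_section(c(7, 7)), 7L)
  expect_error(median_cross_section(c(8, 5)), class = "tcmbmd_domain_error")
})

test_that("elliptical ROI means match brute-force voxel enumeration", {
  # ramp image: value = 3*x + 7*y so any mask error shifts the mean
  dims <- c(24, 20, 4)
  data <- array(0, dim = dims)
  for (z in 1:4) data[, , z] <- outer(3 * (0:(dims[1] - 1)),
                                      7 * (0:(dims[2] - 1)), "+")
  vol <- ct_volume(data)
  roi <- ellipse_roi(slice = 2, cx = 10.3, cy = 8.7, a = 2.5, b = 1.5)
  got <- elliptical_roi_mean(vol, roi)

  vals <- c(); n <- 0
  for (x in 0:(dims[1] - 1)) for (y in 0:(dims[2] - 1)) {
    if (((x - 10.3) / 2.5)^2 + ((y - 8.7) / 1.5)^2 <= 1) {
      vals <- c(vals, data[x + 1, y + 1, 3]); n <- n + 1
    }
  }
  expect_equal(got$n_voxels, n)
  expect_equal(got$mean_hu, mean(vals))
})

test_that("a uniform slice averages to its value under any ellipse", {
  vol <- make_test_volume(background = 100)
  for (roi in list(ellipse_roi(0, 15, 15, 3, 2),
                   ellipse_roi(5, 10.5, 20.2, 6.1, 4.9))) {
    expect_equal(elliptical_roi_mean(vol, roi)$mean_hu, 100)
  }
})

test_that("ROI means ignore voxels outside the ellipse", {
  vol <- make_test_volume(background = 50)
  roi <- ellipse_roi(3, 16, 16, 4, 3)
  base <- elliptical_roi_mean(vol, roi)
  # poison everything outside a safety margin around the ellipse
  poisoned <- vol
  x <- seq_len(dim(vol$data)[1]) - 1
  y <- seq_len(dim(vol$data)[2]) - 1
  outside <- outer(((x - 16) / 4)^2, ((y - 16) / 3)^2, "+") > 1
  slice <- poisoned$data[, , 4]
  slice[outside] <- 5000
  poisoned$data[, , 4] <- slice
  expect_equal(elliptical_roi_mean(poisoned, roi), base)
})

test_that("voxel counts grow monotonically with the semi-axes", {
  vol <- make_test_volume()
  counts <- vapply(seq(1, 8, by = 0.5), function(a) {
    elliptical_roi_mean(vol, ellipse_roi(0, 15, 15, a, 3))$n_voxels
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("empty and out-of-volume ROIs raise explicit errors", {
  vol <- make_test_volume(dims = c(16, 16, 4))
  expect_error(elliptical_roi_mean(vol, ellipse_roi(0, 100, 100, 2, 2)),
               class = "tcmbmd_empty_roi")
  expect_error(elliptical_roi_mean(vol, ellipse_roi(10, 8, 8, 2, 2)),
               class = "tcmbmd_domain_error")
  expect_error(ellipse_roi(0, 8, 8, 0, 2), class = "tcmbmd_domain_error")
})

make_vertebra_annotations <- function(path, vertebrae = c("L1", "L2", "L3", "L4")) {
  z_ranges <- list(L1 = c(0, 3), L2 = c(4, 7), L3 = c(8, 11), L4 = c(12, 15))
  ann <- list(
    subject = "SYN01",
    vertebrae = lapply(vertebrae, function(v) {
      list(vertebra = v, z_range = z_ranges[[v]],
           ellipse = list(cx = 15, cy = 15, a = 5, b = 4))
    })
  )
  jsonlite::write_json(ann, path, auto_unbox = TRUE)
  path
}

test_that("annotated vertebrae at a known concentration measure correctly", {
  # vertebra rendered at the HU equivalent of 0.205 g/cm3 (the normal-
  # subject exemplar value) must read back as vBMD 0.205
  spectrum <- make_spectrum(120)
  mu_w <- spectrum_weighted_attenuation(material("water"), spectrum)
  hu_cor <- hu_from_attenuation(
    spectrum_weighted_attenuation(solution_material(1.0), spectrum), mu_w)
  hu_tra <- hu_from_attenuation(
    spectrum_weighted_attenuation(solution_material(0.205), spectrum), mu_w)
  calib <- reference_calibration(0, hu_cor, rho_cortical = 1,
                                 kvp_label = "120kVp")

  vol <- make_test_volume(dims = c(32, 32, 16), background = -60,
                          insert_hu = hu_tra,
                          insert = list(cx = 15, cy = 15, a = 8, b = 7,
                                        z = 0:15))
  path <- withr::local_tempfile(fileext = ".json")
  make_vertebra_annotations(path)
  res <- measure_vertebrae(vol, path, calib)
  expect_equal(nrow(res), 4)
  expect_equal(res$vertebra, c("L1", "L2", "L3", "L4"))
  expect_equal(res$slice, c(1L, 5L, 9L, 13L))
  expect_equal(res$vbmd, rep(0.205, 4), tolerance = 1e-9)
  expect_equal(res$subject, rep("SYN01", 4))
})

test_that("an all-water body reads zero vBMD everywhere", {
  calib <- reference_calibration(0, 1400)
  vol <- make_test_volume(dims = c(32, 32, 16), background = 0)
  path <- withr::local_tempfile(fileext = ".json")
  make_vertebra_annotations(path)
  res <- measure_vertebrae(vol, path, calib)
  expect_equal(res$vbmd, rep(0, 4))
})

test_that("a missing vertebra yields fewer rows plus a warning", {
  calib <- reference_calibration(0, 1400)
  vol <- make_test_volume(dims = c(32, 32, 16), background = 0)
  path <- withr::local_tempfile(fileext = ".json")
  make_vertebra_annotations(path, vertebrae = c("L1", "L2", "L4"))
  expect_warning(res <- measure_vertebrae(vol, path, calib),
                 regexp = "L3")
  expect_equal(nrow(res), 3)
})
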