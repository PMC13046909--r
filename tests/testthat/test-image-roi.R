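test_that("ROI mean on a uniform image is the uniform value", {
  img <- matrix(100, 120, 120)
  pair <- spectral_image_pair(img, img, pixel_spacing = 1)
  for (area in c(0.5, 2, 4)) {
    m <- roi_mean(pair, roi_spec(c(60, 60), area_cm2 = area))
    expect_equal(m$le_mean, 100)
    expect_equal(m$he_mean, 100)
  }
})

test_that("ROI mean agrees exactly with a brute-force pixel oracle", {
  set.seed(99)
  spacing <- 0.8
  low <- matrix(rnorm(80 * 90, 50, 20), 80, 90)
  high <- matrix(rnorm(80 * 90, 20, 20), 80, 90)
  pair <- spectral_image_pair(low, high, spacing)
  for (i in 1:5) {
    center <- runif(2, 20, 40)
    area <- runif(1, 0.5, 3)
    roi <- roi_spec(center, area_cm2 = area)
    m <- roi_mean(pair, roi)
    o_low <- brute_force_roi_mean(low, spacing, center, roi$radius_mm)
    o_high <- brute_force_roi_mean(high, spacing, center, roi$radius_mm)
    expect_identical(m$le_mean, o_low$mean)
    expect_identical(m$he_mean, o_high$mean)
    expect_identical(m$n_pixels, o_low$n)
    # same pixel count in both channels
    expect_identical(o_low$n, o_high$n)
  }
})

test_that("half-plane ROI centered on the boundary averages to the midpoint", {
  n <- 100
  img <- matrix(0, n, n)
  img[, ((n / 2) + 1):n] <- 200  # step at x = 49.5 mm with 1 mm pixels
  pair <- spectral_image_pair(img, img, pixel_spacing = 1)
  m <- roi_mean(pair, roi_spec(c(49.5, 50), area_cm2 = 4))
  expect_equal(m$le_mean, 100)  # mask is symmetric about the step
})

test_that("selected pixel count approximates the circle area", {
  # pixel-center counting error scales with perimeter/area, so the small
  # 2 cm2 ROI needs finer sampling than the 4 cm2 one
  cases <- data.frame(spacing = c(0.5, 1, 0.5), area = c(4, 4, 2))
  for (k in seq_len(nrow(cases))) {
    spacing <- cases$spacing[k]
    n <- ceiling(120 / spacing)
    img <- matrix(0, n, n)
    pair <- spectral_image_pair(img, img, spacing)
    m <- roi_mean(pair, roi_spec(c(60, 60), area_cm2 = cases$area[k]))
    expect_equal(m$n_pixels * spacing^2, cases$area[k] * 100,
                 tolerance = 0.03)
  }
})

test_that("out-of-bounds and degenerate ROIs are rejected", {
  pair <- spectral_image_pair(matrix(0, 50, 50), matrix(0, 50, 50), 1)
  expect_error(roi_mean(pair, roi_spec(c(2, 25), area_cm2 = 4)), "bounds")
  expect_error(roi_mean(pair, roi_spec(c(25, 48.5), area_cm2 = 4)), "bounds")
  expect_error(spectral_image_pair(matrix(0, 2, 2), matrix(0, 3, 2), 1),
               "different shapes")
  expect_error(spectral_image_pair(matrix(0, 2, 2), matrix(0, 2, 2), 0),
               "positive")
})

test_that("3-D ROI means average the requested slices", {
  set.seed(3)
  vol_low <- array(rnorm(40 * 40 * 5, 100, 10), c(40, 40, 5))
  vol_high <- array(rnorm(40 * 40 * 5, 50, 10), c(40, 40, 5))
  pair <- spectral_image_pair(vol_low, vol_high, 1)
  roi_all <- roi_spec(c(20, 20), area_cm2 = 2, slices = 1:5)
  m <- roi_mean(pair, roi_all)
  per_slice <- vapply(1:5, function(k) {
    roi_mean(pair, roi_spec(c(20, 20), area_cm2 = 2, slices = k))$le_mean
  }, 0)
  expect_equal(m$le_mean, mean(per_slice))
  # default slice selection is the central slice
  expect_equal(roi_mean(pair, roi_spec(c(20, 20), area_cm2 = 2))$le_mean,
               per_slice[3])
  expect_error(roi_mean(pair, roi_spec(c(20, 20), 2, slices = 6)),
               "out of range")
})

test_that("raw fixture image pairs round-trip bit-exactly", {
  spec <- phantom_spec("iron", kv = "120", noise_sd = c(5, 5), seed = 21)
  pair <- generate_phantom(spec)$pair
  dir <- withr::local_tempdir()
  write_image_pair(pair, dir, prefix = "fix")
  back <- load_image_pair(file.path(dir, "fix_low.raw"),
                          file.path(dir, "fix_high.raw"))
  expect_identical(back$low, pair$low)
  expect_identical(back$high, pair$high)
  expect_identical(back$pixel_spacing, pair$pixel_spacing)
  expect_identical(back$metadata$material, "iron")

  # geometry mismatch between channels is refused
  other <- spectral_image_pair(matrix(0, 10, 10), matrix(0, 10, 10), 1.5)
  write_image_pair(other, dir, prefix = "small")
  expect_error(load_image_pair(file.path(dir, "fix_low.raw"),
                               file.path(dir, "small_high.raw")),
               "geometry mismatch")
  expect_error(load_image_pair(file.path(dir, "nope_low.raw"),
                               file.path(dir, "fix_high.raw")), "not found")
})

test_that("NIfTI image pairs load with spacing from the header", {
  dir <- withr::local_tempdir()
  set.seed(5)
  low <- matrix(rnorm(64 * 64, 40, 5), 64, 64)
  high <- matrix(rnorm(64 * 64, 10, 5), 64, 64)
  lp <- file.path(dir, "low.nii.gz"); hp <- file.path(dir, "high.nii.gz")
  nlow <- RNifti::asNifti(low); RNifti::pixdim(nlow) <- c(1.2, 1.2)
  nhigh <- RNifti::asNifti(high); RNifti::pixdim(nhigh) <- c(1.2, 1.2)
  RNifti::writeNifti(nlow, lp)
  RNifti::writeNifti(nhigh, hp)
  pair <- load_image_pair(lp, hp, metadata = list(material = "iodine",
                                                  kv = "140", dose_pct = 100,
                                                  fat_ring = FALSE))
  expect_equal(pair$pixel_spacing, 1.2, tolerance = 1e-6)
  expect_equal(as.numeric(pair$low), as.numeric(low), tolerance = 1e-6)
  m <- extract_measurements(pair,
                            data.frame(center_x_mm = 37.8, center_y_mm = 37.8,
                                       concentration_mg_ml = 2),
                            area_cm2 = 2)
  expect_equal(nrow(m), 1)
  expect_identical(m$material, "iodine")
})

test_that("measurement extraction copies metadata and keeps duplicates", {
  spec <- phantom_spec("iodine", kv = "140", noise_sd = c(0, 0))
  g <- generate_phantom(spec)
  rods <- g$manifest$rods
  # duplicate concentration: two rods, two rows
  rods2 <- rbind(rods[, 1:3], rods[1, 1:3])
  tab <- extract_measurements(g$pair, rods2, area_cm2 = 2)
  expect_equal(nrow(tab), nrow(rods) + 1)
  expect_identical(tab$kv, rep("140", nrow(tab)))

  empty <- extract_measurements(g$pair, rods[0, ], area_cm2 = 2)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("le_hu", "he_hu") %in% names(empty)))
})
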