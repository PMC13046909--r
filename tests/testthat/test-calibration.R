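test_that("base-material intercepts are read off noiseless lines", {
  conc <- c(0.5, 1, 2, 5, 10, 15)
  tab <- data.frame(material = "iodine", kv = "140", dose_pct = 100,
                    fat_ring = FALSE, concentration_mg_ml = conc,
                    le_hu = 26 * conc - 5.0, he_hu = 10 * conc + 0.7)
  fit <- fit_base_intercepts(tab)
  expect_equal(fit$le_base, -5.0)
  expect_equal(fit$he_base, 0.7)
  expect_equal(fit$delta_base, 5.7)

  # all-zero channels give zero intercepts
  tab$le_hu <- tab$he_hu <- 0
  fit0 <- fit_base_intercepts(tab)
  expect_equal(c(fit0$le_base, fit0$he_base, fit0$delta_base), c(0, 0, 0))
})

test_that("DER fit recovers the material-line slope", {
  conc <- c(1, 2, 5, 10)
  he <- 10 * conc - 7
  tab <- data.frame(material = "iodine", kv = "140", dose_pct = 100,
                    fat_ring = FALSE, concentration_mg_ml = conc,
                    le_hu = 2.5 * he + 3, he_hu = he)
  expect_equal(fit_der(tab)$der, 2.5)

  # points on the water line give slope 1, rejected downstream by der > 1
  tab$le_hu <- tab$he_hu
  expect_equal(fit_der(tab)$der, 1)
  expect_error(cm_measured(10, 5, der = fit_der(tab)$der), "exceed 1")

  # no spread in the predictor
  tab$he_hu <- 5
  expect_error(fit_der(tab), "zero variance")
})

test_that("alpha fit recovers the CM-per-concentration slope", {
  tab <- make_linear_roi_table(a_low = 26.3, der = 2.49,
                               le_base = -2, he_base = -7)
  spec <- phantom_spec("iodine", kv = "140")
  # by construction cm_corrected = implied_alpha * C exactly
  fit <- fit_alpha(tab, der = 2.49, w = 0.5, delta_base = -5)
  expect_equal(fit$alpha, implied_alpha(spec, w = 0.5), tolerance = 1e-9)
  # intercept is a QC diagnostic, ~0 after the delta_base correction
  expect_lt(abs(fit$diagnostics$intercept), 1e-9)

  # all-zero CM values give slope 0 (flagged invalid downstream)
  tab0 <- tab
  tab0$le_hu <- tab0$he_hu <- 10  # matched channels, delta_base = 0
  fit0 <- fit_alpha(tab0, der = 2.49, w = 0.5, delta_base = 0)
  expect_equal(fit0$alpha, 0)
  expect_error(concentration_from_cm(1, alpha = fit0$alpha), "> 0")
})

test_that("alpha rescales exactly with the w blending factor", {
  tab <- make_linear_roi_table()
  der <- fit_der(tab)$der
  delta <- fit_base_intercepts(tab)$delta_base
  a_half <- fit_alpha(tab, der, w = 0.5, delta_base = delta)$alpha
  a_one <- fit_alpha(tab, der, w = 1.0, delta_base = delta)$alpha
  expect_equal(a_one / a_half, der / (der * 0.5 + 0.5), tolerance = 1e-9)
})

test_that("configuration calibration recovers noiseless ground truth", {
  truth <- list(le_base = -2, he_base = -7, a_low = 26.3, der = 2.49)
  tab <- make_linear_roi_table(le_base = truth$le_base,
                               he_base = truth$he_base,
                               a_low = truth$a_low, der = truth$der)
  rec <- calibrate_configuration(tab, w = 0.5)
  expect_rel_equal(rec$le_base, truth$le_base)
  expect_rel_equal(rec$he_base, truth$he_base)
  expect_rel_equal(rec$delta_base, -5)
  expect_rel_equal(rec$der, truth$der)
  expect_rel_equal(rec$alpha,
                   (truth$der * 0.5 + 0.5) * truth$a_low / truth$der)
  expect_identical(rec$material, "iodine")
  expect_identical(rec$n_rods, 6L)
})

test_that("degenerate calibration inputs are rejected", {
  tab <- make_linear_roi_table()
  expect_error(calibrate_configuration(tab[0, ]), "distinct")
  expect_error(calibrate_configuration(tab[1, ]), "distinct")
  two_cfg <- rbind(tab, transform(tab, dose_pct = 200))
  expect_error(calibrate_configuration(two_cfg), "more than one")
  expect_equal(length(calibrate_study(two_cfg)), 2)
})

test_that("mean-method aggregation uses mean and n-1 standard deviation", {
  # single record: means equal the record, SDs reported as 0
  rec <- calibrate_configuration(make_linear_roi_table(), w = 0.5)
  p1 <- aggregate_mean_method(list(rec))
  expect_equal(p1$der_avg, rec$der)
  expect_equal(p1$der_sd, 0)
  expect_identical(p1$n_configs, 1L)

  tab <- data.frame(material = "iron", kv = "120",
                    delta_base = c(-4.24, -4.58, -5.64, -2.66, -3.50, -4.64),
                    der = c(1.95, 1.91, 1.92, 1.93, 1.96, 1.91),
                    alpha = c(4.03, 4.05, 4.02, 4.12, 4.07, 4.09))
  p <- aggregate_mean_method(tab, w = 0.5)
  expect_equal(p$der_avg, mean(tab$der))
  expect_equal(p$alpha_sd, sd(tab$alpha))
  expect_equal(round(p$alpha_avg, 2), 4.06)

  # mixed groups are refused
  tab2 <- tab; tab2$kv[1] <- "140"
  expect_error(aggregate_mean_method(tab2), "mixed")
  expect_equal(length(aggregate_study(tab2)), 2)
})

test_that("mean-method quantification separates corrected and uncorrected", {
  tab <- make_linear_roi_table()
  rec <- calibrate_configuration(tab, w = 0.5)
  params <- aggregate_mean_method(list(rec))
  out <- quantify_with_mean_method(tab, params)

  # rods generated exactly on the calibrated model quantify exactly
  expect_rel_equal(out$concentration_corrected, tab$concentration_mg_ml, 1e-8)
  expect_true(all(abs(out$error_corrected_pct) < 1e-6))
  # skipping the delta_base term biases every rod; here delta_base = -5 < 0
  expect_true(all(abs(out$error_uncorrected_pct) >
                    abs(out$error_corrected_pct)))
  # fixed absolute CM bias: relative error shrinks as concentration grows
  expect_true(all(diff(abs(out$error_uncorrected_pct)[
    order(out$concentration_mg_ml)]) < 0))

  # a zero-concentration rod is quantified but has no defined error
  tab0 <- rbind(tab, transform(tab[1, ], concentration_mg_ml = 0,
                               le_hu = -2, he_hu = -7))
  out0 <- quantify_with_mean_method(tab0, params)
  z <- out0$concentration_mg_ml == 0
  expect_true(is.na(out0$error_corrected_pct[z]))
  expect_true(is.na(out0$error_uncorrected_pct[z]))
  expect_false(anyNA(out0$concentration_corrected))
})

test_that("ROI tables round-trip through CSV and are validated", {
  tab <- make_linear_roi_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_roi_table(tab, path)
  back <- read_roi_table(path)
  expect_equal(back, tab)

  expect_error(validate_roi_table(tab[-5]), "missing columns")
  bad <- tab; bad$concentration_mg_ml[1] <- -1
  expect_error(validate_roi_table(bad), ">= 0")
  bad <- tab; bad$le_hu[2] <- NA
  expect_error(validate_roi_table(bad), "finite")
})

test_that("calibration records and mean-method params round-trip YAML", {
  tab <- rbind(make_linear_roi_table(),
               make_linear_roi_table(dose_pct = 200, a_low = 26.5))
  records <- calibrate_study(tab, w = 0.5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_calibration_records(records, path)
  back <- read_calibration_records(path)
  expect_equal(length(back), 2)
  expect_equal(calibration_table(back), calibration_table(records),
               tolerance = 1e-12)

  params <- aggregate_study(records)
  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_mean_method_params(params, path2)
  back2 <- read_mean_method_params(path2)
  expect_equal(mean_method_table(back2), mean_method_table(params),
               tolerance = 1e-12)
})
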