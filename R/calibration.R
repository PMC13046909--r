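#' @importFrom stats lm coef sd var setNames
NULL

roi_table_columns <- c("material", "kv", "dose_pct", "fat_ring",
                       "concentration_mg_ml", "le_hu", "he_hu")

#' Validate a ROI measurement table
#'
#' A ROI measurement table holds one row per phantom rod per scan
#' configuration: mean low-/high-energy HU inside the rod ROI, the known rod
#' concentration, and the acquisition metadata that identifies the
#' configuration.
#'
#' @param x A data.frame with columns \code{material}, \code{kv},
#'   \code{dose_pct}, \code{fat_ring}, \code{concentration_mg_ml},
#'   \code{le_hu}, \code{he_hu}.
#' @return The validated data.frame (invisibly coerced types:
#'   \code{fat_ring} to logical, numeric columns to numeric).
#' @export
validate_roi_table <- function(x) {
  if (!is.data.frame(x)) stop("ROI table must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(roi_table_columns, names(x))
  if (length(missing_cols) > 0) {
    stop("ROI table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x$fat_ring <- as.logical(x$fat_ring)
  x$material <- as.character(x$material)
  x$kv <- as.character(x$kv)
  for (col in c("dose_pct", "concentration_mg_ml", "le_hu", "he_hu")) {
    x[[col]] <- as.numeric(x[[col]])
  }
  if (any(!is.finite(x$le_hu)) || any(!is.finite(x$he_hu))) {
    stop("ROI table HU values must be finite", call. = FALSE)
  }
  if (any(x$concentration_mg_ml < 0)) {
    stop("rod concentrations must be >= 0", call. = FALSE)
  }
  if (any(!nzchar(as.character(x$material))) || any(!nzchar(as.character(x$kv)))) {
    stop("material and kv labels must be non-empty", call. = FALSE)
  }
  x
}

#' Read / write a ROI measurement table
#'
#' Comma-separated text with a mandatory header; columns \code{material},
#' \code{kv}, \code{dose_pct}, \code{fat_ring}, \code{concentration_mg_ml},
#' \code{le_hu}, \code{he_hu}.
#'
#' @param path File path.
#' @return \code{read_roi_table} returns the validated data.frame.
#' @export
read_roi_table <- function(path) {
  if (!file.exists(path)) stop("ROI table not found: ", path, call. = FALSE)
  validate_roi_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_roi_table
#' @param x ROI measurement table (data.frame).
#' @export
write_roi_table <- function(x, path) {
  x <- validate_roi_table(x)
  utils::write.csv(x[roi_table_columns], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.check_fit_input <- function(measurements) {
  measurements <- validate_roi_table(measurements)
  if (length(unique(measurements$concentration_mg_ml)) < 2) {
    stop("need >= 2 distinct rod concentrations to fit", call. = FALSE)
  }
  measurements
}

# Slope/intercept plus the diagnostics reported in calibration records.
.ols <- function(y, x) {
  fit <- lm(y ~ x)
  # summary.lm warns on exact fits; noiseless phantoms are a supported input
  s <- suppressWarnings(summary(fit))
  list(intercept = unname(coef(fit)[1]),
       slope = unname(coef(fit)[2]),
       r_squared = if (is.null(s$r.squared)) NA_real_ else s$r.squared,
       residual_se = s$sigma)
}

#' Fit base-material CT numbers from rod measurements
#'
#' Ordinary-least-squares fits of mean low- and high-energy HU against known
#' rod concentration; the y-intercepts are the low- and high-energy CT
#' numbers of the base material (LE_base, HE_base), i.e. what the base
#' material reads in each channel at zero contrast concentration. Their
#' mismatch is \code{delta_base = he_base - le_base} — the sign for which
#' the corrected CM of a pure base-material voxel is exactly 0.
#'
#' @param measurements ROI measurement table for a single scan
#'   configuration; needs at least 2 distinct concentrations.
#' @return List with \code{le_base}, \code{he_base}, \code{delta_base} (HU)
#'   and \code{diagnostics} (per-channel slope, R-squared, residual SE).
#' @export
fit_base_intercepts <- function(measurements) {
  m <- .check_fit_input(measurements)
  fit_le <- .ols(m$le_hu, m$concentration_mg_ml)
  fit_he <- .ols(m$he_hu, m$concentration_mg_ml)
  list(le_base = fit_le$intercept,
       he_base = fit_he$intercept,
       delta_base = fit_he$intercept - fit_le$intercept,
       diagnostics = list(le = fit_le, he = fit_he))
}

#' Fit the dual-energy ratio of one configuration
#'
#' Regresses mean low-energy HU on mean high-energy HU across the rods
#' (free intercept); the slope is the DER, the slope of the material line
#' in the (HE, LE) plane. Along the rod series only the contrast
#' concentration varies, so the points move parallel to the material line
#' and the slope isolates the material's low/high response ratio even in
#' the presence of base offsets.
#'
#' @inheritParams fit_base_intercepts
#' @return List with \code{der} and \code{diagnostics}.
#' @export
fit_der <- function(measurements) {
  m <- .check_fit_input(measurements)
  if (var(m$he_hu) == 0) {
    stop("zero variance in high-energy HU: cannot fit DER", call. = FALSE)
  }
  fit <- .ols(m$le_hu, m$he_hu)
  list(der = fit$slope, diagnostics = fit)
}

#' Fit the concentration scaling factor alpha
#'
#' Computes the corrected CM value of every rod (using the supplied
#' \code{der}, \code{w} and \code{delta_base}) and regresses it on the known
#' concentration with a free intercept. The slope is \code{alpha} (HU per
#' mg/mL); the intercept is retained as a QC diagnostic and should be near 0
#' once \code{delta_base} is corrected for.
#'
#' @inheritParams fit_base_intercepts
#' @param der Dual-energy ratio (> 1).
#' @param w Weighting factor in [0, 1].
#' @param delta_base Base-material mismatch (HU).
#' @return List with \code{alpha} and \code{diagnostics}.
#' @export
fit_alpha <- function(measurements, der, w = 0.5, delta_base = 0) {
  m <- .check_fit_input(measurements)
  cm <- cm_corrected(m$le_hu, m$he_hu, der = der, w = w,
                     delta_base = delta_base)
  fit <- .ols(cm, m$concentration_mg_ml)
  list(alpha = fit$slope, diagnostics = fit)
}

#' Calibrate one scan configuration
#'
#' Chains the three calibration fits on the rods of a single configuration:
#' base-material intercepts (delta_base), the dual-energy ratio (DER), and
#' the concentration scaling factor (alpha, computed from corrected CM
#' values with the just-fitted delta_base and DER).
#'
#' @inheritParams fit_base_intercepts
#' @param w Weighting factor used for the alpha fit (and recorded).
#' @return A \code{"calibration_record"}: \code{le_base}, \code{he_base},
#'   \code{delta_base}, \code{der}, \code{alpha}, \code{w}, fit
#'   \code{diagnostics}, and the configuration metadata (\code{material},
#'   \code{kv}, \code{dose_pct}, \code{fat_ring}, \code{n_rods}).
#' @export
calibrate_configuration <- function(measurements, w = 0.5) {
  m <- .check_fit_input(measurements)
  .check_w(w)
  key <- unique(m[c("material", "kv", "dose_pct", "fat_ring")])
  if (nrow(key) != 1) {
    stop("measurements span more than one scan configuration; ",
         "use calibrate_study()", call. = FALSE)
  }
  base <- fit_base_intercepts(m)
  der <- fit_der(m)
  alpha <- fit_alpha(m, der = der$der, w = w, delta_base = base$delta_base)
  structure(list(
    material = as.character(key$material), kv = as.character(key$kv),
    dose_pct = key$dose_pct, fat_ring = key$fat_ring,
    le_base = base$le_base, he_base = base$he_base,
    delta_base = base$delta_base, der = der$der, alpha = alpha$alpha,
    w = w, n_rods = nrow(m),
    diagnostics = list(base_le = base$diagnostics$le,
                       base_he = base$diagnostics$he,
                       der = der$diagnostics,
                       alpha = alpha$diagnostics)
  ), class = "calibration_record")
}

#' @export
print.calibration_record <- function(x, ...) {
  cat(sprintf("Calibration record: %s, %s kV, %g%% dose, fat ring %s (%d rods)\n",
              x$material, x$kv, x$dose_pct, ifelse(x$fat_ring, "yes", "no"),
              x$n_rods))
  cat(sprintf("  delta_base = %8.3f HU   (LE_base %.3f, HE_base %.3f)\n",
              x$delta_base, x$le_base, x$he_base))
  cat(sprintf("  DER        = %8.4f\n", x$der))
  cat(sprintf("  alpha      = %8.4f HU per mg/mL   (w = %.2f)\n", x$alpha, x$w))
  invisible(x)
}

#' Calibrate every configuration in a ROI table
#'
#' Splits a ROI measurement table by (material, kv, dose_pct, fat_ring) and
#' calibrates each group.
#'
#' @param roi_table ROI measurement table (or path to one).
#' @param w Weighting factor.
#' @return List of \code{\link{calibrate_configuration}} records.
#' @export
calibrate_study <- function(roi_table, w = 0.5) {
  if (is.character(roi_table)) roi_table <- read_roi_table(roi_table)
  m <- validate_roi_table(roi_table)
  key <- interaction(m$material, m$kv, m$dose_pct, m$fat_ring, drop = TRUE)
  groups <- split(m, key)
  records <- lapply(groups, calibrate_configuration, w = w)
  names(records) <- NULL
  records
}

#' Flatten calibration records to a table
#'
#' @param records List of calibration records (or a single record).
#' @return data.frame with one row per configuration, mirroring the
#'   per-configuration parameter table (delta_base, DER, alpha plus
#'   metadata).
#' @export
calibration_table <- function(records) {
  if (inherits(records, "calibration_record")) records <- list(records)
  do.call(rbind, lapply(records, function(r) {
    data.frame(material = r$material, kv = r$kv, dose_pct = r$dose_pct,
               fat_ring = r$fat_ring, le_base = r$le_base,
               he_base = r$he_base, delta_base = r$delta_base, der = r$der,
               alpha = r$alpha, w = r$w, n_rods = r$n_rods,
               stringsAsFactors = FALSE)
  }))
}

#' Mean-method parameters for one material and tube voltage
#'
#' Per-(material, kV) averages of delta_base, DER and alpha across scan
#' configurations (dose levels, fat-ring states), with sample standard
#' deviations. These are the site-specific parameters a center plugs into
#' the corrected concentration conversion.
#'
#' @param delta_base_avg,der_avg,alpha_avg Means across configurations.
#' @param delta_base_sd,der_sd,alpha_sd Sample standard deviations
#'   (n - 1 denominator); 0 when a single configuration is supplied.
#' @param n_configs Number of configurations averaged.
#' @param w Weighting factor the alphas were fitted with.
#' @param material,kv Group labels.
#' @return Object of class \code{"mean_method_params"}.
#' @export
mean_method_params <- function(delta_base_avg, der_avg, alpha_avg,
                               delta_base_sd = 0, der_sd = 0, alpha_sd = 0,
                               n_configs = 1L, w = 0.5,
                               material = "", kv = "") {
  .check_der(der_avg); .check_w(w); .check_alpha(alpha_avg)
  stopifnot(n_configs >= 1, delta_base_sd >= 0, der_sd >= 0, alpha_sd >= 0)
  structure(list(material = material, kv = kv,
                 delta_base_avg = delta_base_avg, delta_base_sd = delta_base_sd,
                 der_avg = der_avg, der_sd = der_sd,
                 alpha_avg = alpha_avg, alpha_sd = alpha_sd,
                 n_configs = as.integer(n_configs), w = w),
            class = "mean_method_params")
}

#' @export
print.mean_method_params <- function(x, ...) {
  cat(sprintf("Mean-method parameters: %s, %s kV (%d configurations, w = %.2f)\n",
              x$material, x$kv, x$n_configs, x$w))
  cat(sprintf("  delta_base_avg = %7.2f +/- %.2f HU\n",
              x$delta_base_avg, x$delta_base_sd))
  cat(sprintf("  DER_avg        = %7.2f +/- %.2f\n", x$der_avg, x$der_sd))
  cat(sprintf("  alpha_avg      = %7.2f +/- %.2f HU per mg/mL\n",
              x$alpha_avg, x$alpha_sd))
  invisible(x)
}

#' Average calibration records into mean-method parameters
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' delta_base, DER and alpha over the scan configurations of one material
#' and tube voltage, averaging over dose levels and fat-ring states. With a
#' single record the means equal the record and SDs are reported as 0.
#'
#' @param records List of calibration records, or a data.frame with columns
#'   \code{delta_base}, \code{der}, \code{alpha} (and optionally
#'   \code{material}, \code{kv}). All rows must share one material and kV.
#' @param w Weighting factor to record; defaults to the records' common
#'   \code{w} (data.frame input without a \code{w} column uses 0.5).
#' @return A \code{\link{mean_method_params}} object.
#' @export
aggregate_mean_method <- function(records, w = NULL) {
  if (is.data.frame(records)) {
    tab <- records
  } else {
    if (inherits(records, "calibration_record")) records <- list(records)
    if (length(records) == 0) stop("no calibration records", call. = FALSE)
    tab <- calibration_table(records)
  }
  needed <- c("delta_base", "der", "alpha")
  if (!all(needed %in% names(tab))) {
    stop("records must provide delta_base, der and alpha", call. = FALSE)
  }
  if (!"material" %in% names(tab)) tab$material <- ""
  if (!"kv" %in% names(tab)) tab$kv <- ""
  if (length(unique(tab$material)) > 1 || length(unique(tab$kv)) > 1) {
    stop("mixed material/kV group: aggregate per material and tube voltage",
         call. = FALSE)
  }
  if (is.null(w)) {
    w <- if ("w" %in% names(tab)) {
      if (length(unique(tab$w)) > 1) {
        stop("records were calibrated with different w", call. = FALSE)
      }
      tab$w[1]
    } else 0.5
  }
  n <- nrow(tab)
  sd0 <- function(x) if (n > 1) sd(x) else 0
  mean_method_params(
    delta_base_avg = mean(tab$delta_base), delta_base_sd = sd0(tab$delta_base),
    der_avg = mean(tab$der), der_sd = sd0(tab$der),
    alpha_avg = mean(tab$alpha), alpha_sd = sd0(tab$alpha),
    n_configs = n, w = w, material = tab$material[1], kv = as.character(tab$kv[1])
  )
}

#' Aggregate a whole study per (material, kV)
#'
#' @param records List of calibration records or a calibration table.
#' @param w Weighting factor (see \code{\link{aggregate_mean_method}}).
#' @return Named list of \code{mean_method_params}, one per
#'   (material, kV) group; names are \code{"material_kv"}.
#' @export
aggregate_study <- function(records, w = NULL) {
  tab <- if (is.data.frame(records)) records else calibration_table(records)
  groups <- split(tab, interaction(tab$material, tab$kv, drop = TRUE))
  out <- lapply(groups, aggregate_mean_method, w = w)
  names(out) <- vapply(out, function(p) paste(p$material, p$kv, sep = "_"),
                       character(1))
  out
}

#' Mean-method parameters as a one-row table
#'
#' @param params A \code{mean_method_params} object or list of them.
#' @return data.frame mirroring the per-kV summary table
#'   (means and SDs of delta_base, DER, alpha).
#' @export
mean_method_table <- function(params) {
  if (inherits(params, "mean_method_params")) params <- list(params)
  do.call(rbind, lapply(params, function(p) {
    data.frame(material = p$material, kv = p$kv,
               delta_base_avg = p$delta_base_avg, delta_base_sd = p$delta_base_sd,
               der_avg = p$der_avg, der_sd = p$der_sd,
               alpha_avg = p$alpha_avg, alpha_sd = p$alpha_sd,
               n_configs = p$n_configs, w = p$w, stringsAsFactors = FALSE)
  }))
}

#' Quantify rods with the mean method
#'
#' Converts each rod's mean (LE, HE) pair to a concentration estimate with
#' the mean-method parameters: the uncorrected CM value via
#' \code{\link{cm_measured}} (using \code{der_avg} and \code{w}), then the
#' corrected concentration via \code{\link{mean_method_concentration}}. An
#' uncorrected estimate (same formula with \code{delta_base_avg} forced to
#' 0) is reported alongside for comparison. Relative errors versus the known
#' concentrations are included; rods with a true concentration of 0 are
#' still quantified but their error columns are NA (relative error
#' undefined).
#'
#' @param measurements ROI measurement table.
#' @param params A \code{\link{mean_method_params}} object.
#' @return data.frame: the input metadata plus \code{cm_measured_hu},
#'   \code{concentration_corrected}, \code{concentration_uncorrected},
#'   \code{error_corrected_pct}, \code{error_uncorrected_pct}.
#' @export
quantify_with_mean_method <- function(measurements, params) {
  m <- validate_roi_table(measurements)
  cm <- cm_measured(m$le_hu, m$he_hu, der = params$der_avg, w = params$w)
  conc_corr <- mean_method_concentration(cm, params)
  conc_unc <- concentration_from_cm(cm, params$alpha_avg)
  nonzero <- m$concentration_mg_ml != 0
  err_corr <- err_unc <- rep(NA_real_, nrow(m))
  err_corr[nonzero] <- relative_error(conc_corr[nonzero],
                                      m$concentration_mg_ml[nonzero])
  err_unc[nonzero] <- relative_error(conc_unc[nonzero],
                                     m$concentration_mg_ml[nonzero])
  cbind(m[roi_table_columns],
        data.frame(cm_measured_hu = cm,
                   concentration_corrected = conc_corr,
                   concentration_uncorrected = conc_unc,
                   error_corrected_pct = err_corr,
                   error_uncorrected_pct = err_unc))
}

#' Example per-configuration calibration table
#'
#' Per-configuration \code{delta_base}, DER and alpha values measured on a
#' clinical photon-counting CT system with a QRM spectral abdomen phantom
#' (iodine-in-water and iron-in-liver rod inserts; 120/140 kV; 100/120/200%
#' dose; with and without a fat ring). Useful as realistic input to
#' \code{\link{aggregate_mean_method}} and in the package's examples.
#'
#' @return data.frame with columns \code{material}, \code{kv},
#'   \code{fat_ring}, \code{dose_pct}, \code{delta_base}, \code{der},
#'   \code{alpha}.
#' @export
example_calibration_table <- function() {
  path <- system.file("extdata", "pcdct_calibration_table.csv",
                      package = "pcdquant", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$fat_ring <- as.logical(tab$fat_ring)
  tab$kv <- as.character(tab$kv)
  tab
}
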