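#' @importFrom stats rnorm dist
NULL

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.default_concentrations <- function(material) {
  switch(material,
         iodine = c(0.5, 1.0, 2.0, 5.0, 10.0, 15.0),
         iron = c(2.0, 5.0, 15.0, 25.0),
         stop("unknown material: ", material, call. = FALSE))
}

.default_true_der <- function(material, kv) {
  ders <- list(iodine = c("140" = 2.49, "120" = 2.10),
               iron = c("140" = 2.18, "120" = 1.93))
  d <- ders[[material]][as.character(kv)]
  if (is.na(d)) stop("no default DER for ", material, " at ", kv, " kV",
                     call. = FALSE)
  unname(d)
}

.default_hu_per_conc_low <- function(material) {
  switch(material, iodine = 26.3, iron = 8.8)
}

# Base-material offsets of the rod matrix: water-equivalent for iodine,
# liver-equivalent for iron. delta_base = he - le = -5 HU in both cases.
.default_base_hu <- function(material) {
  switch(material,
         iodine = c(le = -2, he = -7),
         iron = c(le = 57, he = 52))
}

#' Synthetic spectral abdomen phantom specification
#'
#' Describes a QRM-style spectral abdomen phantom: an elliptic
#' water-equivalent body (optionally wrapped in a fat ring emulating a
#' larger habitus) carrying 20 mm cylindrical rods of contrast material at
#' known concentrations. The spectral ground truth is linear in
#' concentration: a rod at concentration C reads
#' \code{le_base + hu_per_conc_low * C} in the low-energy channel and
#' \code{he_base + (hu_per_conc_low / true_der) * C} in the high-energy
#' channel, before additive Gaussian noise.
#'
#' @param material \code{"iodine"} (in water-equivalent rods) or
#'   \code{"iron"} (in liver-equivalent rods); sets the default
#'   concentration series (0.5-15 mg/mL iodine, 2-25 mg/mL iron), DER and
#'   HU-per-concentration slope.
#' @param kv Tube-voltage label ("120" or "140"); selects the default
#'   \code{true_der} (iodine 2.10/2.49, iron 1.93/2.18).
#' @param dose_pct Dose level in percent; noise SD scales as
#'   \code{1/sqrt(dose_pct/100)}.
#' @param fat_ring Add the outer fat ring (noise inflated by 1.25).
#' @param concentrations Rod concentrations (mg/mL); default per material.
#' @param hu_per_conc_low Low-energy HU per mg/mL (iodine 26.3, iron 8.8).
#' @param true_der Ground-truth dual-energy ratio (> 1).
#' @param le_base,he_base Base-material CT numbers per channel (HU);
#'   defaults give \code{delta_base = he_base - le_base = -5} HU.
#' @param body_hu,fat_hu Length-2 (low, high) HU of the body and fat ring.
#' @param noise_sd Length-2 (low, high) Gaussian noise SD in HU at 100%
#'   dose without fat ring.
#' @param shape Image dimensions (rows, cols).
#' @param pixel_spacing Pixel size in mm.
#' @param n_slices Number of identical-truth slices (independent noise).
#' @param rod_diameter_mm Rod diameter (20 mm).
#' @param rod_ring_radius_mm Radius of the circle the rods sit on.
#' @param seed RNG seed for the noise (NULL: use the current RNG state).
#' @return Object of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(material = "iodine", kv = "140", dose_pct = 100,
                         fat_ring = FALSE, concentrations = NULL,
                         hu_per_conc_low = NULL, true_der = NULL,
                         le_base = NULL, he_base = NULL,
                         body_hu = c(-2, -7), fat_hu = c(-110, -90),
                         noise_sd = c(10, 10), shape = c(256, 256),
                         pixel_spacing = 1.5, n_slices = 1,
                         rod_diameter_mm = 20, rod_ring_radius_mm = 60,
                         seed = NULL) {
  material <- match.arg(material, c("iodine", "iron"))
  kv <- as.character(kv)
  if (is.null(concentrations)) concentrations <- .default_concentrations(material)
  if (is.null(hu_per_conc_low)) hu_per_conc_low <- .default_hu_per_conc_low(material)
  if (is.null(true_der)) true_der <- .default_true_der(material, kv)
  base <- .default_base_hu(material)
  if (is.null(le_base)) le_base <- unname(base["le"])
  if (is.null(he_base)) he_base <- unname(base["he"])
  .check_der(true_der)
  stopifnot(all(concentrations >= 0), hu_per_conc_low > 0,
            all(noise_sd >= 0), dose_pct > 0, pixel_spacing > 0,
            n_slices >= 1, rod_diameter_mm > 0)

  # body ellipse: 300 x 200 mm; fat ring extends it to 350 x 250 mm
  center <- (rev(shape) - 1) * pixel_spacing / 2  # (x, y) mm
  spec <- structure(list(
    material = material, kv = kv, dose_pct = dose_pct, fat_ring = fat_ring,
    concentrations = concentrations, hu_per_conc_low = hu_per_conc_low,
    true_der = true_der, le_base = le_base, he_base = he_base,
    delta_base = he_base - le_base,
    body_hu = body_hu, fat_hu = fat_hu,
    body_axes_mm = c(150, 100), fat_axes_mm = c(175, 125),
    center_mm = center, noise_sd = noise_sd, shape = as.integer(shape),
    pixel_spacing = pixel_spacing, n_slices = as.integer(n_slices),
    rod_radius_mm = rod_diameter_mm / 2,
    rod_ring_radius_mm = rod_ring_radius_mm, seed = seed
  ), class = "phantom_spec")
  spec$rods <- .rod_layout(spec)
  .validate_phantom_spec(spec)
  spec
}

# Evenly spaced rod centers on a circle around the phantom center.
.rod_layout <- function(spec) {
  n <- length(spec$concentrations)
  angles <- 2 * pi * (seq_len(n) - 1) / n
  data.frame(center_x_mm = spec$center_mm[1] + spec$rod_ring_radius_mm * cos(angles),
             center_y_mm = spec$center_mm[2] + spec$rod_ring_radius_mm * sin(angles),
             concentration_mg_ml = spec$concentrations)
}

.validate_phantom_spec <- function(spec) {
  rods <- spec$rods
  r <- spec$rod_radius_mm
  n <- nrow(rods)
  if (n >= 2) {
    d <- as.matrix(dist(rods[c("center_x_mm", "center_y_mm")]))
    if (min(d[upper.tri(d)]) <= 2 * r) {
      stop("phantom spec invalid: rod circles overlap", call. = FALSE)
    }
  }
  # conservative inside-ellipse test: bounding offset by the rod radius
  dx <- abs(rods$center_x_mm - spec$center_mm[1]) + r
  dy <- abs(rods$center_y_mm - spec$center_mm[2]) + r
  if (any((dx / spec$body_axes_mm[1])^2 + (dy / spec$body_axes_mm[2])^2 > 1)) {
    stop("phantom spec invalid: rods extend outside the phantom body",
         call. = FALSE)
  }
  extent <- (rev(spec$shape) - 1) * spec$pixel_spacing
  ax <- if (spec$fat_ring) spec$fat_axes_mm else spec$body_axes_mm
  if (any(spec$center_mm - ax < 0) || any(spec$center_mm + ax > extent)) {
    stop("phantom spec invalid: phantom exceeds the image field of view",
         call. = FALSE)
  }
  invisible(spec)
}

#' Effective noise SD of a phantom configuration
#'
#' Base SD scaled by \code{1/sqrt(dose_pct/100)} and inflated by 1.25 when
#' the fat ring is present (larger habitus, more attenuation).
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @return Length-2 numeric (low, high) SD in HU.
#' @export
effective_noise_sd <- function(spec) {
  spec$noise_sd / sqrt(spec$dose_pct / 100) * if (spec$fat_ring) 1.25 else 1
}

#' Ground-truth alpha implied by a phantom spec
#'
#' For the linear ground truth, the corrected CM of a rod equals
#' \code{(der*w + 1 - w) * hu_per_conc_low / der * C}, so the concentration
#' scaling factor a calibration should recover is
#' \code{(der*w + 1 - w) * hu_per_conc_low / der}.
#'
#' @param spec A \code{\link{phantom_spec}} (or its manifest).
#' @param w Weighting factor.
#' @return alpha in HU per mg/mL.
#' @export
implied_alpha <- function(spec, w = 0.5) {
  der <- spec$true_der
  (der * w + 1 - w) * spec$hu_per_conc_low / der
}

# Noiseless (le, he) of a rod at concentration C.
.rod_truth <- function(spec, conc) {
  list(le = spec$le_base + spec$hu_per_conc_low * conc,
       he = spec$he_base + spec$hu_per_conc_low / spec$true_der * conc)
}

#' Generate a synthetic phantom image pair
#'
#' Rasterizes the phantom (pixel-center membership: air, fat ring, body,
#' rods) into paired low/high-energy HU images and adds independent
#' additive Gaussian noise per channel under the spec's seed. The returned
#' manifest records the exact noiseless rod values and the global spectral
#' truth, so calibration results can be compared against ground truth.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @return List with \code{pair} (a \code{\link{spectral_image_pair}}) and
#'   \code{manifest} (class \code{"phantom_manifest"}).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  sp <- spec$pixel_spacing
  x <- (seq_len(d[2]) - 1) * sp
  y <- (seq_len(d[1]) - 1) * sp
  xx <- matrix(x, nrow = d[1], ncol = d[2], byrow = TRUE)
  yy <- matrix(y, nrow = d[1], ncol = d[2])

  in_ellipse <- function(axes) {
    ((xx - spec$center_mm[1]) / axes[1])^2 +
      ((yy - spec$center_mm[2]) / axes[2])^2 <= 1
  }
  le <- matrix(-1000, d[1], d[2])
  he <- matrix(-1000, d[1], d[2])
  if (spec$fat_ring) {
    ring <- in_ellipse(spec$fat_axes_mm)
    le[ring] <- spec$fat_hu[1]; he[ring] <- spec$fat_hu[2]
  }
  body <- in_ellipse(spec$body_axes_mm)
  le[body] <- spec$body_hu[1]; he[body] <- spec$body_hu[2]

  rods <- spec$rods
  rods$le_noiseless <- NA_real_
  rods$he_noiseless <- NA_real_
  for (i in seq_len(nrow(rods))) {
    truth <- .rod_truth(spec, rods$concentration_mg_ml[i])
    rods$le_noiseless[i] <- truth$le
    rods$he_noiseless[i] <- truth$he
    inside <- (xx - rods$center_x_mm[i])^2 + (yy - rods$center_y_mm[i])^2 <=
      spec$rod_radius_mm^2
    le[inside] <- truth$le
    he[inside] <- truth$he
  }

  sd_eff <- effective_noise_sd(spec)
  n_sl <- spec$n_slices
  stack <- function(img, sd1) {
    vol <- array(img, dim = c(d, n_sl))
    if (sd1 > 0) vol <- vol + rnorm(length(vol), sd = sd1)
    if (n_sl == 1) vol <- array(vol, dim = d)
    vol
  }
  imgs <- .with_seed(spec$seed, list(low = stack(le, sd_eff[1]),
                                     high = stack(he, sd_eff[2])))

  metadata <- list(material = spec$material, kv = spec$kv,
                   dose_pct = spec$dose_pct, fat_ring = spec$fat_ring)
  pair <- spectral_image_pair(imgs$low, imgs$high, sp, metadata)
  manifest <- structure(list(
    material = spec$material, kv = spec$kv, dose_pct = spec$dose_pct,
    fat_ring = spec$fat_ring, true_der = spec$true_der,
    hu_per_conc_low = spec$hu_per_conc_low, le_base = spec$le_base,
    he_base = spec$he_base, delta_base = spec$delta_base,
    implied_alpha_w05 = implied_alpha(spec, w = 0.5),
    rods = rods, seed = spec$seed, noise_sd = sd_eff,
    pixel_spacing = sp, shape = d, n_slices = n_sl
  ), class = "phantom_manifest")
  list(pair = pair, manifest = manifest)
}

#' @export
print.phantom_manifest <- function(x, ...) {
  cat(sprintf("Phantom manifest: %s, %s kV, %g%% dose, fat ring %s\n",
              x$material, x$kv, x$dose_pct, ifelse(x$fat_ring, "yes", "no")))
  cat(sprintf("  truth: DER %.3f, delta_base %.2f HU, %.2f HU/(mg/mL) low, %d rods\n",
              x$true_der, x$delta_base, x$hu_per_conc_low, nrow(x$rods)))
  cat(sprintf("  noise SD (low, high): %.2f, %.2f HU; seed %s\n",
              x$noise_sd[1], x$noise_sd[2],
              ifelse(is.null(x$seed), "none", x$seed)))
  invisible(x)
}

#' Generate the full 12-configuration phantom study
#'
#' Replicates the study design for one material: 2 tube voltages x 3 dose
#' levels (100, 120, 200%) x fat ring on/off, with a per-kV ground-truth
#' DER and dose-scaled noise. Each configuration gets a deterministic seed
#' derived from \code{seed}.
#'
#' @param material \code{"iodine"} or \code{"iron"}.
#' @param seed Integer base seed; configuration k uses \code{seed + k}.
#' @param noise_sd Length-2 noise SD at 100% dose (0 for a noiseless study).
#' @param ... Further arguments passed to \code{\link{phantom_spec}}.
#' @return List of class \code{"phantom_study"}: one element per
#'   configuration with \code{spec}, \code{pair}, \code{manifest}.
#' @export
generate_study <- function(material = "iodine", seed = 1,
                           noise_sd = c(10, 10), ...) {
  grid <- expand.grid(kv = c("140", "120"), dose_pct = c(100, 120, 200),
                      fat_ring = c(FALSE, TRUE), stringsAsFactors = FALSE)
  configs <- lapply(seq_len(nrow(grid)), function(k) {
    spec <- phantom_spec(material = material, kv = grid$kv[k],
                         dose_pct = grid$dose_pct[k],
                         fat_ring = grid$fat_ring[k], noise_sd = noise_sd,
                         seed = if (is.null(seed)) NULL else seed + k, ...)
    c(list(spec = spec), generate_phantom(spec))
  })
  names(configs) <- sprintf("%s_%skv_%03dpct_%s", material, grid$kv,
                            grid$dose_pct,
                            ifelse(grid$fat_ring, "ring", "noring"))
  structure(configs, class = "phantom_study")
}

#' ROI measurement table of a whole study
#'
#' Runs \code{\link{extract_measurements}} on every configuration of a
#' generated study, placing one ROI at each rod center.
#'
#' @param study A \code{\link{generate_study}} result.
#' @param area_cm2 ROI area (cm2); the default 2 cm2 circle (radius 7.98
#'   mm) fits inside the 20 mm rods.
#' @return ROI measurement table across all configurations.
#' @export
study_roi_table <- function(study, area_cm2 = 2) {
  stopifnot(inherits(study, "phantom_study"))
  do.call(rbind, lapply(study, function(cfg) {
    extract_measurements(cfg$pair, cfg$manifest$rods, area_cm2 = area_cm2)
  }))
}

#' Write a generated study to disk
#'
#' Materializes each configuration as a raw-format image pair plus a study
#' manifest (\code{study.yaml}) holding geometry, rod layout and ground
#' truth, so the study can be re-loaded with \code{\link{load_image_pair}}
#' and calibrated from files.
#'
#' @param study A \code{\link{generate_study}} result.
#' @param dir Output directory.
#' @return Path of the study manifest (invisibly).
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "phantom_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(names(study), function(nm) {
    cfg <- study[[nm]]
    paths <- write_image_pair(cfg$pair, dir, prefix = nm)
    man <- cfg$manifest
    list(name = nm,
         low_image = basename(paths[["low"]]),
         high_image = basename(paths[["high"]]),
         material = man$material, kv = man$kv, dose_pct = man$dose_pct,
         fat_ring = man$fat_ring,
         truth = list(true_der = man$true_der,
                      hu_per_conc_low = man$hu_per_conc_low,
                      le_base = man$le_base, he_base = man$he_base,
                      delta_base = man$delta_base),
         noise_sd = as.numeric(man$noise_sd), seed = man$seed,
         rods = lapply(seq_len(nrow(man$rods)), function(i)
           as.list(man$rods[i, c("center_x_mm", "center_y_mm",
                                 "concentration_mg_ml")])))
  })
  path <- file.path(dir, "study.yaml")
  yaml::write_yaml(list(configurations = entries), path)
  invisible(path)
}

#' Load a written study's ROI measurement table
#'
#' Reads \code{study.yaml}, loads every image pair and extracts the rod
#' ROI measurements.
#'
#' @param dir Study directory written by \code{\link{write_study}}.
#' @param area_cm2 ROI area in cm2.
#' @return ROI measurement table.
#' @export
read_study_measurements <- function(dir, area_cm2 = 2) {
  path <- file.path(dir, "study.yaml")
  if (!file.exists(path)) stop("no study.yaml in ", dir, call. = FALSE)
  study <- yaml::read_yaml(path)
  do.call(rbind, lapply(study$configurations, function(e) {
    pair <- load_image_pair(file.path(dir, e$low_image),
                            file.path(dir, e$high_image))
    rods <- do.call(rbind, lapply(e$rods, as.data.frame))
    extract_measurements(pair, rods, area_cm2 = area_cm2)
  }))
}

#' Simulate a ROI measurement table directly (no images)
#'
#' Measurement-level counterpart of \code{\link{generate_phantom}}: draws
#' rod-mean HU values from the linear spectral ground truth plus Gaussian
#' noise on the ROI means themselves. Useful for fast Monte-Carlo studies
#' of the calibration fits.
#'
#' @param spec A \code{\link{phantom_spec}} (its geometry fields are
#'   ignored; only the spectral truth, concentrations and metadata are
#'   used).
#' @param noise_sd SD of the Gaussian noise added to each rod-mean HU
#'   (both channels, HU). Note this is noise on the ROI mean, not on
#'   pixels.
#' @param seed Optional seed (NULL: current RNG state).
#' @return ROI measurement table for the configuration.
#' @export
simulate_roi_table <- function(spec, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), noise_sd >= 0)
  conc <- spec$concentrations
  truth <- .rod_truth(spec, conc)
  n <- length(conc)
  .with_seed(seed, {
    validate_roi_table(data.frame(
      material = spec$material, kv = spec$kv, dose_pct = spec$dose_pct,
      fat_ring = spec$fat_ring, concentration_mg_ml = conc,
      le_hu = truth$le + if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0,
      he_hu = truth$he + if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0,
      stringsAsFactors = FALSE))
  })
}
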