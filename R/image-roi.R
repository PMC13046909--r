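#' Paired low/high-energy image container
#'
#' Holds co-registered low- and high-energy HU arrays (2-D slice or 3-D
#' volume) with isotropic in-plane pixel spacing and the acquisition
#' metadata of the scan configuration. Image coordinates are in mm with the
#' origin at the center of the first pixel: \code{x} runs along columns,
#' \code{y} along rows.
#'
#' @param low,high Numeric arrays of HU values with identical dimensions.
#' @param pixel_spacing In-plane pixel spacing in mm (> 0).
#' @param metadata Named list of configuration labels; \code{material},
#'   \code{kv}, \code{dose_pct} and \code{fat_ring} are used when building
#'   ROI measurement tables.
#' @return Object of class \code{"spectral_image_pair"}.
#' @export
spectral_image_pair <- function(low, high, pixel_spacing, metadata = list()) {
  if (!identical(dim(low), dim(high))) {
    stop("low- and high-energy images have different shapes", call. = FALSE)
  }
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1 ||
      !is.finite(pixel_spacing) || pixel_spacing <= 0) {
    stop("pixel_spacing must be a single positive number (mm)", call. = FALSE)
  }
  nd <- length(dim(low))
  if (nd < 2 || nd > 3) stop("images must be 2-D or 3-D arrays", call. = FALSE)
  structure(list(low = low, high = high, pixel_spacing = pixel_spacing,
                 metadata = metadata),
            class = "spectral_image_pair")
}

#' @export
print.spectral_image_pair <- function(x, ...) {
  cat("Spectral image pair:", paste(dim(x$low), collapse = " x "),
      sprintf("voxels, %.3g mm pixels\n", x$pixel_spacing))
  md <- x$metadata
  if (length(md) > 0) {
    cat("  metadata:", paste(names(md), unlist(md), sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

.n_slices <- function(pair) {
  d <- dim(pair$low)
  if (length(d) == 3) d[3] else 1L
}

#' Circular ROI specification
#'
#' @param center ROI center \code{c(x, y)} in mm (image coordinates, origin
#'   at the first-pixel center).
#' @param area_cm2 ROI area in cm2; the ROI is the circle of radius
#'   \code{sqrt(area / pi)} (4 cm2 gives radius 11.28 mm).
#' @param slices Slice index or index range for 3-D volumes; \code{NULL}
#'   selects the single central slice.
#' @return Object of class \code{"roi_spec"}.
#' @export
roi_spec <- function(center, area_cm2 = 4, slices = NULL) {
  stopifnot(length(center) == 2, all(is.finite(center)),
            is.numeric(area_cm2), area_cm2 > 0)
  structure(list(center = as.numeric(center), area_cm2 = area_cm2,
                 radius_mm = sqrt(area_cm2 * 100 / pi), slices = slices),
            class = "roi_spec")
}

# Logical pixel-center-in-circle mask for one slice. Deterministic and
# shared across both energy channels.
.roi_mask <- function(dims, spacing, center, radius) {
  x <- (seq_len(dims[2]) - 1) * spacing
  y <- (seq_len(dims[1]) - 1) * spacing
  outer(y, x, function(yy, xx) (xx - center[1])^2 + (yy - center[2])^2 <= radius^2)
}

#' Mean HU inside a circular ROI
#'
#' Averages the pixels whose centers lie inside the ROI circle; the same
#' pixel set is used for both energy channels. On a 3-D volume the mean is
#' computed per slice and averaged with equal weights over the requested
#' slice range (default: the central slice only).
#'
#' @param pair A \code{\link{spectral_image_pair}}.
#' @param roi A \code{\link{roi_spec}}.
#' @return List with \code{le_mean}, \code{he_mean} (HU) and
#'   \code{n_pixels} (per slice).
#' @export
roi_mean <- function(pair, roi) {
  stopifnot(inherits(pair, "spectral_image_pair"), inherits(roi, "roi_spec"))
  d <- dim(pair$low)
  spacing <- pair$pixel_spacing
  extent <- (d[c(2, 1)] - 1) * spacing  # (x, y) extents in mm
  if (any(roi$center - roi$radius_mm < 0) ||
      any(roi$center + roi$radius_mm > extent)) {
    stop(sprintf("ROI (center %.1f,%.1f mm, radius %.1f mm) exceeds image bounds",
                 roi$center[1], roi$center[2], roi$radius_mm), call. = FALSE)
  }
  mask <- .roi_mask(d[1:2], spacing, roi$center, roi$radius_mm)
  n <- sum(mask)
  if (n == 0) stop("ROI selects zero pixels", call. = FALSE)

  n_sl <- .n_slices(pair)
  slices <- roi$slices
  if (is.null(slices)) slices <- as.integer(ceiling(n_sl / 2))
  if (any(slices < 1) || any(slices > n_sl)) {
    stop("slice index out of range", call. = FALSE)
  }
  slice_mean <- function(img, k) {
    sl <- if (length(dim(img)) == 3) img[, , k] else img
    mean(sl[mask])
  }
  list(le_mean = mean(vapply(slices, function(k) slice_mean(pair$low, k), 0)),
       he_mean = mean(vapply(slices, function(k) slice_mean(pair$high, k), 0)),
       n_pixels = n)
}

#' Extract a ROI measurement table from an image pair
#'
#' Measures the mean low-/high-energy HU in one ROI per rod and assembles
#' the ROI measurement table consumed by the calibration fits; the
#' configuration metadata is copied from the image pair.
#'
#' @param pair A \code{\link{spectral_image_pair}} whose metadata carries
#'   \code{material}, \code{kv}, \code{dose_pct} and \code{fat_ring}.
#' @param rois data.frame with columns \code{center_x_mm},
#'   \code{center_y_mm}, \code{concentration_mg_ml} (one row per rod).
#' @param area_cm2 ROI area (cm2) used for every rod.
#' @param slices Slice selection passed to \code{\link{roi_mean}}.
#' @return ROI measurement table (see \code{\link{validate_roi_table}}).
#' @export
extract_measurements <- function(pair, rois, area_cm2 = 2, slices = NULL) {
  stopifnot(inherits(pair, "spectral_image_pair"), is.data.frame(rois))
  md <- pair$metadata
  need <- c("material", "kv", "dose_pct", "fat_ring")
  if (!all(need %in% names(md))) {
    stop("image pair metadata must include material, kv, dose_pct, fat_ring",
         call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(rois)), function(i) {
    m <- roi_mean(pair, roi_spec(c(rois$center_x_mm[i], rois$center_y_mm[i]),
                                 area_cm2 = area_cm2, slices = slices))
    data.frame(material = md$material, kv = as.character(md$kv),
               dose_pct = md$dose_pct, fat_ring = md$fat_ring,
               concentration_mg_ml = rois$concentration_mg_ml[i],
               le_hu = m$le_mean, he_hu = m$he_mean,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    return(data.frame(material = character(), kv = character(),
                      dose_pct = numeric(), fat_ring = logical(),
                      concentration_mg_ml = numeric(), le_hu = numeric(),
                      he_hu = numeric(), stringsAsFactors = FALSE))
  }
  validate_roi_table(do.call(rbind, rows))
}

.is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path)

.sidecar_path <- function(path) paste0(sub("\\.(raw|bin)$", "", path), ".json")

.read_raw_channel <- function(path) {
  sidecar <- .sidecar_path(path)
  if (!file.exists(sidecar)) {
    stop("missing JSON sidecar for raw image: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("shape", "pixel_spacing_mm")) {
    if (is.null(meta[[field]])) {
      stop("raw-image sidecar lacks required field '", field, "': ", sidecar,
           call. = FALSE)
    }
  }
  shape <- as.integer(meta$shape)
  values <- readBin(path, what = "double", n = prod(shape), size = 8,
                    endian = "little")
  if (length(values) != prod(shape)) {
    stop("raw image size does not match sidecar shape: ", path, call. = FALSE)
  }
  list(data = array(values, dim = shape),
       spacing = as.numeric(meta$pixel_spacing_mm),
       metadata = if (is.null(meta$metadata)) list() else as.list(meta$metadata))
}

.read_nifti_channel <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (length(pd) >= 2 && abs(pd[1] - pd[2]) > 1e-6) {
    stop("anisotropic in-plane spacing not supported: ", path, call. = FALSE)
  }
  list(data = array(as.numeric(img), dim = dim(img)),
       spacing = as.numeric(pd[1]), metadata = list())
}

#' Load a low/high-energy image pair from disk
#'
#' Supports NIfTI (\code{.nii} / \code{.nii.gz}, HU already applied) and the
#' package's raw fixture format: a little-endian float64 array
#' (column-major) with a JSON sidecar of the same basename carrying
#' \code{shape}, \code{pixel_spacing_mm} and optional \code{metadata}
#' labels. Both channels must share geometry.
#'
#' @param low_path,high_path Paths to the two energy-channel images.
#' @param metadata Extra metadata entries; override anything read from the
#'   sidecars.
#' @return A \code{\link{spectral_image_pair}}.
#' @export
load_image_pair <- function(low_path, high_path, metadata = list()) {
  for (p in c(low_path, high_path)) {
    if (!file.exists(p)) stop("image file not found: ", p, call. = FALSE)
  }
  read1 <- function(p) {
    if (.is_nifti_path(p)) .read_nifti_channel(p) else .read_raw_channel(p)
  }
  lo <- read1(low_path)
  hi <- read1(high_path)
  if (!identical(dim(lo$data), dim(hi$data))) {
    stop("geometry mismatch: channel shapes differ", call. = FALSE)
  }
  if (abs(lo$spacing - hi$spacing) > 1e-9) {
    stop("geometry mismatch: channel pixel spacings differ", call. = FALSE)
  }
  md <- utils::modifyList(lo$metadata, metadata)
  spectral_image_pair(lo$data, hi$data, lo$spacing, md)
}

#' Write an image pair in the raw fixture format
#'
#' Writes \code{<prefix>_low.raw} / \code{<prefix>_high.raw} (little-endian
#' float64, column-major) plus JSON sidecars; \code{\link{load_image_pair}}
#' round-trips them bit-exactly.
#'
#' @param pair A \code{\link{spectral_image_pair}}.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the two \code{.raw} paths (invisibly).
#' @export
write_image_pair <- function(pair, dir, prefix = "image") {
  stopifnot(inherits(pair, "spectral_image_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write1 <- function(data, channel) {
    raw_path <- file.path(dir, sprintf("%s_%s.raw", prefix, channel))
    writeBin(as.numeric(data), raw_path, size = 8, endian = "little")
    jsonlite::write_json(
      list(shape = dim(data), pixel_spacing_mm = pair$pixel_spacing,
           channel = channel, metadata = pair$metadata),
      .sidecar_path(raw_path), auto_unbox = TRUE, digits = NA)
    raw_path
  }
  invisible(c(low = write1(pair$low, "low"), high = write1(pair$high, "high")))
}
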