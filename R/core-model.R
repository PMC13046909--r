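#' pcdquant: phantom-based calibration for PCD-CT material decomposition
#'
#' Two-material decomposition in image space projects each voxel's paired
#' low/high-energy CT numbers onto the material line of slope DER (the
#' dual-energy ratio) along a line parallel to the water line, producing a
#' concentration map (CM) in HU. Residual scanner-calibration tolerances
#' leave a mismatch `delta_base` between the high- and low-energy CT numbers
#' of the base material (water- or liver-equivalent), and the DER itself
#' varies with protocol; both propagate into concentration errors. This
#' package estimates `delta_base`, DER and the concentration scaling factor
#' `alpha` from phantom ROI measurements, averages them per tube voltage
#' ("mean method"), and applies the corrected conversion to concentration
#' in mg/mL.
#'
#' @keywords internal
"_PACKAGE"

# Guard against a degenerate material line: all formulas divide by der - 1.
.check_der <- function(der) {
  if (!is.numeric(der) || any(!is.finite(der))) {
    stop("`der` must be finite numeric", call. = FALSE)
  }
  if (any(abs(der - 1) < 1e-6) || any(der <= 1)) {
    stop("`der` must exceed 1: the material line must be steeper than the ",
         "water line (division by der - 1)", call. = FALSE)
  }
  invisible(der)
}

.check_w <- function(w) {
  if (!is.numeric(w) || any(!is.finite(w)) || any(w < 0) || any(w > 1)) {
    stop("`w` must lie in [0, 1]", call. = FALSE)
  }
  invisible(w)
}

.check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("`alpha` must be > 0 (HU per mg/mL)", call. = FALSE)
  }
  invisible(alpha)
}

#' Decomposition parameters for a single configuration
#'
#' Bundles the four quantities that define the corrected two-material
#' decomposition: the dual-energy ratio \code{der} (> 1), the vendor
#' weighting factor \code{w} in [0, 1] blending the low- and high-energy
#' contrast-material components, the base-material CT-number mismatch
#' \code{delta_base} (HU, defined as HE_base - LE_base), and the
#' concentration scaling factor \code{alpha} (HU per mg/mL).
#'
#' @param der Dual-energy ratio (dimensionless, > 1).
#' @param w Weighting factor in [0, 1]. The default 0.5 is safe because the
#'   end-to-end concentration is invariant to \code{w} whenever \code{alpha}
#'   is fitted with the same \code{w} (the factor \code{der*w + 1 - w} is a
#'   pure scale absorbed by \code{alpha}).
#' @param delta_base Base-material mismatch HE_base - LE_base (HU).
#' @param alpha Concentration scaling factor (HU per mg/mL, > 0).
#' @return An object of class \code{"decomposition_params"}.
#' @examples
#' decomposition_params(der = 2.10, w = 0.5, delta_base = -5.56, alpha = 26.29)
#' @export
decomposition_params <- function(der, w = 0.5, delta_base = 0, alpha = 1) {
  .check_der(der); .check_w(w); .check_alpha(alpha)
  stopifnot(is.finite(delta_base))
  structure(list(der = der, w = w, delta_base = delta_base, alpha = alpha),
            class = "decomposition_params")
}

#' @export
print.decomposition_params <- function(x, ...) {
  cat("Two-material decomposition parameters\n")
  cat(sprintf("  DER        = %.4f\n", x$der))
  cat(sprintf("  w          = %.3f\n", x$w))
  cat(sprintf("  delta_base = %.3f HU\n", x$delta_base))
  cat(sprintf("  alpha      = %.4f HU per mg/mL\n", x$alpha))
  invisible(x)
}

#' Project a voxel onto the material line
#'
#' A measured voxel (HE, LE) containing a mixture of base material and
#' contrast material is projected onto the material line
#' (LE = DER * HE) along a line parallel to the water line (slope 1). The
#' intersection (HE_CM, LE_CM) is the contrast-material component of the
#' voxel:
#' \deqn{HE_{CM} = (LE - HE)/(DER - 1), \quad LE_{CM} = DER \cdot HE_{CM}.}
#'
#' @param le,he Low- and high-energy CT numbers (HU). Vectorized.
#' @param der Dual-energy ratio (> 1).
#' @return A list with components \code{le_cm} and \code{he_cm} (HU); the
#'   displacement from the input point is parallel to the water line
#'   (\code{le - le_cm == he - he_cm}).
#' @examples
#' project_to_material_line(le = 100, he = 40, der = 2) # le_cm 120, he_cm 60
#' @export
project_to_material_line <- function(le, he, der) {
  .check_der(der)
  stopifnot(is.finite(le), is.finite(he))
  he_cm <- (le - he) / (der - 1)
  list(le_cm = der * he_cm, he_cm = he_cm)
}

#' Uncorrected concentration-map value of a voxel
#'
#' The concentration-map (CM) value is the weighted sum of the two
#' contrast-material components,
#' \deqn{CM_{measured} = w \cdot LE_{CM} + (1 - w) \cdot HE_{CM}
#'       = (DER \cdot w + 1 - w) \cdot (LE - HE)/(DER - 1),}
#' in HU at a 70 keV virtual-monoenergetic-image equivalent. A pure
#' base-material voxel with matched channels (LE = HE) maps to 0 for any
#' \code{der} and \code{w}.
#'
#' @inheritParams project_to_material_line
#' @param w Weighting factor in [0, 1].
#' @return CM value(s) in HU.
#' @examples
#' cm_measured(le = 100, he = 40, der = 2, w = 0.5) # 90
#' @export
cm_measured <- function(le, he, der, w = 0.5) {
  .check_der(der); .check_w(w)
  (der * w + 1 - w) * (le - he) / (der - 1)
}

#' Corrected concentration-map value of a voxel
#'
#' Adds the base-material mismatch \code{delta_base = HE_base - LE_base}
#' inside the channel difference, so that a pure base-material voxel
#' (le = LE_base, he = HE_base) maps exactly to 0:
#' \deqn{CM_{corrected} = (DER \cdot w + 1 - w) \cdot
#'       (LE - HE + \Delta_{base})/(DER - 1).}
#' Equivalently \code{cm_corrected = cm_measured +
#' (der*w + 1 - w) * delta_base / (der - 1)}.
#'
#' @inheritParams cm_measured
#' @param delta_base Base-material mismatch (HU).
#' @return Corrected CM value(s) in HU.
#' @examples
#' cm_corrected(le = 100, he = 40, der = 2, w = 0.5, delta_base = -4) # 84
#' @export
cm_corrected <- function(le, he, der, w = 0.5, delta_base = 0) {
  .check_der(der); .check_w(w)
  stopifnot(is.finite(delta_base))
  (der * w + 1 - w) * (le - he + delta_base) / (der - 1)
}

#' Convert a concentration-map value to concentration
#'
#' \deqn{C = CM / \alpha} with \code{alpha} in HU per mg/mL. Sign is
#' preserved: negative CM values yield negative concentrations (no
#' clipping; callers that display concentration maps may clip).
#'
#' @param cm Concentration-map value(s) in HU.
#' @param alpha Concentration scaling factor (HU per mg/mL, > 0).
#' @return Concentration(s) in mg/mL.
#' @export
concentration_from_cm <- function(cm, alpha) {
  .check_alpha(alpha)
  cm / alpha
}

#' Mean-method concentration from an uncorrected CM value
#'
#' Applies the mean-method correction in one step: given a CM value produced
#' by a standard decomposition with \code{der_avg} (and weighting \code{w}),
#' \deqn{C = \frac{1}{\alpha_{avg}} \left( CM_{measured} +
#'   (DER_{avg} w + 1 - w) \frac{\Delta_{base,avg}}{DER_{avg} - 1} \right).}
#' Algebraically identical to \code{concentration_from_cm(cm_corrected(...))}
#' when the CM value came from \code{\link{cm_measured}} with the same
#' \code{der} and \code{w}.
#'
#' @param cm Uncorrected CM value(s) in HU.
#' @param params A \code{\link{mean_method_params}} object (or any list with
#'   fields \code{der_avg}, \code{w}, \code{delta_base_avg},
#'   \code{alpha_avg}).
#' @return Concentration(s) in mg/mL.
#' @export
mean_method_concentration <- function(cm, params) {
  der <- params$der_avg
  w <- params$w
  .check_der(der); .check_w(w); .check_alpha(params$alpha_avg)
  offset <- (der * w + 1 - w) * params$delta_base_avg / (der - 1)
  (cm + offset) / params$alpha_avg
}

#' Signed relative error of a concentration estimate
#'
#' \deqn{Error = (C_{measured} - C_{true})/C_{true} \cdot 100\%.}
#' Undefined for a true concentration of 0; such inputs raise an error
#' rather than returning Inf/NaN.
#'
#' @param c_measured Estimated concentration(s), mg/mL.
#' @param c_true True concentration(s), mg/mL; must be nonzero.
#' @return Signed percentage error(s).
#' @examples
#' relative_error(2.3, 2.0) # +15
#' @export
relative_error <- function(c_measured, c_true) {
  if (any(c_true == 0)) {
    stop("relative error is undefined for a true concentration of 0",
         call. = FALSE)
  }
  (c_measured - c_true) / c_true * 100
}
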