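#' Write / read calibration records
#'
#' Round-trippable structured text (YAML): one entry per configuration
#' with the fitted parameters, the weighting factor used, and the fit
#' diagnostics.
#'
#' @param records List of calibration records (or one record).
#' @param path Output file.
#' @return \code{read_calibration_records} returns the list of records.
#' @export
write_calibration_records <- function(records, path) {
  if (inherits(records, "calibration_record")) records <- list(records)
  entries <- lapply(records, function(r) unclass(r))
  yaml::write_yaml(list(calibration_records = entries), path,
                   precision = 15)
  invisible(path)
}

#' @rdname write_calibration_records
#' @export
read_calibration_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$calibration_records)) {
    stop("not a calibration-record file: ", path, call. = FALSE)
  }
  lapply(raw$calibration_records, function(e) {
    e$kv <- as.character(e$kv)
    structure(e, class = "calibration_record")
  })
}

#' Write / read mean-method parameter sets
#'
#' Round-trippable structured text (YAML) for one or more
#' \code{\link{mean_method_params}} groups.
#'
#' @param params A \code{mean_method_params} object or list of them.
#' @param path Output file.
#' @return \code{read_mean_method_params} returns a named list of
#'   \code{mean_method_params}.
#' @export
write_mean_method_params <- function(params, path) {
  if (inherits(params, "mean_method_params")) params <- list(params)
  yaml::write_yaml(list(mean_method = lapply(params, unclass)), path,
                   precision = 15)
  invisible(path)
}

#' @rdname write_mean_method_params
#' @export
read_mean_method_params <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$mean_method)) {
    stop("not a mean-method parameter file: ", path, call. = FALSE)
  }
  out <- lapply(raw$mean_method, function(e) {
    mean_method_params(delta_base_avg = e$delta_base_avg,
                       der_avg = e$der_avg, alpha_avg = e$alpha_avg,
                       delta_base_sd = e$delta_base_sd, der_sd = e$der_sd,
                       alpha_sd = e$alpha_sd, n_configs = e$n_configs,
                       w = e$w, material = e$material,
                       kv = as.character(e$kv))
  })
  names(out) <- vapply(out, function(p) paste(p$material, p$kv, sep = "_"),
                       character(1))
  out
}
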