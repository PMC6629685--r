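#' End-to-end blind restoration
#'
#' One-call pipelines that chain resolution measurement, PSF estimation
#' and restoration:
#' \describe{
#'   \item{`"frc_denoise"`}{single-image FRC cutoff + frequency-domain
#'     low-pass filter (ideal by default).}
#'   \item{`"blind_wiener"`}{FRC (2D) or SFSC (3D, anisotropic) Gaussian
#'     PSF + Wiener inverse filter.}
#'   \item{`"blind_rl"`}{FRC/SFSC Gaussian PSF + Richardson-Lucy with
#'     FRC-driven stopping.}
#' }
#' 3D volumes are resampled to isotropic spacing first; their cutoff /
#' PSF uses the lateral and axial SFSC resolutions (elliptical cutoff
#' surface, anisotropic PSF).  Input and output resolutions in the report
#' are measured with the same FRC mode (single-image, uncalibrated unless
#' a calibration is supplied).
#'
#' @param image An [frc_image].
#' @param method `"frc_denoise"`, `"blind_wiener"` or `"blind_rl"`.
#' @param filter Low-pass family for `"frc_denoise"` (default
#'   `"ideal"`).
#' @param filter_order Butterworth order.
#' @param snr_reg Wiener regularization SNR; defaults to 0.1 in 2D and
#'   0.005 in 3D.
#' @param options [rl_options()] for `"blind_rl"`.
#' @param calibration Optional [frc_calibration] used for all
#'   single-image FRC measurements of the pipeline.
#' @return A list of class `restore_result`: `image` (restored) and
#'   `report` (a `restore_report` list: method, input/output `d_min_nm`,
#'   PSF FWHM, parameters, and for RL the stop reason and iteration
#'   count).
#' @export
restore <- function(image, method = c("frc_denoise", "blind_wiener",
                                      "blind_rl"),
                    filter = c("ideal", "butterworth", "gaussian"),
                    filter_order = 3, snr_reg = NULL,
                    options = rl_options(), calibration = NULL) {
  method <- match.arg(method)
  filter <- match.arg(filter)
  stopifnot(is_frc_image(image))
  rank <- length(dim(image))
  if (rank == 3L) image <- resample_isotropic(image)
  if (is.null(snr_reg)) snr_reg <- if (rank == 2L) 0.1 else 0.005
  meas <- blind_measure(image, calibration)
  report <- list(method = method, d_min_in_nm = meas$d_min,
                 frc_mode = meas$mode, psf_fwhm_nm = NULL, params = list())
  out <- switch(
    method,
    frc_denoise = {
      r_th <- unname(1 / meas$fwhm)
      if (length(unique(r_th)) == 1L) r_th <- r_th[1]
      report$params <- list(filter = filter, order = filter_order,
                            cutoff_nm_inv = unname(r_th))
      tf <- lowpass_transfer(filter, r_th = r_th, image = image,
                             n = filter_order)
      filter_image(image, tf)
    },
    blind_wiener = {
      psf <- make_gaussian_psf(meas$fwhm, image$spacing)
      report$psf_fwhm_nm <- unname(meas$fwhm)
      report$params <- list(snr_reg = snr_reg)
      wiener_deconvolve(image, psf, snr_reg = snr_reg)
    },
    blind_rl = {
      options$calibration <- calibration
      psf <- make_gaussian_psf(meas$fwhm, image$spacing)
      report$psf_fwhm_nm <- unname(meas$fwhm)
      rl <- rl_deconvolve(image, psf, options)
      report$params <- list(
        iterations = max(rl$trace$k),
        stop_reason = attr(rl$trace, "stop_reason"),
        stop_grad_threshold = options$stop_grad_threshold,
        tv_lambda = options$tv_lambda,
        adjustive = options$adjustive,
        background = rl$background)
      report$trace <- as.data.frame(rl$trace)
      rl$image
    })
  report$d_min_out_nm <- blind_measure(out, calibration)$d_min
  structure(list(image = out,
                 report = structure(report, class = "restore_report")),
            class = "restore_result")
}

# Blind resolution measurement used by the pipelines: single-image FRC
# in 2D, sectioned FSC of the split volume in 3D.  Returns the scalar
# d_min reported, the per-axis FWHM for PSF construction, and the mode.
blind_measure <- function(image, calibration = NULL) {
  if (length(dim(image)) == 2L) {
    res <- one_image_frc(image, calibration = calibration)$resolution
    list(d_min = res$d_min_nm, fwhm = rep(res$d_min_nm, 2),
         mode = if (isTRUE(res$calibrated)) "one_image_calibrated" else
           "one_image_raw")
  } else {
    halves <- volume_split(image)
    sf <- sfsc(halves[[1]], halves[[2]])
    dla <- sfsc_lateral_axial(sf)
    list(d_min = unname(dla["lateral"]),
         fwhm = unname(c(dla["axial"], dla["lateral"], dla["lateral"])),
         mode = "sfsc_single_volume")
  }
}

#' @export
print.restore_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("<restore_result> %s: d_min %.1f -> %.1f nm (%s FRC)\n",
              r$method, r$d_min_in_nm, r$d_min_out_nm, r$frc_mode))
  invisible(x)
}

#' Serialize / deserialize a restoration report
#'
#' Reports are plain lists of scalars, vectors and (for RL) a trace data
#' frame, so they round-trip losslessly through JSON.
#'
#' @param report A `restore_report` (from [restore()]).
#' @param path Optional file to write to / read from.
#' @return `report_to_json()`: a JSON string (invisibly, if written to
#'   `path`); `report_from_json()`: the report list.
#' @export
report_to_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @param json A JSON string (ignored when `path` is given).
#' @rdname report_to_json
#' @export
report_from_json <- function(json, path = NULL) {
  if (!is.null(path)) json <- paste(readLines(path), collapse = "\n")
  out <- jsonlite::fromJSON(json)
  if (!is.null(out$trace)) out$trace <- as.data.frame(out$trace)
  structure(out, class = "restore_report")
}
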