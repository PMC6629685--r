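#' Calibrate single-image FRC against the two-image reference
#'
#' The raw single-image FRC resolution is systematically displaced from
#' the two-image ("gold standard") value: the checkerboard sub-images are
#' sampled at twice the pixel pitch while the raw curve is plotted against
#' the original pitch, and the diagonal sub-pixel offset between the
#' sub-images of a pair modulates the spectrum.  Both effects are
#' monotone in resolution at a fixed threshold, so they can be absorbed by
#' a single monotone univariate correction fitted against paired
#' measurements of the same scenes.  The default model is a least-squares
#' quadratic constrained to be monotone increasing over the fitted range;
#' if the quadratic fit is non-monotone there, a linear fit is used
#' instead.  The model is tagged with the threshold it was fitted for
#' (only the fixed 1/7 criterion is supported) and must not be reused for
#' other criteria.
#'
#' @param raw Raw single-image resolutions (nm), or a data frame / matrix
#'   whose first two columns are raw and reference.
#' @param reference Matching two-image reference resolutions (nm).
#' @param degree Polynomial degree of the correction (default 2).
#' @return An object of class `frc_calibration` with `coefficients`
#'   (intercept first), `degree`, `range` (raw values spanned) and
#'   `threshold`.
#' @seealso [default_calibration()] for a model fitted on a synthetic
#'   calibration series, [one_image_frc()] for applying it.
#' @export
fit_calibration <- function(raw, reference = NULL, degree = 2) {
  if (is.null(reference)) {
    raw <- as.data.frame(raw)
    reference <- raw[[2]]
    raw <- raw[[1]]
  }
  if (length(raw) != length(reference)) {
    stop("`raw` and `reference` must have equal length")
  }
  if (length(raw) < 4L) {
    stop("calibration needs at least 4 (raw, reference) pairs")
  }
  fit_poly <- function(deg) {
    stats::lm(reference ~ stats::poly(raw, deg, raw = TRUE))
  }
  monotone <- function(co, rng) {
    x <- seq(rng[1], rng[2], length.out = 201)
    deriv <- rep(0, length(x))
    for (p in seq_along(co)[-1]) {
      deriv <- deriv + (p - 1) * co[p] * x^(p - 2)
    }
    all(deriv > 0)
  }
  rng <- range(raw)
  co <- unname(stats::coef(fit_poly(degree)))
  if (degree > 1 && !monotone(co, rng)) {
    degree <- 1
    co <- unname(stats::coef(fit_poly(1)))
  }
  if (!monotone(co, rng)) {
    stop("calibration data do not support a monotone increasing correction")
  }
  structure(list(coefficients = co, degree = degree, range = rng,
                 threshold = "fixed_1_7"),
            class = "frc_calibration")
}

#' @param object An `frc_calibration`.
#' @param newdata Raw single-image resolution values (nm).
#' @param ... Unused.
#' @rdname fit_calibration
#' @export
predict.frc_calibration <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  out <- rep(object$coefficients[1], length(x))
  for (p in seq_along(object$coefficients)[-1]) {
    out <- out + object$coefficients[p] * x^(p - 1)
  }
  if (any(x < object$range[1] - 1e-9) || any(x > object$range[2] + 1e-9)) {
    warning("raw resolution outside the calibrated range [",
            signif(object$range[1], 4), ", ", signif(object$range[2], 4),
            "] nm; extrapolating")
  }
  out
}

#' @export
print.frc_calibration <- function(x, ...) {
  cat(sprintf(
    "<frc_calibration> degree-%d monotone fit over raw %.0f-%.0f nm (1/7 threshold)\n",
    x$degree, x$range[1], x$range[2]))
  cat("  coefficients:", paste(signif(x$coefficients, 6), collapse = ", "),
      "\n")
  invisible(x)
}

#' Default calibration from a synthetic acquisition series
#'
#' Reproduces the calibration procedure on synthetic data: a filament
#' phantom is imaged at a series of pixel sizes spanning 29-113 nm while
#' the optical resolution (PSF FWHM) is held fixed, emulating a microscope
#' re-sampling the same scene at different zoom settings.  For every pixel
#' size a two-image FRC reference is measured from two independent noise
#' realizations and a raw single-image FRC from one realization; the
#' resulting pairs are fed to [fit_calibration()].
#'
#' @param seed Random seed for the synthetic series.
#' @param pixel_sizes Pixel sizes of the series (nm).
#' @param fwhm_nm Fixed PSF FWHM of the simulated optics (nm).
#' @param shape Image size in pixels.
#' @param peak_photons Peak photon count of the simulation.
#' @param reps Independent scene replicates per pixel size.
#' @return An [fit_calibration()] model.
#' @export
default_calibration <- function(seed = 1, pixel_sizes = c(29, 46, 63, 80,
                                                          97, 113),
                                fwhm_nm = 250, shape = c(256, 256),
                                peak_photons = 200, reps = 2) {
  raw <- ref <- numeric(0)
  for (px in pixel_sizes) {
    for (r in seq_len(reps)) {
      spec <- acquisition_spec(kind = "filaments", shape = shape,
                               pixel_size_nm = px, fwhm_nm = fwhm_nm,
                               peak_photons = peak_photons,
                               n_realizations = 2,
                               seed = seed + 997L * r + round(px))
      ph <- make_phantom(spec)
      ims <- simulate_acquisition(ph, spec)
      two <- two_image_frc(ims[[1]], ims[[2]])$resolution
      one <- one_image_frc(ims[[1]])$resolution
      if (!two$no_crossing && !one$no_crossing) {
        raw <- c(raw, one$d_min_nm)
        ref <- c(ref, two$d_min_nm)
      }
    }
  }
  fit_calibration(raw, ref)
}
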