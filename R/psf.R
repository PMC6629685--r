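#' Convert between resolution (FWHM) and Gaussian sigma
#'
#' The effective PSF of the microscope is approximated as a Gaussian whose
#' full width at half maximum equals the measured FRC resolution:
#' \eqn{FWHM = 2\sqrt{2\ln 2}\,\sigma \approx 2.3548\,\sigma}.
#'
#' @param d_min Resolution / FWHM in nm, > 0.
#' @return `resolution_to_sigma()`: the Gaussian sigma in nm.
#' @export
resolution_to_sigma <- function(d_min) {
  if (!is.numeric(d_min) || any(d_min <= 0)) {
    stop("`d_min` must be positive")
  }
  d_min / (2 * sqrt(2 * log(2)))
}

#' @param sigma Gaussian sigma in nm, > 0.
#' @return `sigma_to_fwhm()`: the FWHM in nm.
#' @rdname resolution_to_sigma
#' @export
sigma_to_fwhm <- function(sigma) {
  if (!is.numeric(sigma) || any(sigma <= 0)) {
    stop("`sigma` must be positive")
  }
  sigma * 2 * sqrt(2 * log(2))
}

#' Render a normalized Gaussian PSF kernel
#'
#' Builds a separable Gaussian kernel from per-axis FWHM values (nm),
#' sampled at voxel centres on the image grid.  Kernel sizes are forced
#' odd so the kernel is centred on a voxel (a half-pixel off-centre kernel
#' would shift every deconvolution result); the automatic support covers
#' +/- 4 sigma per axis, > 99.99% of the Gaussian mass.  The kernel is
#' normalized to unit sum.
#'
#' @param fwhm_nm FWHM per axis in nm (scalar recycled; 3D order z, y, x).
#' @param spacing_nm Voxel spacing per axis in nm (scalar recycled).
#' @param rank Kernel dimensionality if both arguments are scalar
#'   (default 2).
#' @param shape Kernel size per axis (odd integers), or `"auto"`.
#' @return An object of class `psf_model`: `fwhm_nm`, `sigma_nm`,
#'   `kernel` (unit-sum array), `spacing_nm`.
#' @examples
#' psf <- make_gaussian_psf(fwhm_nm = 200, spacing_nm = 50)
#' sum(psf$kernel)  # 1
#' @export
make_gaussian_psf <- function(fwhm_nm, spacing_nm, rank = 2, shape = "auto") {
  rank <- max(length(fwhm_nm), length(spacing_nm), rank)
  if (!rank %in% c(2L, 3L)) stop("PSF rank must be 2 or 3")
  fwhm_nm <- rep_len(as.numeric(fwhm_nm), rank)
  spacing_nm <- rep_len(as.numeric(spacing_nm), rank)
  if (any(fwhm_nm <= 0) || any(spacing_nm <= 0)) {
    stop("`fwhm_nm` and `spacing_nm` must be positive")
  }
  sigma <- resolution_to_sigma(fwhm_nm)
  if (identical(shape, "auto")) {
    half <- pmax(1L, ceiling(4 * sigma / spacing_nm))
  } else {
    shape <- as.integer(rep_len(shape, rank))
    if (any(shape %% 2L == 0L)) stop("kernel `shape` must be odd")
    half <- (shape - 1L) / 2L
  }
  axes <- lapply(seq_len(rank), function(ax) {
    x <- (-half[ax]:half[ax]) * spacing_nm[ax]
    exp(-x^2 / (2 * sigma[ax]^2))
  })
  kernel <- Reduce(`%o%`, axes)
  kernel <- kernel / sum(kernel)
  structure(list(fwhm_nm = fwhm_nm, sigma_nm = sigma, kernel = kernel,
                 spacing_nm = spacing_nm),
            class = "psf_model")
}

#' @export
print.psf_model <- function(x, ...) {
  cat(sprintf("<psf_model> Gaussian, FWHM %s nm, kernel %s @ %s nm\n",
              paste(signif(x$fwhm_nm, 5), collapse = " x "),
              paste(dim(x$kernel), collapse = " x "),
              paste(signif(x$spacing_nm, 5), collapse = " x ")))
  invisible(x)
}

#' Export / import a PSF kernel as TIFF
#'
#' Thin wrappers over [write_image()] / [read_image()] for
#' interoperability checks with other deconvolution software.  The
#' re-imported PSF keeps the rendered kernel and spacing; the analytic
#' FWHM is recovered from the kernel's interpolated half-maximum
#' crossings.
#'
#' @param psf A [psf_model].
#' @param path TIFF path.
#' @return `read_psf()`: a [psf_model] with the kernel re-normalized to
#'   unit sum.
#' @export
write_psf <- function(psf, path) {
  stopifnot(inherits(psf, "psf_model"))
  write_image(frc_image(psf$kernel, psf$spacing_nm), path, bits = "float32")
}

#' @rdname write_psf
#' @export
read_psf <- function(path) {
  img <- read_image(path)
  kern <- img$pixels / sum(img$pixels)
  fwhm <- vapply(seq_along(dim(kern)), function(ax) {
    kernel_fwhm_px(profile_along(kern, ax)) * img$spacing[ax]
  }, numeric(1))
  structure(list(fwhm_nm = fwhm, sigma_nm = resolution_to_sigma(fwhm),
                 kernel = kern, spacing_nm = img$spacing),
            class = "psf_model")
}

# Central 1D profile of a kernel along one axis.
profile_along <- function(kern, axis) {
  d <- dim(kern)
  idx <- as.list((d + 1L) / 2L)
  idx[[axis]] <- seq_len(d[axis])
  as.numeric(do.call(`[`, c(list(kern), idx)))
}

# FWHM in samples from interpolated half-maximum crossings of a unimodal
# symmetric profile.
kernel_fwhm_px <- function(p) {
  half <- max(p) / 2
  i0 <- which.max(p)
  right <- which(p[i0:length(p)] < half)
  if (length(right) == 0L) return(NA_real_)
  k <- i0 + right[1] - 1L
  frac <- (p[k - 1] - half) / (p[k - 1] - p[k])
  2 * (k - 1L + frac - i0)
}
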