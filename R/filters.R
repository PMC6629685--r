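#' Low-pass transfer-function value at a given frequency
#'
#' Pure evaluator for the three transfer-function families used by
#' [lowpass_transfer()]:
#' ideal \eqn{H(r) = 1} for \eqn{r < r_{th}}, else 0;
#' Butterworth \eqn{H(r) = 1 / (1 + (r/r_{th})^{2n})};
#' Gaussian \eqn{H(r) = \exp(-r^2 / (2 r_{th}^2))}.
#' At the cutoff the Butterworth filter passes exactly 1/2 for every
#' order, and the Gaussian filter \eqn{e^{-1/2} \approx 0.607}.
#'
#' @param kind `"ideal"`, `"butterworth"` or `"gaussian"`.
#' @param r Frequency (same units as `r_th`).
#' @param r_th Cutoff frequency, > 0.
#' @param n Butterworth order, >= 1.
#' @return `H(r)`, vectorized over `r`.
#' @export
transfer_value <- function(kind = c("ideal", "butterworth", "gaussian"),
                           r, r_th, n = 3) {
  kind <- match.arg(kind)
  if (!is.numeric(r_th) || length(r_th) != 1L || r_th <= 0) {
    stop("`r_th` must be a positive scalar")
  }
  h_from_rho2(kind, (r / r_th)^2, n)
}

# H as a function of the squared normalized radius rho^2 = (r / r_th)^2
# (or its elliptical generalization).
h_from_rho2 <- function(kind, rho2, n) {
  switch(kind,
         ideal = 1 * (rho2 < 1),
         butterworth = {
           if (n < 1) stop("Butterworth order `n` must be >= 1")
           1 / (1 + rho2^n)
         },
         gaussian = exp(-rho2 / 2))
}

#' Sampled low-pass transfer function on an image frequency grid
#'
#' Samples an ideal, Butterworth or Gaussian low-pass transfer function on
#' the FFT frequency grid of an image, with the cutoff `r_th` in physical
#' units (1/nm) — typically the FRC crossing frequency.  A vector `r_th`
#' with one entry per axis defines an elliptical cutoff surface (useful in
#' 3D when the lateral and axial resolutions differ, e.g. from an SFSC
#' measurement): the scalar radius `r / r_th` is replaced by the
#' elliptical radius \eqn{\sqrt{\sum_j (f_j / r_{th,j})^2}}.
#'
#' @param kind Filter family: `"ideal"`, `"butterworth"` or `"gaussian"`.
#' @param r_th Cutoff frequency (1/nm), scalar or one per axis.
#' @param image An [frc_image] supplying the grid, or NULL if `dims` and
#'   `spacing` are given.
#' @param n Butterworth order (default 3).
#' @param dims,spacing Grid geometry if `image` is not supplied.
#' @return An object of class `transfer_function` with the sampled values
#'   `H` (unshifted FFT layout), `kind`, `r_th`, `order`, `dims`,
#'   `spacing`.
#' @export
lowpass_transfer <- function(kind = c("ideal", "butterworth", "gaussian"),
                             r_th, image = NULL, n = 3, dims = NULL,
                             spacing = NULL) {
  kind <- match.arg(kind)
  if (!is.null(image)) {
    stopifnot(is_frc_image(image))
    dims <- dim(image)
    spacing <- image$spacing
  }
  if (is.null(dims) || is.null(spacing)) {
    stop("supply either `image` or both `dims` and `spacing`")
  }
  if (!is.numeric(r_th) || any(r_th <= 0)) stop("`r_th` must be positive")
  if (!length(r_th) %in% c(1L, length(dims))) {
    stop("`r_th` must be scalar or one value per axis")
  }
  rho2 <- 0
  for (ax in seq_along(dims)) {
    cutoff <- if (length(r_th) == 1L) r_th else r_th[ax]
    rho2 <- rho2 + (freq_coord(dims, ax, spacing) / cutoff)^2
  }
  H <- h_from_rho2(kind, rho2, n)
  structure(list(H = H, kind = kind, r_th = r_th, order = n,
                 dims = dims, spacing = spacing),
            class = "transfer_function")
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf("<transfer_function> %s low-pass, cutoff %s 1/nm%s, grid %s\n",
              x$kind, paste(signif(x$r_th, 4), collapse = "/"),
              if (x$kind == "butterworth") paste0(", order ", x$order) else "",
              paste(x$dims, collapse = " x ")))
  invisible(x)
}

#' Apply a frequency-domain transfer function to an image
#'
#' Multiplies the image spectrum by the sampled transfer function and
#' transforms back.  Since `H(0) = 1` for all supported filters, the image
#' mean (DC) is preserved exactly, and since `H <= 1` the total energy
#' never increases.
#'
#' @param image An [frc_image].
#' @param transfer A [lowpass_transfer()] object sampled on the image's
#'   grid.
#' @return The filtered [frc_image] (real part; the imaginary residue of
#'   the inverse transform is of round-off size and discarded).
#' @export
filter_image <- function(image, transfer) {
  stopifnot(is_frc_image(image), inherits(transfer, "transfer_function"))
  if (!identical(dim(image), as.integer(transfer$dims)) &&
      !identical(as.integer(dim(image)), as.integer(transfer$dims))) {
    stop("transfer function was sampled on a different grid")
  }
  out <- ifftn(stats::fft(image$pixels) * transfer$H)
  frc_image(array(Re(out), dim(image)), image$spacing)
}
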