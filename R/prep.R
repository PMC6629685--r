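#' Resample a 3D volume to isotropic voxel spacing
#'
#' Linearly interpolates every axis whose spacing is coarser than the
#' finest axis, so that all axes end up at `min(spacing)`.  This upsamples
#' the (typically coarser) axial direction while leaving the lateral axes
#' untouched when they are already the finest, and is required before any
#' Fourier-shell measurement so that frequency shells are spherical in
#' physical units.
#'
#' The resampled axis keeps the physical origin of the first sample: new
#' sample positions are `0, t, 2t, ...` up to the old axis extent, giving
#' `floor((n - 1) * s / t) + 1` samples for an axis of `n` samples at
#' spacing `s` and target `t`.
#'
#' @param image A 3D [frc_image].  2D images are returned unchanged with a
#'   warning (nothing to do).
#' @return An [frc_image] with equal spacing on all axes.
#' @export
resample_isotropic <- function(image) {
  stopifnot(is_frc_image(image))
  if (length(dim(image)) == 2L) {
    warning("resample_isotropic() is a no-op on 2D images")
    return(image)
  }
  target <- min(image$spacing)
  px <- image$pixels
  for (ax in seq_along(image$spacing)) {
    s <- image$spacing[ax]
    if (abs(s - target) < 1e-9 * target) next
    px <- interp_axis(px, ax, s, target)
  }
  frc_image(px, rep(target, 3))
}

# Linear interpolation of a 3D array along one axis, from spacing `s` to
# spacing `t` (t < s), keeping the physical extent of the sampled grid.
interp_axis <- function(arr, axis, s, t) {
  d <- dim(arr)
  n <- d[axis]
  old_pos <- (seq_len(n) - 1) * s
  new_n <- floor((n - 1) * s / t) + 1
  new_pos <- (seq_len(new_n) - 1) * t
  perm <- c(axis, seq_along(d)[-axis])
  m <- matrix(aperm(arr, perm), nrow = n)
  out <- apply(m, 2, function(col) {
    stats::approx(old_pos, col, xout = new_pos)$y
  })
  out <- array(out, c(new_n, d[-axis]))
  aperm(out, order(perm))
}

#' Apply a separable apodization window
#'
#' Multiplies the image by the outer product of per-axis window vectors
#' to suppress the spurious spectral correlations that the periodic FFT
#' boundary would otherwise introduce.  Applied to every image (or
#' sub-image) before an FRC/FSC measurement.  `"hamming"`
#' (`0.54 - 0.46 cos(2 pi k/(N-1))`) is the default for 2D FRC;
#' `"hann"` (`0.5 - 0.5 cos`) trades a slightly wider main lobe for much
#' faster side-lobe decay and is used for the 3D sectioned measurement,
#' where Hamming side lobes leak the strong in-plane spectrum into the
#' sparsely populated high-inclination sections.
#'
#' @param image An [frc_image].
#' @param kind Window type: `"hamming"` (default) or `"hann"`.
#' @return The windowed [frc_image] (same shape and spacing).
#' @export
apply_window <- function(image, kind = c("hamming", "hann")) {
  stopifnot(is_frc_image(image))
  if (!is.character(kind) || !all(kind %in% c("hamming", "hann"))) {
    stop("unknown window kind: ", paste(kind, collapse = ", "))
  }
  kind <- match.arg(kind)
  d <- dim(image)
  w <- lapply(d, if (kind == "hamming") hamming_vec else hann_vec)
  win <- Reduce(`%o%`, w)
  frc_image(image$pixels * win, image$spacing)
}

hamming_vec <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

hann_vec <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Register two images by phase correlation
#'
#' Estimates the translation of `moving` relative to `reference` from the
#' peak of the phase-correlation surface, refines it to sub-pixel accuracy
#' by a local quadratic fit of the peak, and returns the moving image
#' shifted back onto the reference grid (by the rounded integer shift,
#' with circular wrap).
#'
#' @param reference,moving Two [frc_image]s of identical shape and spacing.
#' @return A list with `shift` (sub-pixel estimate, per axis, in pixels;
#'   positive means `moving` is displaced towards higher indices),
#'   `shift_int` (rounded shift actually applied) and `registered` (the
#'   realigned moving image).
#' @export
register_translation <- function(reference, moving) {
  stopifnot(is_frc_image(reference), is_frc_image(moving))
  if (!identical(dim(reference), dim(moving))) {
    stop("images must have identical dimensions")
  }
  F1 <- stats::fft(reference$pixels)
  F2 <- stats::fft(moving$pixels)
  R <- Conj(F1) * F2
  mag <- Mod(R)
  R <- R / pmax(mag, .Machine$double.eps)
  cc <- Re(ifftn(R))
  peak <- arrayInd(which.max(cc), dim(cc))[1, ]
  d <- dim(cc)
  shift_int <- ifelse(peak - 1 > d / 2, peak - 1 - d, peak - 1)
  # quadratic refinement per axis on the wrapped neighbours of the peak
  frac <- vapply(seq_along(d), function(ax) {
    at <- function(off) {
      idx <- peak
      idx[ax] <- ((idx[ax] - 1 + off) %% d[ax]) + 1
      cc[matrix(idx, 1)]
    }
    c0 <- at(0); cm <- at(-1); cp <- at(1)
    den <- cm - 2 * c0 + cp
    if (abs(den) < .Machine$double.eps) 0 else
      max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
  }, numeric(1))
  shift <- shift_int + frac
  registered <- frc_image(roll_array(moving$pixels, -round(shift)),
                          moving$spacing)
  list(shift = shift, shift_int = shift_int, registered = registered)
}
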