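#' Fourier ring/shell correlation between two images
#'
#' Computes the normalized spectral cross-correlation between two
#' registered images of the same field with independent noise,
#'
#' \deqn{FRC(r_i) = \frac{\sum_{r \in r_i} Re\, F_1(r) F_2(r)^*}
#'   {\sqrt{\sum_{r \in r_i} |F_1(r)|^2 \; \sum_{r \in r_i} |F_2(r)|^2}}}
#'
#' over concentric frequency rings (2D) or shells (3D).  Rings are indexed
#' on the normalized frequency radius \eqn{\sqrt{\sum_j (k_j/N_j)^2}}
#' (cycles/pixel) with a default width of one frequency pixel of the
#' longest axis, so square images reproduce the classic integer-radius
#' rings.  The caller is expected to window (and, for two physically
#' acquired images, register) the inputs first; see [two_image_frc()] for
#' the full measurement workflow.
#'
#' @param image1,image2 Two [frc_image]s of identical shape and spacing.
#' @param bin_width Ring width in frequency pixels of the longest axis
#'   (default 1).
#' @param max_freq Highest ring centre retained, in cycles/pixel
#'   (default 0.5, the axis Nyquist; the spectrum corner extends to
#'   \eqn{0.5\sqrt{2}}).
#' @return An object of class `frc_curve`: list with `freq` (ring centres,
#'   cycles/pixel), `correlation`, `n_points` (Fourier samples per ring)
#'   and `pixel_size_nm`.  Rings whose normalization vanishes (e.g. all
#'   rings but DC for a constant image) are dropped.
#' @examples
#' a <- frc_image(matrix(rpois(64 * 64, 20), 64, 64), spacing = 50)
#' frc_curve(a, a)  # correlation 1 in every ring
#' @export
frc_curve <- function(image1, image2, bin_width = 1, max_freq = 0.5) {
  stopifnot(is_frc_image(image1), is_frc_image(image2))
  if (!identical(dim(image1), dim(image2))) {
    stop("images must have identical dimensions")
  }
  if (max(abs(image1$spacing - image2$spacing)) >
      1e-6 * mean(image1$spacing)) {
    stop("images must have identical spacing")
  }
  curve <- frc_curve_arrays(image1$pixels, image2$pixels, bin_width, max_freq)
  curve$pixel_size_nm <- lateral_spacing(image1)
  curve
}

# Core ring binning on bare arrays; pixel size attached by callers.
frc_curve_arrays <- function(a1, a2, bin_width = 1, max_freq = 0.5,
                             ring = NULL) {
  d <- dim(a1)
  L <- max(d)
  F1 <- stats::fft(a1)
  F2 <- stats::fft(a2)
  if (is.null(ring)) ring <- ring_index(d, bin_width)
  sums <- rowsum(cbind(as.vector(Re(F1 * Conj(F2))), as.vector(Mod(F1)^2),
                       as.vector(Mod(F2)^2), 1),
                 group = as.vector(ring))
  idx <- as.integer(rownames(sums))
  freq <- idx * bin_width / L
  denom <- sqrt(sums[, 2] * sums[, 3])
  keep <- sums[, 4] > 0 & denom > 0 & freq <= max_freq + 1e-12
  structure(
    list(freq = freq[keep],
         correlation = unname(sums[keep, 1] / denom[keep]),
         n_points = unname(as.integer(sums[keep, 4])),
         pixel_size_nm = NA_real_,
         bin_width = bin_width),
    class = "frc_curve")
}

ring_index <- function(dims, bin_width = 1) {
  r <- freq_radius(dims)             # cycles/pixel
  as.integer(round(r * max(dims) / bin_width))
}

#' @export
print.frc_curve <- function(x, ...) {
  cat(sprintf("<frc_curve> %d rings, freq 0..%.3f cycles/pixel, pixel %s nm\n",
              length(x$freq), max(x$freq),
              if (is.na(x$pixel_size_nm)) "?" else
                format(signif(x$pixel_size_nm, 5))))
  invisible(x)
}

#' @export
as.data.frame.frc_curve <- function(x, ...) {
  data.frame(freq_cyc_px = x$freq,
             freq_nm_inv = if (is.na(x$pixel_size_nm)) NA_real_ else
               x$freq / x$pixel_size_nm,
             correlation = x$correlation,
             n_points = x$n_points)
}

#' @param x An `frc_curve`.
#' @param threshold Optional [frc_threshold] to overlay.
#' @param ... Passed to [graphics::plot()].
#' @rdname frc_curve
#' @export
plot.frc_curve <- function(x, threshold = NULL, ...) {
  xs <- if (is.na(x$pixel_size_nm)) x$freq else x$freq / x$pixel_size_nm
  xl <- if (is.na(x$pixel_size_nm)) "frequency (cycles/pixel)" else
    "frequency (1/nm)"
  graphics::plot(xs, x$correlation, type = "l", xlab = xl,
                 ylab = "FRC", ylim = c(min(0, x$correlation), 1), ...)
  graphics::abline(h = 0, col = "grey")
  if (!is.null(threshold)) {
    ts <- if (is.na(x$pixel_size_nm)) threshold$freq else
      threshold$freq / x$pixel_size_nm
    graphics::lines(ts, threshold$threshold, lty = 2, col = "red")
  }
  invisible(x)
}

#' Split an image into checkerboard sub-image pairs
#'
#' Partitions the pixel lattice by row/column parity into four sub-images:
#' pair A holds the (even, even) and (odd, odd) classes (one diagonal of
#' the checkerboard), pair B the (even, odd) and (odd, even) classes
#' (indices counted from 0).  The two sub-images of a pair share the image
#' structure but carry independent noise, which is what makes single-image
#' FRC possible.  For odd image dimensions the trailing row/column is
#' truncated so the parity classes stay balanced.  Sub-image spacing is
#' twice the original.
#'
#' @param image A 2D [frc_image] with both dimensions at least 2.
#' @return A list with elements `pair_a` and `pair_b`, each a list of two
#'   [frc_image]s.
#' @export
checkerboard_split <- function(image) {
  stopifnot(is_frc_image(image))
  if (length(dim(image)) != 2L) stop("checkerboard_split() expects a 2D image")
  d <- dim(image)
  if (any(d < 2L)) stop("image dimensions must be at least 2")
  px <- image$pixels
  ny <- d[1] - d[1] %% 2L
  nx <- d[2] - d[2] %% 2L
  px <- px[seq_len(ny), seq_len(nx), drop = FALSE]
  ev_y <- seq(1L, ny, 2L); od_y <- seq(2L, ny, 2L)
  ev_x <- seq(1L, nx, 2L); od_x <- seq(2L, nx, 2L)
  s2 <- image$spacing * 2
  sub <- function(ry, rx) frc_image(px[ry, rx, drop = FALSE], s2)
  list(pair_a = list(sub(ev_y, ev_x), sub(od_y, od_x)),
       pair_b = list(sub(ev_y, od_x), sub(od_y, ev_x)))
}

#' Single-image FRC measurement
#'
#' Measures the effective resolution of a single image by checkerboard
#' sub-sampling: the image is split into two sub-image pairs
#' ([checkerboard_split()]), an FRC curve is computed for each pair, and
#' the two curves are averaged bin-wise (averaging suppresses the spectral
#' asymmetries that arise when image detail is predominantly oriented in
#' one direction).  Following the convention of the single-image method,
#' the frequency axis of the raw curve is expressed against the
#' *original* pixel size even though the sub-images are sampled at twice
#' the pitch; the resulting apparent shift of the curve, together with the
#' spectral modulation introduced by the sub-pixel offset between the two
#' sub-images of a pair, is absorbed by the calibration.  The raw
#' resolution number is therefore not directly comparable to a two-image
#' measurement unless a [fit_calibration()] model is applied.
#'
#' @param image A 2D [frc_image], at least 16x16 pixels.
#' @param calibration Optional [frc_calibration] mapping the raw
#'   single-image resolution onto the two-image reference scale.  Only
#'   valid for the fixed 1/7 threshold.
#' @param bin_width,max_freq Ring binning, as in [frc_curve()].
#' @param threshold Resolution criterion: `"fixed_1_7"` (default) or
#'   `"snr_e"` (requires `snr_e`).
#' @param snr_e Expected SNR for the `"snr_e"` criterion.
#' @param window Apply a Hamming window to each sub-image (default TRUE).
#' @return A list of class `one_image_frc` with `curve` (the averaged
#'   [frc_curve]) and `resolution` (an [frc_resolution]).
#' @export
one_image_frc <- function(image, calibration = NULL, bin_width = 1,
                          max_freq = 0.5, threshold = c("fixed_1_7", "snr_e"),
                          snr_e = NULL, window = TRUE) {
  stopifnot(is_frc_image(image))
  threshold <- match.arg(threshold)
  if (length(dim(image)) != 2L) stop("one_image_frc() expects a 2D image")
  if (any(dim(image) < 16L)) {
    stop("image too small for a meaningful FRC (need at least 16x16 pixels)")
  }
  sp <- checkerboard_split(image)
  prep <- function(im) if (window) apply_window(im)$pixels else im$pixels
  ca <- frc_curve_arrays(prep(sp$pair_a[[1]]), prep(sp$pair_a[[2]]),
                         bin_width, max_freq)
  cb <- frc_curve_arrays(prep(sp$pair_b[[1]]), prep(sp$pair_b[[2]]),
                         bin_width, max_freq)
  curve <- average_curves(ca, cb)
  # frequency axis against the ORIGINAL pixel pitch (see Details)
  curve$pixel_size_nm <- lateral_spacing(image)
  thr <- make_threshold(curve, criterion = threshold, snr_e = snr_e)
  res <- resolution_from_curve(curve, thr)
  res$mode <- "one_image"
  if (!is.null(calibration)) {
    if (threshold != "fixed_1_7") {
      warning("calibration model is only valid for the fixed 1/7 threshold")
    }
    res$d_min_nm <- predict(calibration, res$d_min_nm)
    res$crossing_freq <- 1 / res$d_min_nm
    res$calibrated <- TRUE
  }
  structure(list(curve = curve, resolution = res), class = "one_image_frc")
}

#' @export
print.one_image_frc <- function(x, ...) {
  print(x$resolution)
  invisible(x)
}

# Bin-wise average of two frc_curves on identical binning; n_points are
# summed (two measurements contribute to each bin).
average_curves <- function(ca, cb) {
  common <- intersect(ca$freq, cb$freq)
  ia <- match(common, ca$freq)
  ib <- match(common, cb$freq)
  structure(
    list(freq = common,
         correlation = (ca$correlation[ia] + cb$correlation[ib]) / 2,
         n_points = ca$n_points[ia] + cb$n_points[ib],
         pixel_size_nm = NA_real_,
         bin_width = ca$bin_width),
    class = "frc_curve")
}

#' Two-image FRC measurement
#'
#' The reference ("gold standard") FRC workflow: optional phase-correlation
#' registration, Hamming windowing of both images, ring correlation and
#' resolution extraction.
#'
#' @inheritParams frc_curve
#' @inheritParams one_image_frc
#' @param register Register `image2` onto `image1` first (default FALSE;
#'   synthetic realizations are already aligned).
#' @return A list of class `two_image_frc` with `curve` and `resolution`.
#' @export
two_image_frc <- function(image1, image2, bin_width = 1, max_freq = 0.5,
                          threshold = c("fixed_1_7", "snr_e"), snr_e = NULL,
                          register = FALSE, window = TRUE) {
  threshold <- match.arg(threshold)
  if (register) {
    image2 <- register_translation(image1, image2)$registered
  }
  if (window) {
    image1 <- apply_window(image1)
    image2 <- apply_window(image2)
  }
  curve <- frc_curve(image1, image2, bin_width, max_freq)
  thr <- make_threshold(curve, criterion = threshold, snr_e = snr_e)
  res <- resolution_from_curve(curve, thr)
  res$mode <- "two_image"
  structure(list(curve = curve, resolution = res), class = "two_image_frc")
}

#' @export
print.two_image_frc <- function(x, ...) {
  print(x$resolution)
  invisible(x)
}

#' Resolution threshold curve
#'
#' Builds the per-ring threshold against which an FRC/FSC curve is
#' compared.  `"fixed_1_7"` is the constant 1/7 criterion customary in
#' super-resolution FRC.  `"snr_e"` is the SNR-based family
#'
#' \deqn{T(r_i) = \frac{SNR_e + (2\sqrt{SNR_e} + 1)/\sqrt{N(r_i)}}
#'   {SNR_e + 1 + 2\sqrt{SNR_e}/\sqrt{N(r_i)}}}
#'
#' where \eqn{N(r_i)} is the number of Fourier samples in ring/shell
#' \eqn{i}; `snr_e = 0.5` gives the "one-bit" curve used with sectioned
#' FSC.  As \eqn{N \to \infty} the threshold tends to
#' \eqn{SNR_e/(SNR_e+1)}, and at \eqn{SNR_e = 0} it reduces to
#' \eqn{1/\sqrt{N}}.
#'
#' @param curve An [frc_curve] supplying the binning and `n_points`.
#' @param criterion `"fixed_1_7"` or `"snr_e"`.
#' @param snr_e Expected SNR at the cutoff (required for `"snr_e"`,
#'   must be >= 0).
#' @return An object of class `frc_threshold` with `freq`, `threshold`,
#'   `criterion` and (for the SNR family) `snr_e`.
#' @export
make_threshold <- function(curve, criterion = c("fixed_1_7", "snr_e"),
                           snr_e = NULL) {
  criterion <- match.arg(criterion)
  if (criterion == "fixed_1_7") {
    thr <- rep(1 / 7, length(curve$freq))
  } else {
    if (is.null(snr_e)) stop("criterion \"snr_e\" requires `snr_e`")
    if (!is.numeric(snr_e) || snr_e < 0) stop("`snr_e` must be >= 0")
    N <- curve$n_points
    thr <- (snr_e + (2 * sqrt(snr_e) + 1) / sqrt(N)) /
      (snr_e + 1 + 2 * sqrt(snr_e) / sqrt(N))
  }
  structure(list(freq = curve$freq, threshold = thr, criterion = criterion,
                 snr_e = if (criterion == "snr_e") snr_e else NULL),
            class = "frc_threshold")
}

#' Numeric resolution from an FRC/FSC curve
#'
#' Finds the lowest frequency at which the correlation drops below the
#' threshold curve; the crossing is located by linear interpolation of
#' `correlation - threshold` between the two bracketing rings, and
#' converted to a physical resolution `d_min = pixel_size / f_cross` (nm).
#' The DC ring is never eligible as a crossing.  If the curve never drops
#' below the threshold within the measured band, the result is flagged
#' `no_crossing` and the sampling-limited bound `2 * pixel_size` is
#' reported.
#'
#' @param curve An [frc_curve] with a physical `pixel_size_nm`.
#' @param threshold An [frc_threshold] on the same binning, or a criterion
#'   string accepted by [make_threshold()].
#' @param snr_e Passed to [make_threshold()] when `threshold` is a string.
#' @return An object of class `frc_resolution`: `d_min_nm`,
#'   `crossing_freq` (1/nm), `criterion`, `calibrated`, `mode`,
#'   `no_crossing`, `pixel_size_nm`.
#' @export
resolution_from_curve <- function(curve, threshold = "fixed_1_7",
                                  snr_e = NULL) {
  if (is.character(threshold)) {
    threshold <- make_threshold(curve, criterion = threshold, snr_e = snr_e)
  }
  if (!identical(curve$freq, threshold$freq)) {
    stop("curve and threshold must share the same binning")
  }
  px <- curve$pixel_size_nm
  if (is.na(px)) stop("curve has no physical pixel size")
  g <- curve$correlation - threshold$threshold
  elig <- which(curve$freq > 0)          # DC never a crossing
  below <- elig[g[elig] < 0]
  if (length(below) == 0L) {
    return(structure(
      list(d_min_nm = 2 * px, crossing_freq = 1 / (2 * px),
           criterion = threshold$criterion, calibrated = FALSE,
           mode = NA_character_, no_crossing = TRUE, pixel_size_nm = px),
      class = "frc_resolution"))
  }
  k <- below[1]
  if (k == 1L) {
    f_cross <- curve$freq[1]
  } else {
    g0 <- g[k - 1]; g1 <- g[k]
    f0 <- curve$freq[k - 1]; f1 <- curve$freq[k]
    f_cross <- f0 + (f1 - f0) * g0 / (g0 - g1)
  }
  structure(
    list(d_min_nm = px / f_cross, crossing_freq = f_cross / px,
         criterion = threshold$criterion, calibrated = FALSE,
         mode = NA_character_, no_crossing = FALSE, pixel_size_nm = px),
    class = "frc_resolution")
}

#' @export
print.frc_resolution <- function(x, ...) {
  cat(sprintf(
    "<frc_resolution> d_min = %.1f nm (%s%s%s)\n",
    x$d_min_nm,
    switch(x$criterion, fixed_1_7 = "1/7 threshold", snr_e = "SNR threshold",
           x$criterion),
    if (isTRUE(x$calibrated)) ", calibrated" else "",
    if (isTRUE(x$no_crossing)) ", NO CROSSING - sampling bound" else ""))
  invisible(x)
}
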