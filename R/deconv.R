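#' Blind Wiener deconvolution
#'
#' Single-step inverse filtering with Tikhonov-style regularization:
#' \deqn{O = \frac{H^*}{|H|^2 + w}\, I}
#' evaluated in the frequency domain, where `H` is the transfer function
#' of the PSF and `w = |N|^2/|O|^2` the noise-to-signal power ratio that
#' regularizes the inverse (algebraically the same as the textbook
#' `1/H * |H|^2 / (|H|^2 + w)` form, but stable where `H` vanishes;
#' since the PSF transfer satisfies `|H| <= 1`, `w` is the level of
#' `|H|^2` below which the inverse rolls off).  The image is
#' mirror-padded by one PSF half support before the transform so the
#' circular product does not wrap real structure across the boundary.
#' For a blind application pass the PSF produced by
#' [make_gaussian_psf()] from an FRC/SFSC resolution estimate.
#'
#' @param image An [frc_image].
#' @param psf A [psf_model] rendered on the image's spacing.
#' @param snr_reg Regularization constant `w`, > 0: *smaller* values
#'   regularize less (crisper, noisier).  Customary choices: 0.1 for 2D
#'   confocal data, 0.005 for 3D stacks.
#' @param clip Clip negative output values to zero (display contract,
#'   default TRUE); the unclipped result is returned when FALSE.
#' @return The deconvolved [frc_image].
#' @export
wiener_deconvolve <- function(image, psf, snr_reg = 0.1, clip = TRUE) {
  stopifnot(is_frc_image(image), inherits(psf, "psf_model"))
  if (max(abs(psf$spacing_nm - image$spacing)) > 1e-6 * mean(image$spacing)) {
    stop("PSF was rendered at a different spacing than the image")
  }
  if (!is.numeric(snr_reg) || snr_reg <= 0) stop("`snr_reg` must be > 0")
  pad <- (dim(psf$kernel) - 1L) / 2L
  P <- sym_pad(image$pixels, pad)
  H <- stats::fft(embed_kernel(psf$kernel, dim(P)))
  O <- Conj(H) / (Mod(H)^2 + snr_reg) * stats::fft(P)
  out <- crop_center(Re(ifftn(O)), pad)
  if (clip) out <- pmax(out, 0)
  frc_image(array(out, dim(image)), image$spacing)
}

#' One multiplicative Richardson-Lucy update
#'
#' Computes the next object estimate
#' \deqn{o_{k+1} = \left\{\frac{i}{h \otimes o_k + b} \otimes h^*\right\}
#'   o_k}
#' optionally divided by the total-variation factor
#' \eqn{1 - \lambda_{TV}\,\mathrm{div}(\nabla o_k / |\nabla o_k|)}
#' (multiplicative TV regularization).  Convolutions are evaluated in the
#' frequency domain; with `boundary = "symmetric"` (default) the image is
#' mirror-extended by one PSF half support first, with `"circular"` the
#' plain periodic convolution is used (under which the update conserves
#' total flux exactly when `b = 0`).
#'
#' @param estimate Current object estimate (array or [frc_image]),
#'   non-negative, not identically zero.
#' @param image Observed image (same shape).
#' @param psf A [psf_model] (kernel normalized to unit sum).
#' @param b Non-negative scalar background term.
#' @param tv_lambda TV regularization weight (0 disables; 5e-4 is the
#'   customary value for the adjustive TV variant).
#' @param boundary `"symmetric"` or `"circular"`.
#' @return The next estimate, same type as `estimate`, non-negative.
#' @export
rl_step <- function(estimate, image, psf, b = 0, tv_lambda = 0,
                    boundary = c("symmetric", "circular")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(psf, "psf_model"))
  o <- if (is_frc_image(estimate)) estimate$pixels else estimate
  i <- if (is_frc_image(image)) image$pixels else image
  if (!identical(dim(o), dim(i))) stop("estimate and image shapes differ")
  if (!is.numeric(b) || b < 0) stop("background `b` must be >= 0")
  if (tv_lambda < 0) stop("`tv_lambda` must be >= 0")
  if (all(o == 0)) stop("all-zero estimate is a fixed point of RL")
  h <- psf$kernel
  blur <- conv_fft(o, h, boundary = boundary)
  ratio <- i / pmax(blur + b, .Machine$double.eps)
  corr <- conv_fft(ratio, h, correlate = TRUE, boundary = boundary)
  out <- o * corr
  if (tv_lambda > 0) {
    den <- 1 - tv_lambda * div_unit_gradient(o)
    out <- out / pmax(den, .Machine$double.eps)
  }
  out <- pmax(out, 0)
  if (is_frc_image(estimate)) frc_image(out, estimate$spacing) else out
}

# Divergence of the unit gradient field div(grad o / |grad o|), central
# differences with replicated edges; the TV curvature term.
div_unit_gradient <- function(o, eps = 1e-8) {
  d <- dim(o)
  rank <- length(d)
  shift_ax <- function(a, ax, by) {
    idx <- lapply(d, seq_len)
    idx[[ax]] <- pmin(pmax(idx[[ax]] + by, 1L), d[ax])
    do.call(`[`, c(list(a), idx))
  }
  grads <- lapply(seq_len(rank), function(ax) {
    (shift_ax(o, ax, 1L) - shift_ax(o, ax, -1L)) / 2
  })
  mag <- sqrt(Reduce(`+`, lapply(grads, function(g) g^2)) + eps^2)
  div <- 0
  for (ax in seq_len(rank)) {
    u <- grads[[ax]] / mag
    div <- div + (shift_ax(u, ax, 1L) - shift_ax(u, ax, -1L)) / 2
  }
  div
}

#' Relative change between successive deconvolution estimates
#'
#' \deqn{\tau_1 = \sum |o_k - o_{k-1}| / \sum o_k}
#' a classical convergence measure for iterative deconvolution.
#'
#' @param current,previous Two estimates of identical shape (arrays or
#'   [frc_image]s); `sum(current)` must be positive.
#' @return The scalar \eqn{\tau_1}.
#' @export
tau1 <- function(current, previous) {
  c_ <- if (is_frc_image(current)) current$pixels else current
  p_ <- if (is_frc_image(previous)) previous$pixels else previous
  if (!identical(dim(c_), dim(p_))) stop("estimate shapes differ")
  s <- sum(c_)
  if (s <= 0) stop("current estimate has non-positive sum")
  sum(abs(c_ - p_)) / s
}

#' Fraction of non-converging pixels in the RL ratio image
#'
#' Evaluates \eqn{u = (i / (h \otimes o_k)) \otimes h^*} and counts the
#' pixels whose value is neither within `epsilon` of 0 nor within
#' `epsilon` of 1: \eqn{\eta_k = N(u)/N}.  At convergence the ratio image
#' is 1 everywhere and \eqn{\eta_k = 0}.
#'
#' @param image Observed image.
#' @param estimate Current estimate.
#' @param psf A [psf_model].
#' @param epsilon Convergence epsilon, in (0, 0.5); default 0.05.
#' @param boundary Convolution boundary, as in [rl_step()].
#' @return \eqn{\eta_k} in `[0, 1]`.
#' @export
eta_k <- function(image, estimate, psf, epsilon = 0.05,
                  boundary = c("symmetric", "circular")) {
  boundary <- match.arg(boundary)
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon >= 0.5) {
    stop("`epsilon` must be in (0, 0.5)")
  }
  o <- if (is_frc_image(estimate)) estimate$pixels else estimate
  i <- if (is_frc_image(image)) image$pixels else image
  h <- psf$kernel
  blur <- conv_fft(o, h, boundary = boundary)
  u <- conv_fft(i / pmax(blur, .Machine$double.eps), h, correlate = TRUE,
                boundary = boundary)
  bad <- u < -epsilon | (u > epsilon & u < 1 - epsilon) | u > 1 + epsilon
  mean(bad)
}

#' Blind background level estimate
#'
#' Segments the image into signal and background by an automatic
#' intensity threshold (maximizing the between-class variance over a
#' 256-bin histogram, Otsu's rule) and returns the mean intensity of the
#' background segment — the `b` term of [rl_step()].
#'
#' @param image An [frc_image] or array.
#' @return Scalar background level `b >= 0`.  A constant image returns the
#'   constant with a warning.
#' @export
estimate_background <- function(image) {
  px <- if (is_frc_image(image)) image$pixels else image
  rng <- range(px)
  if (diff(rng) == 0) {
    warning("constant image: background equals the constant value")
    return(rng[1])
  }
  thr <- otsu_threshold(px)
  below <- px[px < thr]
  if (length(below) == 0L) return(rng[1])
  mean(below)
}

# Otsu's between-class variance maximization on a 256-bin histogram;
# returns the threshold intensity.
otsu_threshold <- function(px, nbins = 256L) {
  rng <- range(px)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  counts <- tabulate(findInterval(px, breaks, all.inside = TRUE), nbins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- cumsum(counts)
  mu <- cumsum(counts * mids)
  n <- w[nbins]; mu_t <- mu[nbins]
  w0 <- w[-nbins]; mu0 <- mu[-nbins]
  between <- (mu_t * w0 - mu0)^2 / pmax(w0 * (n - w0), 1)
  breaks[which.max(between) + 1L]
}
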