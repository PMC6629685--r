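# Internal FFT helpers shared by the spectral-correlation, filtering and
# deconvolution code.  All spectra are kept in the "unshifted" FFT layout
# (DC at index 1); ring/shell geometry is computed from wrapped frequency
# coordinates so no fftshift is ever needed.

# Wrapped integer frequency index for an axis of length n:
# 0, 1, ..., floor((n-1)/2), -floor(n/2), ..., -1
fft_freq_index <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

# Array of per-axis frequency coordinates (cycles per physical unit when
# spacing is given, cycles/pixel otherwise), axis `axis` of dims `dims`.
freq_coord <- function(dims, axis, spacing = rep(1, length(dims))) {
  f <- fft_freq_index(dims[axis]) / (dims[axis] * spacing[axis])
  rank <- length(dims)
  shape <- rep(1L, rank)
  shape[axis] <- dims[axis]
  aperm(array(f, dims[c(axis, seq_len(rank)[-axis])]),
        order(c(axis, seq_len(rank)[-axis])))
}

# Radial frequency magnitude array: cycles/pixel (spacing = 1) or 1/nm.
freq_radius <- function(dims, spacing = rep(1, length(dims))) {
  r2 <- 0
  for (ax in seq_along(dims)) {
    r2 <- r2 + freq_coord(dims, ax, spacing)^2
  }
  sqrt(r2)
}

ifftn <- function(z) stats::fft(z, inverse = TRUE) / length(z)

# Circular shift: result[i] == a[i - shift] (wrapped), per axis.
roll_array <- function(a, shift) {
  d <- dim(a)
  idx <- mapply(function(n, s) ((seq_len(n) - 1 - s) %% n) + 1,
                d, shift, SIMPLIFY = FALSE)
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# Symmetric (mirror, edge included) padding by `pad` samples per axis.
sym_pad <- function(a, pad) {
  d <- dim(a)
  idx <- mapply(function(n, p) {
    if (p == 0L) return(seq_len(n))
    if (p > n) stop("padding exceeds image extent")
    c(p:1, seq_len(n), n:(n - p + 1))
  }, d, pad, SIMPLIFY = FALSE)
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

crop_center <- function(a, pad) {
  d <- dim(a)
  idx <- mapply(function(n, p) (p + 1):(n - p), d, pad, SIMPLIFY = FALSE)
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# Embed an odd-sized kernel into an array of dims `out_dim`, with the
# kernel centre moved to the DC position (index 1) so that frequency-domain
# multiplication performs an unshifted convolution.
embed_kernel <- function(kern, out_dim) {
  kd <- dim(kern)
  if (any(kd %% 2L == 0L)) stop("kernel dimensions must be odd")
  if (any(kd > out_dim)) stop("kernel is larger than the image it is applied to")
  big <- array(0, out_dim)
  idx <- lapply(kd, seq_len)
  big <- do.call(`[<-`, c(list(big), idx, list(kern)))
  roll_array(big, -(kd - 1L) / 2L)
}

# Linear convolution (or correlation) of an array with an odd-sized kernel,
# computed in the frequency domain.  boundary = "symmetric" mirrors the
# image by half a kernel support before the circular FFT product, which is
# equivalent to direct spatial convolution over the mirrored extension;
# boundary = "circular" wraps.
conv_fft <- function(x, kern, correlate = FALSE,
                     boundary = c("symmetric", "circular")) {
  boundary <- match.arg(boundary)
  pad <- if (boundary == "symmetric") (dim(kern) - 1L) / 2L else
    rep(0L, length(dim(x)))
  xp <- if (boundary == "symmetric") sym_pad(x, pad) else x
  K <- stats::fft(embed_kernel(kern, dim(xp)))
  if (correlate) K <- Conj(K)
  out <- Re(ifftn(stats::fft(xp) * K))
  if (boundary == "symmetric") out <- crop_center(out, pad) else out
  out
}
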