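# Independent brute-force oracles and small fixture builders used across
# the test files.  The oracles deliberately avoid the package's FFT
# helpers: DFTs are evaluated with explicit transform matrices and
# convolutions with explicit spatial sums.

# Full 2D DFT via explicit transform matrices (no stats::fft).
dft2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  W1 <- outer(0:(n1 - 1), 0:(n1 - 1),
              function(j, k) exp(-2i * pi * j * k / n1))
  W2 <- outer(0:(n2 - 1), 0:(n2 - 1),
              function(j, k) exp(-2i * pi * j * k / n2))
  W1 %*% x %*% W2
}

# Brute-force FRC: explicit ring enumeration of Eq-style per-ring sums on
# the wrapped frequency lattice (ring convention shared with the package:
# rings of unit width on the normalized radius times the longest axis).
frc_brute <- function(a1, a2) {
  d <- dim(a1); L <- max(d)
  F1 <- dft2(a1); F2 <- dft2(a2)
  wrap <- function(k, n) ifelse(k > n / 2, k - n, k)
  rings <- list()
  for (j in seq_len(d[1])) {
    for (k in seq_len(d[2])) {
      fy <- wrap(j - 1, d[1]) / d[1]
      fx <- wrap(k - 1, d[2]) / d[2]
      ri <- as.character(round(sqrt(fy^2 + fx^2) * L))
      rings[[ri]] <- rbind(rings[[ri]], c(j, k))
    }
  }
  idx <- sort(as.integer(names(rings)))
  corr <- n_pts <- numeric(0)
  freq <- numeric(0)
  for (ri in idx) {
    mem <- rings[[as.character(ri)]]
    num <- den1 <- den2 <- 0
    for (m in seq_len(nrow(mem))) {
      f1 <- F1[mem[m, 1], mem[m, 2]]
      f2 <- F2[mem[m, 1], mem[m, 2]]
      num <- num + Re(f1 * Conj(f2))
      den1 <- den1 + Mod(f1)^2
      den2 <- den2 + Mod(f2)^2
    }
    if (den1 * den2 > 0 && ri / L <= 0.5 + 1e-12) {
      corr <- c(corr, num / sqrt(den1 * den2))
      n_pts <- c(n_pts, nrow(mem))
      freq <- c(freq, ri / L)
    }
  }
  list(freq = freq, correlation = corr, n_points = n_pts)
}

# Smooth low-frequency structure with unit peak amplitude (for
# peak-SNR-controlled noise experiments).
smooth_structure <- function(n) {
  g <- seq(0, 2 * pi, length.out = n)
  outer(sin(3 * g), cos(2 * g)) * 0.5 + 0.5 * outer(cos(g), sin(4 * g))
}

# Circular shift of a matrix: result[i] = x[i - s] (wrapped).
roll_shift <- function(x, s) {
  d <- dim(x)
  idx <- mapply(function(n, sh) ((seq_len(n) - 1 - sh) %% n) + 1, d, s,
                SIMPLIFY = FALSE)
  x[idx[[1]], idx[[2]], drop = FALSE]
}

# Mirror (symmetric, edge-repeated) index lookup.
reflect_idx <- function(i, n) {
  ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
}

# Direct spatial convolution / correlation with an odd kernel over the
# mirror-extended image.
conv_brute <- function(x, kern, correlate = FALSE) {
  d <- dim(x); kd <- dim(kern); h <- (kd - 1) / 2
  out <- array(0, d)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      acc <- 0
      for (u in seq_len(kd[1])) {
        for (v in seq_len(kd[2])) {
          du <- u - h[1] - 1; dv <- v - h[2] - 1
          if (correlate) {
            ii <- i + du; jj <- j + dv
          } else {
            ii <- i - du; jj <- j - dv
          }
          acc <- acc + kern[u, v] * x[reflect_idx(ii, d[1]),
                                      reflect_idx(jj, d[2])]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Brute-force RL update: direct spatial evaluation of the multiplicative
# update over the mirror-extended image.
rl_brute <- function(o, i, kern, b = 0) {
  blur <- conv_brute(o, kern)
  ratio <- i / pmax(blur + b, .Machine$double.eps)
  o * conv_brute(ratio, kern, correlate = TRUE)
}

# A small noisy blurred test scene with ground truth attached.
tiny_scene <- function(seed = 1, shape = c(64, 64), peak = 200,
                       fwhm = 250, px = 50, background = 0) {
  spec <- acquisition_spec(shape = shape, pixel_size_nm = px,
                           fwhm_nm = fwhm, peak_photons = peak,
                           background_photons = background, seed = seed)
  ph <- make_phantom(spec)
  ims <- simulate_acquisition(ph, spec)
  list(spec = spec, phantom = ph, images = ims,
       noiseless = attr(ims, "noiseless"))
}
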