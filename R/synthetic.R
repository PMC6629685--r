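#' Specification of a synthetic acquisition
#'
#' Describes a simulated fluorescence acquisition with known ground
#' truth: a phantom structure, a Gaussian blur (the "microscope"), and
#' Poisson photon counting.  The defaults emulate a confocal acquisition
#' of a filamentous (cytoskeleton-like) sample: 50 nm pixels, 250 nm
#' lateral PSF FWHM, a peak signal of 200 photons and no camera offset.
#' In 3D the default axial FWHM is three times the lateral one, the
#' typical anisotropy of a single-objective microscope.
#'
#' @param kind Phantom structure: `"filaments"`, `"points"`, `"mixed"`.
#' @param shape Image size in pixels, `(y, x)` or `(z, y, x)`.
#' @param pixel_size_nm Sampling distance (nm), scalar (isotropic).
#' @param fwhm_nm PSF FWHM per axis (nm); a scalar is expanded to
#'   `(3f, f, f)` for 3D shapes.
#' @param peak_photons Expected photon count at the brightest pixel of
#'   the blurred structure, > 0.
#' @param background_photons Uniform background photon rate added to the
#'   signal before Poisson sampling.
#' @param n_realizations Number of independent noise realizations
#'   [simulate_acquisition()] generates.
#' @param density Expected emitters per pixel for the `"points"` phantom.
#' @param seed Random seed; everything downstream is deterministic given
#'   the spec.
#' @return A list of class `acquisition_spec`.  A spec whose FWHM is
#'   below the pixel size is flagged `subresolved` (the blur is not
#'   resolvable on the grid).
#' @export
acquisition_spec <- function(kind = c("filaments", "points", "mixed"),
                             shape = c(256, 256), pixel_size_nm = 50,
                             fwhm_nm = 250, peak_photons = 200,
                             background_photons = 0, n_realizations = 2,
                             density = 1e-3, seed = 1) {
  kind <- match.arg(kind)
  rank <- length(shape)
  if (!rank %in% c(2L, 3L) || any(shape < 4)) stop("degenerate `shape`")
  if (peak_photons <= 0) stop("`peak_photons` must be > 0")
  if (background_photons < 0) stop("`background_photons` must be >= 0")
  if (length(fwhm_nm) == 1L && rank == 3L) {
    fwhm_nm <- c(3 * fwhm_nm, fwhm_nm, fwhm_nm)
  }
  fwhm_nm <- rep_len(fwhm_nm, rank)
  structure(list(kind = kind, shape = as.integer(shape),
                 pixel_size_nm = pixel_size_nm, fwhm_nm = fwhm_nm,
                 peak_photons = peak_photons,
                 background_photons = background_photons,
                 n_realizations = as.integer(n_realizations),
                 density = density, seed = as.integer(seed),
                 subresolved = any(fwhm_nm < pixel_size_nm)),
            class = "acquisition_spec")
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a noiseless ground-truth phantom
#'
#' Renders the phantom structure of an [acquisition_spec()] on its pixel
#' grid, unblurred and noiseless, with values in `[0, 1]`:
#' `"filaments"` are smoothed random-walk curves (random starting points
#' and headings, small angular diffusion per step) deposited with
#' sub-pixel linear splatting, emulating cytoskeletal fibres;
#' `"points"` are isolated sub-pixel emitters at a Poisson-distributed
#' count with expectation `density * n_pixels`; `"mixed"` superimposes
#' both.  Deterministic given the spec's seed.
#'
#' @param spec An [acquisition_spec()].
#' @return An [frc_image] ground-truth phantom.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "acquisition_spec"))
  with_seed(spec$seed, {
    n_emitters <- NULL
    px <- switch(spec$kind,
                 filaments = render_filaments(spec$shape),
                 points = {
                   p <- render_points(spec$shape, spec$density)
                   n_emitters <- attr(p, "n_emitters")
                   p
                 },
                 mixed = 0.7 * render_filaments(spec$shape) +
                   0.3 * render_points(spec$shape, spec$density))
    m <- max(px)
    if (m > 0) px <- px / m
    out <- frc_image(px, spec$pixel_size_nm)
    # ground-truth sidecar for the points phantom
    attr(out, "n_emitters") <- n_emitters
    out
  })
}

render_filaments <- function(shape) {
  rank <- length(shape)
  n_fil <- max(4L, round(prod(shape)^(1 / rank) / 6))
  steps <- round(4 * max(shape))
  pts <- vector("list", n_fil)
  for (f in seq_len(n_fil)) {
    pos <- stats::runif(rank, 1, shape)
    dir <- stats::rnorm(rank)
    dir <- dir / sqrt(sum(dir^2))
    path <- matrix(NA_real_, steps, rank)
    for (s in seq_len(steps)) {
      dir <- dir + stats::rnorm(rank, sd = 0.08)
      dir <- dir / sqrt(sum(dir^2))
      pos <- pos + 0.5 * dir
      if (any(pos < 1) || any(pos > shape)) break
      path[s, ] <- pos
    }
    pts[[f]] <- path[stats::complete.cases(path), , drop = FALSE]
  }
  splat_points(shape, do.call(rbind, pts))
}

render_points <- function(shape, density) {
  n <- stats::rpois(1, density * prod(shape))
  pos <- matrix(stats::runif(n * length(shape), 1, shape),
                ncol = length(shape), byrow = TRUE)
  out <- splat_points(shape, pos)
  attr(out, "n_emitters") <- n
  out
}

# Deposit unit mass at fractional positions (rows of `pos`) by
# multi-linear weighting over the 2^rank neighbouring pixels (sub-pixel
# anti-aliasing), vectorized over points.
splat_points <- function(shape, pos) {
  acc <- array(0, shape)
  if (is.null(pos) || nrow(pos) == 0L) return(acc)
  rank <- length(shape)
  lo <- floor(pos)
  fr <- pos - lo
  stride <- cumprod(c(1, shape[-rank]))
  for (corner in 0:(2^rank - 1)) {
    off <- as.integer(intToBits(corner))[seq_len(rank)]
    idx <- sweep(lo, 2, off, `+`)
    ok <- rowSums(idx >= 1 & idx <= rep(shape, each = nrow(idx))) == rank
    if (!any(ok)) next
    w <- rep(1, nrow(pos))
    for (ax in seq_len(rank)) {
      w <- w * if (off[ax] == 1L) fr[, ax] else 1 - fr[, ax]
    }
    lin <- as.vector((idx[ok, , drop = FALSE] - 1) %*% stride) + 1
    add <- rowsum(w[ok], group = lin)
    at <- as.integer(rownames(add))
    acc[at] <- acc[at] + add[, 1]
  }
  acc
}

#' Simulate noisy acquisitions of a phantom
#'
#' Convolves the phantom with the Gaussian PSF of the spec, scales the
#' blurred structure so its maximum equals `peak_photons`, adds the
#' uniform background rate, and draws `n_realizations` independent
#' Poisson realizations — the "two images of the same field with
#' independent noise" that two-image FRC requires.  The noiseless photon
#' rate is attached as the `"noiseless"` attribute of the returned list.
#'
#' @param phantom The ground-truth [frc_image] from [make_phantom()].
#' @param spec The matching [acquisition_spec()].
#' @return A list of `n_realizations` [frc_image]s sharing the identical
#'   noiseless signal with independent Poisson noise.
#' @export
simulate_acquisition <- function(phantom, spec) {
  stopifnot(is_frc_image(phantom), inherits(spec, "acquisition_spec"))
  psf <- make_gaussian_psf(spec$fwhm_nm, phantom$spacing)
  blurred <- conv_fft(phantom$pixels, psf$kernel)
  blurred <- pmax(blurred, 0)
  m <- max(blurred)
  if (m <= 0) stop("phantom is empty")
  rate <- spec$peak_photons * blurred / m + spec$background_photons
  out <- lapply(seq_len(spec$n_realizations), function(r) {
    with_seed(spec$seed + 7919L * r, {
      frc_image(array(stats::rpois(length(rate), rate), dim(rate)),
                phantom$spacing)
    })
  })
  attr(out, "noiseless") <- frc_image(rate, phantom$spacing)
  out
}
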