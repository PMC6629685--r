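#' Split a single volume into two sub-volumes for single-volume FSC
#'
#' Lateral (xy) planes are split along one checkerboard diagonal — the
#' (even, even) class forms one sub-volume and the (odd, odd) class the
#' other — while consecutive z layers are summed pairwise, which keeps the
#' volume proportions and introduces no axial offset between the two
#' sub-volumes.  Odd dimensions are truncated by one sample first.
#' Sub-volume spacing is twice the original on all axes.
#'
#' @param volume A 3D [frc_image] with all dimensions at least 2.
#' @return A list of two [frc_image] sub-volumes of identical shape.
#' @export
volume_split <- function(volume) {
  stopifnot(is_frc_image(volume))
  if (length(dim(volume)) != 3L) stop("volume_split() expects a 3D image")
  d <- dim(volume)
  if (any(d < 2L)) stop("volume dimensions must be at least 2")
  d2 <- d - d %% 2L
  px <- volume$pixels[seq_len(d2[1]), seq_len(d2[2]), seq_len(d2[3]),
                      drop = FALSE]
  z1 <- seq(1L, d2[1], 2L); z2 <- seq(2L, d2[1], 2L)
  ev_y <- seq(1L, d2[2], 2L); od_y <- seq(2L, d2[2], 2L)
  ev_x <- seq(1L, d2[3], 2L); od_x <- seq(2L, d2[3], 2L)
  s2 <- volume$spacing * 2
  v1 <- px[z1, ev_y, ev_x, drop = FALSE] + px[z2, ev_y, ev_x, drop = FALSE]
  v2 <- px[z1, od_y, od_x, drop = FALSE] + px[z2, od_y, od_x, drop = FALSE]
  list(frc_image(v1, s2), frc_image(v2, s2))
}

#' Sampling-anisotropy frequency correction factor
#'
#' Factor by which the voxel size is multiplied before converting the
#' frequency axis of a directional resolution measurement at inclination
#' `theta` from the lateral (xy) plane:
#' \deqn{k(\theta) = 1 + (z - 1)\,|\sin\theta|}
#' so that a purely lateral section (`theta = 0`) needs no correction and
#' a purely axial one (`theta = pi/2`) is corrected by the full anisotropy
#' factor `z` (e.g. `z = 2` for a stack sampled at half the lateral rate
#' in depth).  Without the correction, directional resolutions at
#' `theta != 0` come out unrealistically optimistic.
#'
#' @param theta Inclination angle(s) from the lateral plane, radians.
#' @param z Sampling anisotropy factor, >= 1.
#' @return The scale factor(s) `k(theta)`.
#' @export
anisotropy_scale <- function(theta, z = 1) {
  if (!is.numeric(z) || any(z < 1)) {
    stop("anisotropy factor `z` must be >= 1")
  }
  1 + (z - 1) * abs(sin(theta))
}

#' Sectioned Fourier shell correlation (SFSC)
#'
#' Direction-dependent 3D resolution measurement.  Each Fourier shell is
#' divided into dihedral wedges about a rotation axis lying in the xy
#' plane (default y): a voxel's direction is projected onto the plane
#' perpendicular to the rotation axis and the inclination of that
#' projection from the lateral plane, folded to `[0, pi)` (a wedge and its
#' point-symmetric mirror form one section), assigns it to the section
#' whose centre angle is nearest.  Sections are centred at multiples of
#' `alpha`, which is also the wedge angular size, so every non-DC voxel
#' belongs to exactly one section.  For every section a full shell
#' correlation curve and a resolution value are computed; the default
#' criterion is the one-bit SNR threshold (`snr_e = 0.5`) evaluated with
#' the section's own per-shell sample counts.  With `alpha >= pi` the
#' single section covers the whole sphere and SFSC reduces to the plain
#' FSC.
#'
#' Volumes must be isotropically sampled (see [resample_isotropic()]).
#' If the isotropic resampling merely interpolated a coarser axial
#' sampling, pass the original axial/lateral sampling ratio as `z_factor`
#' so the frequency axis of inclined sections is corrected by
#' [anisotropy_scale()] before resolutions are reported.
#'
#' @param volume1,volume2 Two registered 3D [frc_image]s with equal,
#'   isotropic spacing (use [volume_split()] when only one volume is
#'   available).
#' @param alpha Wedge size and rotation increment, radians; `pi / alpha`
#'   must be an integer (default `pi / 12`, i.e. 15 degrees).
#' @param rotation_axis `"y"` (default) or `"x"`.
#' @param threshold `"one_bit"` (default) or `"fixed_1_7"`.
#' @param z_factor Sampling anisotropy factor for [anisotropy_scale()].
#' @param bin_width,max_freq Shell binning, as in [frc_curve()].
#' @param window Apodization applied to both volumes first: `"hann"`
#'   (default; its fast side-lobe decay keeps the strong in-plane
#'   spectrum from leaking into the high-inclination sections),
#'   `"hamming"`, or `FALSE` for none.
#' @return An object of class `sfsc_result`: `angles` (radians),
#'   `curves` (one [frc_curve] per section), `resolutions` (a data frame
#'   with `angle_rad`, `d_min_nm`, `no_crossing`), `alpha`,
#'   `rotation_axis`, `z_factor`.
#' @export
sfsc <- function(volume1, volume2, alpha = pi / 12,
                 rotation_axis = c("y", "x"),
                 threshold = c("one_bit", "fixed_1_7"), z_factor = 1,
                 bin_width = 1, max_freq = 0.5, window = "hann") {
  stopifnot(is_frc_image(volume1), is_frc_image(volume2))
  rotation_axis <- match.arg(rotation_axis)
  threshold <- match.arg(threshold)
  if (length(dim(volume1)) != 3L) stop("sfsc() expects 3D volumes")
  if (!identical(dim(volume1), dim(volume2))) {
    stop("volumes must have identical dimensions")
  }
  sp <- volume1$spacing
  if (diff(range(sp)) > 1e-6 * mean(sp)) {
    stop("volumes must be isotropically sampled; see resample_isotropic()")
  }
  if (alpha >= pi - 1e-12) {
    nsec <- 1L
  } else {
    nsec <- pi / alpha
    if (abs(nsec - round(nsec)) > 1e-9) {
      stop("`alpha` must divide pi into an integer number of sections")
    }
    nsec <- as.integer(round(nsec))
  }
  if (!isFALSE(window)) {
    volume1 <- apply_window(volume1, kind = window)
    volume2 <- apply_window(volume2, kind = window)
  }
  d <- dim(volume1)
  L <- max(d)
  F1 <- stats::fft(volume1$pixels)
  F2 <- stats::fft(volume2$pixels)
  shell <- ring_index(d, bin_width)
  if (nsec == 1L) {
    sec <- array(0L, d)
  } else {
    # Inclination of the voxel direction from the lateral plane, in
    # [0, pi/2]; the sign of f_perp * f_z (f_perp = the lateral axis
    # perpendicular to the rotation axis) separates the two diagonal
    # wedge families, so a section and its point-symmetric mirror
    # coincide and sections tile the sphere.
    fz <- freq_coord(d, 1L)
    fy <- freq_coord(d, 2L)
    fx <- freq_coord(d, 3L)
    incl <- atan2(abs(fz), sqrt(fx^2 + fy^2))
    perp <- if (rotation_axis == "y") fx else fy
    phi <- ifelse(perp * fz >= 0, incl, pi - incl)
    sec <- as.integer(round(phi / alpha)) %% nsec
  }
  code <- sec * (max(shell) + 1L) + shell
  sums <- rowsum(cbind(as.vector(Re(F1 * Conj(F2))), as.vector(Mod(F1)^2),
                       as.vector(Mod(F2)^2), 1),
                 group = as.vector(code))
  codes <- as.integer(rownames(sums))
  angles <- (seq_len(nsec) - 1L) * if (nsec == 1L) 0 else alpha
  curves <- vector("list", nsec)
  res <- data.frame(angle_rad = angles, d_min_nm = NA_real_,
                    no_crossing = NA)
  for (j in seq_len(nsec)) {
    in_sec <- codes %/% (max(shell) + 1L) == j - 1L
    idx <- codes[in_sec] %% (max(shell) + 1L)
    freq <- idx * bin_width / L
    denom <- sqrt(sums[in_sec, 2] * sums[in_sec, 3])
    keep <- denom > 0 & freq <= max_freq + 1e-12
    cur <- structure(
      list(freq = freq[keep],
           correlation = unname(sums[in_sec, 1][keep] / denom[keep]),
           n_points = unname(as.integer(sums[in_sec, 4][keep])),
           pixel_size_nm = sp[1] * anisotropy_scale(angles[j], z_factor),
           bin_width = bin_width),
      class = "frc_curve")
    o <- order(cur$freq)
    cur$freq <- cur$freq[o]
    cur$correlation <- cur$correlation[o]
    cur$n_points <- cur$n_points[o]
    curves[[j]] <- cur
    thr <- if (threshold == "one_bit") {
      make_threshold(cur, "snr_e", snr_e = 0.5)
    } else {
      make_threshold(cur, "fixed_1_7")
    }
    r <- resolution_from_curve(cur, thr)
    res$d_min_nm[j] <- r$d_min_nm
    res$no_crossing[j] <- r$no_crossing
  }
  structure(list(angles = angles, curves = curves, resolutions = res,
                 alpha = alpha, rotation_axis = rotation_axis,
                 z_factor = z_factor, threshold = threshold),
            class = "sfsc_result")
}

#' @export
print.sfsc_result <- function(x, ...) {
  cat(sprintf("<sfsc_result> %d section(s), alpha = %.1f deg, axis %s\n",
              length(x$angles), x$alpha * 180 / pi, x$rotation_axis))
  print(transform(x$resolutions, angle_deg = angle_rad * 180 / pi)[
    , c("angle_deg", "d_min_nm", "no_crossing")])
  invisible(x)
}

#' @param x An `sfsc_result`.
#' @param ... Passed to [graphics::plot()].
#' @rdname sfsc
#' @export
plot.sfsc_result <- function(x, ...) {
  th <- c(x$angles, x$angles + pi, x$angles[1])
  d <- c(x$resolutions$d_min_nm, x$resolutions$d_min_nm,
         x$resolutions$d_min_nm[1])
  lim <- max(d) * 1.05
  graphics::plot(d * cos(th), d * sin(th), type = "b", asp = 1,
                 xlim = c(-lim, lim), ylim = c(-lim, lim),
                 xlab = "lateral d_min (nm)", ylab = "axial d_min (nm)", ...)
  graphics::abline(h = 0, v = 0, col = "grey")
  invisible(x)
}

# Directional resolutions most users want: the section nearest the
# lateral plane and the one nearest the optical axis.
sfsc_lateral_axial <- function(sf) {
  ang <- sf$resolutions$angle_rad
  lat <- sf$resolutions$d_min_nm[which.min(pmin(ang, pi - ang))]
  axi <- sf$resolutions$d_min_nm[which.min(abs(ang - pi / 2))]
  c(lateral = lat, axial = axi)
}
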