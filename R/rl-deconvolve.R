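#' Options for Richardson-Lucy deconvolution
#'
#' @param max_iter Maximum number of iterations.
#' @param stop_grad_threshold Stop once the per-iteration resolution
#'   change (nm per iteration; improving resolution means a *negative*
#'   change of `d_min`) rises to or above this value.  Customary choices:
#'   `-1` (most of the resolution gain made), `-0.2` (near-complete
#'   convergence), `0` (maximal resolution).  `-Inf` disables the rule.
#'   The value assumes nanometre units; scale it accordingly for data on
#'   very different length scales.
#' @param adjustive Re-estimate the PSF from the single-image FRC of every
#'   intermediate estimate ("adjustive" blind RL).
#' @param tv_lambda Total-variation weight (0 = off; 5e-4 customary with
#'   the adjustive variant).
#' @param background Background term `b`: non-negative scalar, or
#'   `"auto"` for [estimate_background()].
#' @param epsilon_eta Convergence epsilon of [eta_k()].
#' @param failsafe Stop when the resolution trend reverses (the
#'   second-difference sign flip that signals abnormal convergence, e.g.
#'   background over-fitting).
#' @param calibration Optional [frc_calibration] applied to the
#'   per-iteration single-image FRC so the stopping thresholds act on the
#'   physical (two-image-equivalent) resolution scale.
#' @param grad_smooth Moving-average window (iterations, odd) applied to
#'   the resolution differences before the stopping test; 1 = raw
#'   differences.  Per-iteration FRC values carry estimation noise, so a
#'   3-point average can stabilize the rule on noisy data.
#' @param boundary Convolution boundary handling, see [rl_step()].
#' @return A list of class `rl_options`.
#' @export
rl_options <- function(max_iter = 50L, stop_grad_threshold = -1,
                       adjustive = FALSE, tv_lambda = 0, background = 0,
                       epsilon_eta = 0.05, failsafe = TRUE,
                       calibration = NULL, grad_smooth = 1L,
                       boundary = "symmetric") {
  if (is.finite(stop_grad_threshold) && stop_grad_threshold > 0) {
    stop("`stop_grad_threshold` must be <= 0 (resolution change in nm/it)")
  }
  if (tv_lambda < 0) stop("`tv_lambda` must be >= 0")
  if (max_iter < 0) stop("`max_iter` must be >= 0")
  if (!identical(background, "auto") &&
      (!is.numeric(background) || background < 0)) {
    stop("`background` must be a non-negative number or \"auto\"")
  }
  structure(list(max_iter = as.integer(max_iter),
                 stop_grad_threshold = stop_grad_threshold,
                 adjustive = isTRUE(adjustive), tv_lambda = tv_lambda,
                 background = background, epsilon_eta = epsilon_eta,
                 failsafe = isTRUE(failsafe), calibration = calibration,
                 grad_smooth = as.integer(grad_smooth),
                 boundary = boundary),
            class = "rl_options")
}

#' Evaluate the FRC-based stopping rules on a deconvolution trace
#'
#' Applies, in order: (1) the trend-reversal failsafe — once the
#' resolution has been improving (negative change), a switch to a
#' *worsening* resolution (positive change, i.e. a sign flip of the
#' second difference away from the convergence trend) aborts the run;
#' (2) the gradient threshold — stop when the (optionally smoothed)
#' change of `d_min` per iteration has risen to or above
#' `stop_grad_threshold`; (3) the iteration cap.
#'
#' @param trace A [deconv_trace] (or data frame with a `d_min_nm` column,
#'   one row per iteration, iteration 0 = input image).
#' @param options An [rl_options] object.
#' @return A list with `stop` (logical) and `reason` (`"continue"`,
#'   `"threshold_reached"`, `"max_resolution"`, `"failsafe_grad2"`, or
#'   `"max_iter"`).
#' @export
stopping_check <- function(trace, options = rl_options()) {
  d <- trace$d_min_nm
  n <- length(d)
  iter <- n - 1L                         # row 1 is iteration 0
  if (n >= 3L && options$failsafe) {
    g_now <- d[n] - d[n - 1]
    g_prev <- d[n - 1] - d[n - 2]
    if (g_prev < 0 && g_now > 0) {
      return(list(stop = TRUE, reason = "failsafe_grad2"))
    }
  }
  if (n >= 2L && is.finite(options$stop_grad_threshold)) {
    g <- diff(d)
    w <- min(options$grad_smooth, length(g))
    g_now <- mean(g[(length(g) - w + 1L):length(g)])
    if (g_now >= options$stop_grad_threshold) {
      reason <- if (options$stop_grad_threshold == 0) "max_resolution" else
        "threshold_reached"
      return(list(stop = TRUE, reason = reason))
    }
  }
  if (iter >= options$max_iter) {
    return(list(stop = TRUE, reason = "max_iter"))
  }
  list(stop = FALSE, reason = "continue")
}

#' Blind Richardson-Lucy deconvolution with FRC-driven stopping
#'
#' Iterates [rl_step()] from the observed image, measuring the
#' single-image FRC resolution of every intermediate estimate.  The
#' per-iteration resolution drives the stopping rules
#' ([stopping_check()]) and, in adjustive mode, the re-estimation of the
#' Gaussian PSF.  For 3D volumes the PSF is estimated from a sectioned
#' FSC of the split volume (lateral and axial FWHM separately) and the
#' per-iteration resolution is tracked on the central z plane.
#'
#' @param image Observed [frc_image] (2D or 3D, at least 16 pixels along
#'   every lateral axis).
#' @param psf A [psf_model], or `"auto"` to estimate a Gaussian PSF from
#'   the image itself via single-image FRC (2D) / SFSC (3D).
#' @param options An [rl_options] object.
#' @return A list of class `rl_deconv`: `image` (the estimate at the stop
#'   iteration), `trace` (a [deconv_trace]), `psf` (the PSF used at the
#'   last iteration), `background` (the `b` actually applied).
#' @export
rl_deconvolve <- function(image, psf = "auto", options = rl_options()) {
  stopifnot(is_frc_image(image))
  rank <- length(dim(image))
  b <- options$background
  if (identical(b, "auto")) b <- estimate_background(image)
  if (identical(psf, "auto")) psf <- auto_psf(image, options$calibration)
  o <- image$pixels
  d0 <- iter_resolution(image$pixels, image, options$calibration)
  rows <- list(data.frame(k = 0L, d_min_nm = d0, tau1 = NA_real_,
                          eta = NA_real_))
  reason <- "max_iter"
  if (options$max_iter >= 1L) {
    for (k in seq_len(options$max_iter)) {
      o_new <- rl_step(o, image$pixels, psf, b = b,
                       tv_lambda = options$tv_lambda,
                       boundary = options$boundary)
      dk <- iter_resolution(o_new, image, options$calibration)
      rows[[k + 1L]] <- data.frame(
        k = k, d_min_nm = dk,
        tau1 = tau1(o_new, o),
        eta = eta_k(image$pixels, o_new, psf, epsilon = options$epsilon_eta,
                    boundary = options$boundary))
      o <- o_new
      if (options$adjustive && is.finite(dk)) {
        psf <- make_gaussian_psf(rep(dk, rank), image$spacing)
      }
      check <- stopping_check(do.call(rbind, rows), options)
      if (check$stop) {
        reason <- check$reason
        break
      }
    }
  }
  trace <- build_trace(do.call(rbind, rows), reason)
  list_out <- list(image = frc_image(o, image$spacing), trace = trace,
                   psf = psf, background = b)
  structure(list_out, class = "rl_deconv")
}

# Resolution of an intermediate estimate: single-image FRC on the 2D
# image, or on the central z plane of a 3D estimate (cheap per-iteration
# proxy for the full SFSC).
iter_resolution <- function(pixels, image, calibration) {
  if (length(dim(pixels)) == 3L) {
    mid <- (dim(pixels)[1] + 1L) %/% 2L
    img <- frc_image(pixels[mid, , ], image$spacing[2:3])
  } else {
    img <- frc_image(pixels, image$spacing)
  }
  res <- one_image_frc(img, calibration = calibration)$resolution
  res$d_min_nm
}

# Gaussian PSF estimated blindly from the image itself.
auto_psf <- function(image, calibration = NULL) {
  rank <- length(dim(image))
  if (rank == 2L) {
    res <- one_image_frc(image, calibration = calibration)$resolution
    if (res$no_crossing) {
      stop("single-image FRC found no threshold crossing; ",
           "supply an explicit PSF")
    }
    make_gaussian_psf(rep(res$d_min_nm, 2), image$spacing)
  } else {
    halves <- volume_split(resample_isotropic(image))
    sf <- sfsc(halves[[1]], halves[[2]])
    dla <- sfsc_lateral_axial(sf)
    if (any(!is.finite(dla))) {
      stop("SFSC found no threshold crossing; supply an explicit PSF")
    }
    make_gaussian_psf(c(dla["axial"], dla["lateral"], dla["lateral"]),
                      image$spacing)
  }
}

# Assemble the per-iteration record with first and second differences of
# the resolution.
build_trace <- function(df, stop_reason) {
  grad <- c(NA_real_, diff(df$d_min_nm))
  grad2 <- c(NA_real_, diff(grad))
  out <- data.frame(k = df$k, d_min_nm = df$d_min_nm, grad = grad,
                    grad2 = grad2, tau1 = df$tau1, eta = df$eta)
  structure(out, class = c("deconv_trace", "data.frame"),
            stop_reason = stop_reason)
}

#' Per-iteration deconvolution trace
#'
#' A data frame (class `deconv_trace`) with one row per iteration (row 0
#' is the input image): `k`, `d_min_nm` (single-image FRC resolution of
#' the estimate), `grad` (first difference, nm/iteration), `grad2`
#' (second difference), `tau1`, `eta`.  The stop reason is stored as the
#' `stop_reason` attribute.
#'
#' @param x A `deconv_trace`.
#' @param ... Unused.
#' @name deconv_trace
#' @export
print.deconv_trace <- function(x, ...) {
  cat(sprintf("<deconv_trace> %d iteration(s), stop reason: %s\n",
              max(x$k), attr(x, "stop_reason")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @rdname deconv_trace
#' @export
plot.deconv_trace <- function(x, ...) {
  graphics::plot(x$k, x$d_min_nm, type = "b", xlab = "iteration",
                 ylab = "d_min (nm)", ...)
  invisible(x)
}

#' @export
print.rl_deconv <- function(x, ...) {
  cat(sprintf(
    "<rl_deconv> %d iteration(s), stop: %s, d_min %.1f -> %.1f nm\n",
    max(x$trace$k), attr(x$trace, "stop_reason"),
    x$trace$d_min_nm[1], x$trace$d_min_nm[nrow(x$trace)]))
  invisible(x)
}
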