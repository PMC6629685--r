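#' Microscopy image with physical pixel spacing
#'
#' `frc_image` is the basic data container of the package: a 2D `(y, x)` or
#' 3D `(z, y, x)` pixel array together with the physical sampling distance
#' along every axis.  All spacings are stored internally in nanometres; the
#' optical (z) axis is always the first axis of a 3D array.
#'
#' @param pixels Numeric matrix (2D) or 3D array of finite pixel values.
#'   For photon-counting data values are expected to be non-negative, but
#'   this is not enforced so that intermediate results of linear filters
#'   (which may ring slightly below zero) can be represented.
#' @param spacing Physical sampling distance per axis, either a scalar
#'   (isotropic) or one value per array axis in `(y, x)` / `(z, y, x)`
#'   order.  Must be strictly positive.
#' @param unit Unit of `spacing`: `"nm"` (default) or `"um"`.
#'
#' @return An object of class `frc_image` with elements `pixels`,
#'   `spacing` (nm per axis) and `axes` (axis labels).
#' @examples
#' img <- frc_image(matrix(runif(64), 8, 8), spacing = 51)
#' img
#' @export
frc_image <- function(pixels, spacing, unit = c("nm", "um")) {
  unit <- match.arg(unit)
  if (is.null(dim(pixels))) {
    stop("`pixels` must be a matrix (2D) or a 3D array")
  }
  rank <- length(dim(pixels))
  if (!rank %in% c(2L, 3L)) {
    stop("`pixels` must have 2 or 3 dimensions, got ", rank)
  }
  if (!is.numeric(pixels)) stop("`pixels` must be numeric")
  if (!all(is.finite(pixels))) stop("`pixels` contains non-finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, rank)
  if (length(spacing) != rank) {
    stop("`spacing` must have one entry per axis (", rank, "), got ",
         length(spacing))
  }
  if (!all(is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` entries must be strictly positive and finite")
  }
  if (unit == "um") spacing <- spacing * 1000
  pixels <- array(as.numeric(pixels), dim(pixels))
  structure(
    list(pixels = pixels,
         spacing = spacing,
         axes = if (rank == 2L) c("y", "x") else c("z", "y", "x")),
    class = "frc_image")
}

#' @export
dim.frc_image <- function(x) dim(x$pixels)

#' @export
print.frc_image <- function(x, ...) {
  cat(sprintf("<frc_image> %s image, %s pixels, spacing %s nm\n",
              if (length(dim(x)) == 2L) "2D" else "3D",
              paste(dim(x), collapse = " x "),
              paste(signif(x$spacing, 6), collapse = " x ")))
  v <- range(x$pixels)
  cat(sprintf("  intensity range [%.4g, %.4g], mean %.4g\n",
              v[1], v[2], mean(x$pixels)))
  invisible(x)
}

#' @export
as.array.frc_image <- function(x, ...) x$pixels

#' Test whether an object is an frc_image
#' @param x Any object.
#' @return `TRUE` for `frc_image` objects.
#' @export
is_frc_image <- function(x) inherits(x, "frc_image")

# Accept either an frc_image or a bare array with an explicit spacing.
as_image <- function(x, spacing = NULL) {
  if (is_frc_image(x)) return(x)
  if (is.null(spacing)) stop("pixel spacing unknown; supply an `frc_image`")
  frc_image(x, spacing)
}

# Isotropic in-plane pixel size in nm; errors if the lateral axes disagree
# beyond floating-point noise.
lateral_spacing <- function(image) {
  s <- image$spacing
  lat <- if (length(s) == 3L) s[2:3] else s
  if (diff(range(lat)) > 1e-6 * mean(lat)) {
    stop("non-square pixels (lateral spacing ", paste(signif(lat, 6),
         collapse = " x "), " nm); resample before spectral analysis")
  }
  mean(lat)
}
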