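#' Read a TIFF image with physical pixel-size metadata
#'
#' Reads a single- or multi-page TIFF into an [frc_image].  The pixel
#' spacing is taken, in order of preference, from (1) the `spacing`
#' override, (2) a `spacing_nm=` entry in the ImageDescription tag (as
#' written by [write_image()]), (3) an ImageJ-style description
#' (`spacing=`/`unit=`) combined with the resolution tags, or (4) the
#' X/YResolution + ResolutionUnit tags (2D images only, since baseline
#' TIFF has no z-spacing tag).  If none of these yields a spacing the
#' function fails rather than silently assuming a pixel size of 1.
#'
#' @param path Path to a TIFF file.
#' @param spacing Optional explicit spacing override (per axis or scalar).
#' @param unit Unit of the `spacing` override, `"nm"` or `"um"`.
#' @return An [frc_image]; integer-typed TIFF data is returned as stored
#'   (photon counts are not rescaled to `[0, 1]`).
#' @seealso [write_image()]
#' @export
read_image <- function(path, spacing = NULL, unit = c("nm", "um")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- tiff::readTIFF(path, all = TRUE, info = TRUE, payload = FALSE)
  is_float <- "float" %in% hdr$sample.format
  # integer data is read as stored (photon counts), floats as-is
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = !is_float)
  if (!is.list(pages)) pages <- list(pages)
  info <- attributes(pages[[1]])
  rank <- if (length(pages) > 1L) 3L else 2L
  pix <- if (rank == 2L) {
    p <- pages[[1]]
    attributes(p) <- list(dim = dim(p))
    p
  } else {
    arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
    arr
  }
  if (is.null(spacing)) {
    spacing <- spacing_from_metadata(info, rank)
    if (is.null(spacing)) {
      stop("unknown pixel size: '", path, "' carries no usable spacing ",
           "metadata; pass `spacing` explicitly")
    }
    unit <- "nm"
  }
  frc_image(pix, spacing, unit = unit)
}

# Decode spacing (nm, axis order y,x or z,y,x) from readTIFF info attributes.
spacing_from_metadata <- function(info, rank) {
  desc <- info$description
  if (!is.null(desc)) {
    m <- regmatches(desc, regexpr("spacing_nm=[0-9eE.,+-]+", desc))
    if (length(m) == 1L) {
      s <- as.numeric(strsplit(sub("spacing_nm=", "", m), ",")[[1]])
      if (length(s) == rank && all(is.finite(s)) && all(s > 0)) return(s)
      if (length(s) == 1L && is.finite(s) && s > 0) return(rep(s, rank))
    }
  }
  # OME-XML in the ImageDescription: PhysicalSizeX/Y/Z (+ unit attributes)
  if (!is.null(desc) && grepl("<OME", desc, fixed = TRUE)) {
    ome <- ome_spacing(desc, rank)
    if (!is.null(ome)) return(ome)
  }
  lat <- lateral_from_tags(info)
  if (is.null(lat)) return(NULL)
  if (rank == 2L) return(lat)
  # ImageJ multi-page stacks record the z step as "spacing=" in microns
  if (!is.null(desc) && grepl("ImageJ", desc)) {
    zm <- regmatches(desc, regexpr("spacing=[0-9eE.+-]+", desc))
    un <- regmatches(desc, regexpr("unit=[a-zA-Z]+", desc))
    if (length(zm) == 1L) {
      z <- as.numeric(sub("spacing=", "", zm))
      fac <- if (length(un) == 1L && sub("unit=", "", un) == "nm") 1 else 1000
      if (is.finite(z) && z > 0) return(c(z * fac, lat))
    }
  }
  NULL
}

# PhysicalSizeX/Y/Z attributes of an OME-XML description, converted to nm
# (OME default unit is micron).
ome_spacing <- function(desc, rank) {
  grab <- function(axis) {
    m <- regmatches(desc, regexpr(
      sprintf('PhysicalSize%s="[0-9eE.+-]+"', axis), desc))
    if (length(m) != 1L) return(NULL)
    v <- as.numeric(gsub('.*"([^"]+)"', "\\1", m))
    u <- regmatches(desc, regexpr(
      sprintf('PhysicalSize%sUnit="[^"]+"', axis), desc))
    fac <- if (length(u) == 1L && grepl('"nm"', u)) 1 else 1000
    v * fac
  }
  sx <- grab("X"); sy <- grab("Y")
  if (is.null(sx) || is.null(sy)) return(NULL)
  if (rank == 2L) return(c(sy, sx))
  sz <- grab("Z")
  if (is.null(sz)) return(NULL)
  c(sz, sy, sx)
}

lateral_from_tags <- function(info) {
  xr <- info$x.resolution
  if (is.null(xr) || !is.finite(xr) || xr <= 0) return(NULL)
  yr <- if (is.null(info$y.resolution)) xr else info$y.resolution
  per_nm <- switch(if (is.null(info$resolution.unit)) "inch" else
                     info$resolution.unit,
                   cm = 1e7, inch = 2.54e7, NULL)
  if (is.null(per_nm)) return(NULL)
  c(per_nm / yr, per_nm / xr)
}

#' Write an image as TIFF with pixel-size metadata
#'
#' Writes an [frc_image] as an uncompressed little-endian TIFF (multi-page
#' for 3D volumes).  Non-negative integer-valued data up to 16 bits is
#' stored losslessly as unsigned integers; any other data is stored as
#' 32-bit IEEE floats.  The per-axis spacing is recorded both in the
#' X/YResolution tags (pixels per centimetre) and, with full precision and
#' including the z step, as `spacing_nm=` in the ImageDescription tag, so
#' that [read_image()] round-trips the spacing exactly.
#'
#' @param image An [frc_image].
#' @param path Output path; the parent directory must exist.
#' @param bits Storage type: `"auto"` (default), `"uint16"`, or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = c("auto", "uint16", "float32")) {
  bits <- match.arg(bits)
  stopifnot(is_frc_image(image))
  if (!dir.exists(dirname(path))) {
    stop("directory does not exist: ", dirname(path))
  }
  px <- image$pixels
  integerish <- all(px >= 0) && all(px <= 65535) &&
    all(abs(px - round(px)) < 1e-9)
  use_uint <- switch(bits, auto = integerish, uint16 = TRUE, float32 = FALSE)
  if (use_uint && !integerish) {
    stop("uint16 storage requires integer values in [0, 65535]")
  }
  rank <- length(dim(px))
  pages <- if (rank == 2L) list(px) else
    lapply(seq_len(dim(px)[1]), function(z) px[z, , ])
  desc <- paste0("frcrestore\nspacing_nm=",
                 paste(format(image$spacing, digits = 17, trim = TRUE,
                              scientific = FALSE), collapse = ","),
                 "\nunit=nm")
  write_tiff_pages(pages, path, float = !use_uint,
                   spacing_yx = utils::tail(image$spacing, 2), desc = desc)
  invisible(path)
}

# Minimal baseline TIFF writer (little-endian, one strip per page,
# uncompressed, greyscale).  Written by hand because the available TIFF
# bindings only write data rescaled to [0, 1] and cannot store resolution
# or description tags, both of which this package's I/O contract needs.
write_tiff_pages <- function(pages, path, float, spacing_yx, desc) {
  con <- file(path, "wb")
  on.exit(close(con))
  wb2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wb4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header
  writeBin(charToRaw("II"), con)
  wb2(42L)
  bps <- if (float) 32L else 16L
  bytespp <- bps / 8L
  desc_raw <- c(charToRaw(desc), as.raw(0))
  npages <- length(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  strip_bytes <- h * w * bytespp
  data_off <- 8L
  strip_off <- data_off + (seq_len(npages) - 1L) * strip_bytes
  ifd_start <- data_off + npages * strip_bytes
  n_entries <- 14L
  # per-IFD block: entries + next pointer, then out-of-line values
  # (XResolution rational, YResolution rational, description)
  ifd_core <- 2L + n_entries * 12L + 4L
  extra <- 8L + 8L + length(desc_raw)
  ifd_size <- ifd_core + extra
  wb4(ifd_start)                     # offset of first IFD
  for (p in seq_len(npages)) {       # pixel data, row-major
    v <- t(pages[[p]])
    if (float) {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else {
      writeBin(as.integer(round(v)), con, size = 2, endian = "little")
    }
  }
  # resolution as pixels per cm, rational num/den
  res_rat <- function(s_nm) c(1e9, round(s_nm * 100))
  for (p in seq_len(npages)) {
    ifd_off <- ifd_start + (p - 1L) * ifd_size
    xres_off <- ifd_off + ifd_core
    yres_off <- xres_off + 8L
    desc_off <- yres_off + 8L
    entry <- function(tag, type, count, value) {
      wb2(tag); wb2(type); wb4(count)
      if (type == 3L) { wb2(value); wb2(0L) } else wb4(value)
    }
    wb2(n_entries)
    entry(256L, 4L, 1L, w)                       # ImageWidth
    entry(257L, 4L, 1L, h)                       # ImageLength
    entry(258L, 3L, 1L, bps)                     # BitsPerSample
    entry(259L, 3L, 1L, 1L)                      # Compression: none
    entry(262L, 3L, 1L, 1L)                      # Photometric: BlackIsZero
    entry(270L, 2L, length(desc_raw), desc_off)  # ImageDescription
    entry(273L, 4L, 1L, strip_off[p])            # StripOffsets
    entry(277L, 3L, 1L, 1L)                      # SamplesPerPixel
    entry(278L, 4L, 1L, h)                       # RowsPerStrip
    entry(279L, 4L, 1L, strip_bytes)             # StripByteCounts
    entry(282L, 5L, 1L, xres_off)                # XResolution
    entry(283L, 5L, 1L, yres_off)                # YResolution
    entry(296L, 3L, 1L, 3L)                      # ResolutionUnit: cm
    entry(339L, 3L, 1L, if (float) 3L else 1L)   # SampleFormat
    wb4(if (p < npages) ifd_start + p * ifd_size else 0L)
    wb4(res_rat(spacing_yx[2]))                  # x: spacing along x
    wb4(res_rat(spacing_yx[1]))
    writeBin(desc_raw, con)
  }
  invisible(path)
}
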