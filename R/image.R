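# Projection images: raw ("for processing") detector frames as integer
# matrices with pixel pitch and orientation metadata.

#' Projection image container
#'
#' @param pixels Numeric matrix of non-negative ADU values (rows x columns).
#' @param pixel_pitch Pixel pitch in mm (0.070 for the mammography detector,
#'   0.140 for 2x2-binned DBT frames).
#' @param bit_depth Detector bit depth (default 14).
#' @param orientation Which image edge corresponds to the detector-side
#'   origin of the measurement axis: `"left"`/`"right"` (profile runs along
#'   columns) or `"top"`/`"bottom"` (profile runs along rows).
#' @return An object of class `projection_image`.
#' @export
projection_image <- function(pixels, pixel_pitch, bit_depth = 14,
                             orientation = c("left", "right", "top", "bottom")) {
  orientation <- match.arg(orientation)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (any(pixels < 0)) stop("pixel values must be non-negative")
  if (any(pixels > 2^bit_depth - 1))
    stop(sprintf("pixel values exceed the %d-bit range", bit_depth))
  if (!is.numeric(pixel_pitch) || pixel_pitch <= 0)
    stop("`pixel_pitch` must be positive (mm)")
  structure(list(pixels = pixels, pixel_pitch = pixel_pitch,
                 bit_depth = bit_depth, orientation = orientation),
            class = "projection_image")
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf("<projection_image> %d x %d px, %.3f mm pitch, %d-bit, origin: %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_pitch, x$bit_depth,
              x$orientation))
  cat(sprintf("  ADU range %d-%d\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read a projection image from TIFF, PNG or CSV
#'
#' 16-bit TIFF and PNG files are read at their stored integer scale.  A YAML
#' sidecar `<path>.yaml` with keys `pixel_pitch_mm`, `bit_depth` and
#' `orientation` is honoured when present; explicit arguments override it.
#'
#' @param path Image file (`.tiff`/`.tif`, `.png`, or `.csv` matrix).
#' @param pixel_pitch Pixel pitch in mm (required unless in the sidecar).
#' @param bit_depth Detector bit depth.
#' @param orientation Detector-side origin edge (see [projection_image()]).
#' @return A `projection_image`.
#' @export
read_projection_image <- function(path, pixel_pitch = NULL, bit_depth = NULL,
                                  orientation = NULL) {
  if (!file.exists(path))
    stop(errorCondition(sprintf("image file not found: %s", path),
                        class = c("slitfov_io_error", "error", "condition")))
  side <- paste0(path, ".yaml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  pixel_pitch <- pixel_pitch %||% meta$pixel_pitch_mm
  bit_depth <- bit_depth %||% meta$bit_depth %||% 14
  orientation <- orientation %||% meta$orientation %||% "left"
  if (is.null(pixel_pitch))
    stop(errorCondition(
      sprintf("pixel pitch unknown for %s: pass `pixel_pitch` or provide a sidecar", path),
      class = c("slitfov_config_error", "error", "condition")))
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = round(tiff::readTIFF(path, as.is = TRUE)),
    png = round(png::readPNG(path) * (2^16 - 1)),
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    stop(errorCondition(sprintf("unsupported image format: .%s", ext),
                        class = c("slitfov_io_error", "error", "condition")))
  )
  storage.mode(px) <- "double"
  projection_image(px, pixel_pitch = pixel_pitch, bit_depth = max(bit_depth, ceiling(log2(max(px) + 1))),
                   orientation = orientation)
}

#' Write a projection image as 16-bit TIFF
#'
#' @param image A `projection_image`.
#' @param path Output path (`.tiff`).
#' @return `path`, invisibly.
#' @export
write_projection_image <- function(image, path) {
  stopifnot(inherits(image, "projection_image"))
  tiff::writeTIFF(image$pixels / (2^16 - 1), path, bits.per.sample = 16)
  yaml::write_yaml(list(pixel_pitch_mm = image$pixel_pitch,
                        bit_depth = image$bit_depth,
                        orientation = image$orientation),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Emulate DBT 2x2 pixel binning
#'
#' Sums 2x2 pixel blocks and doubles the pixel pitch, as done by the
#' detector in tomosynthesis mode.  Values are clipped to the bit depth.
#'
#' @param image A `projection_image` with even dimensions.
#' @return The binned `projection_image`.
#' @export
bin_2x2 <- function(image) {
  stopifnot(inherits(image, "projection_image"))
  px <- image$pixels
  nr <- (nrow(px) %/% 2) * 2
  nc <- (ncol(px) %/% 2) * 2
  px <- px[seq_len(nr), seq_len(nc), drop = FALSE]
  b <- px[seq(1, nr, 2), seq(1, nc, 2)] + px[seq(2, nr, 2), seq(1, nc, 2)] +
       px[seq(1, nr, 2), seq(2, nc, 2)] + px[seq(2, nr, 2), seq(2, nc, 2)]
  b <- pmin(b, 2^image$bit_depth - 1)
  projection_image(b, pixel_pitch = 2 * image$pixel_pitch,
                   bit_depth = image$bit_depth, orientation = image$orientation)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
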