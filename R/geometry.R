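# Slit-camera projection geometry.
#
# All positions are 1D detector-plane coordinates in millimetres, with the
# origin at the detector edge nearest the camera (the first or last pixel
# row/column) and the axis positive toward the detector centre.  Heights are
# measured above the detector plane.  X_FOV is the signed distance from the
# detector edge to the X-ray field boundary: negative values mean the field
# extends beyond the detector.

#' Slit-camera geometry for one detector side
#'
#' @param y_foil Height of the fluorescent foil plane above the detector, mm.
#' @param y_slit Height of the slit aperture above the detector, mm.
#' @param x_slit Lateral slit position from the detector-side origin, mm.
#' @param y_source Source height above the detector plane (the SID), mm.
#' @param x_source Lateral source position from the detector-side origin, mm.
#' @param side Which detector side the camera is measuring.
#' @return An object of class `slit_geometry`.
#' @examples
#' chest <- slit_geometry(y_foil = 63.5, y_slit = 31.35, x_slit = 33.0,
#'                        y_source = 661.2, x_source = 23.6, side = "chest_wall")
#' fov_boundary(chest, x_edge = 69.74)
#' @export
slit_geometry <- function(y_foil, y_slit, x_slit, y_source, x_source,
                          side = c("chest_wall", "left", "right", "nipple")) {
  side <- match.arg(side)
  vals <- c(y_foil = y_foil, y_slit = y_slit, x_slit = x_slit,
            y_source = y_source, x_source = x_source)
  if (any(!is.finite(vals)))
    stop("all geometry parameters must be finite")
  if (y_source <= y_foil)
    stop("`y_source` must exceed `y_foil`")
  if (y_foil < 0) stop("`y_foil` must be non-negative")
  # y_foil = 0 (foil on the detector plane) is admitted as a degenerate case
  # in which the projection reduces to the identity
  if (y_foil > 0 && !(y_slit > 0 && y_slit < y_foil))
    stop("geometry must satisfy 0 < y_slit < y_foil < y_source")
  structure(c(as.list(vals), list(side = side)), class = "slit_geometry")
}

#' @export
print.slit_geometry <- function(x, ...) {
  cat(sprintf("<slit_geometry> side: %s\n", x$side))
  cat(sprintf("  y_foil %.2f  y_slit %.2f  y_source %.1f mm (heights)\n",
              x$y_foil, x$y_slit, x$y_source))
  cat(sprintf("  x_slit %.2f  x_source %.2f mm (from detector edge)\n",
              x$x_slit, x$x_source))
  invisible(x)
}

#' X-ray field boundary from the fluorescence edge position
#'
#' The similar-triangles projection relation of the slit camera: the
#' fluorescence edge imaged at `x_edge` inside the camera corresponds to a
#' field boundary at
#' \deqn{X_{FOV} = \frac{x_{edge} + \frac{y_{foil}}{y_{slit}}(x_{slit} -
#'   x_{edge}) - \frac{y_{foil}}{y_{source}} x_{source}}{1 -
#'   y_{foil}/y_{source}}}{X_FOV = [x_edge + (y_foil/y_slit)(x_slit - x_edge)
#'   - (y_foil/y_source) x_source] / (1 - y_foil/y_source)}
#' Negative results mean the field extends beyond the detector edge.
#'
#' @param geom A [slit_geometry()].
#' @param x_edge Fluorescence edge position(s) measured in the image, mm.
#' @return X_FOV in mm (vectorized over `x_edge`).
#' @export
fov_boundary <- function(geom, x_edge) {
  stopifnot(inherits(geom, "slit_geometry"))
  if (geom$y_foil >= geom$y_source)
    stop(errorCondition("degenerate geometry: y_foil >= y_source",
                        class = c("slitfov_geometry_error", "error", "condition")))
  rf <- if (geom$y_foil == 0) 0 else geom$y_foil / geom$y_slit
  rs <- geom$y_foil / geom$y_source
  (x_edge + rf * (geom$x_slit - x_edge) - rs * geom$x_source) / (1 - rs)
}

#' Fluorescence edge position from a known field boundary
#'
#' Algebraic inverse of [fov_boundary()], used to place ground truth when
#' rendering synthetic scenes.
#'
#' @param geom A [slit_geometry()].
#' @param x_fov Field boundary position(s), mm (negative = beyond detector).
#' @return x_edge in mm (vectorized over `x_fov`).
#' @export
invert_fov_boundary <- function(geom, x_fov) {
  stopifnot(inherits(geom, "slit_geometry"))
  if (geom$y_foil >= geom$y_source)
    stop(errorCondition("degenerate geometry: y_foil >= y_source",
                        class = c("slitfov_geometry_error", "error", "condition")))
  rf <- if (geom$y_foil == 0) 0 else geom$y_foil / geom$y_slit
  if (abs(1 - rf) < 1e-12)
    stop(errorCondition("degenerate geometry: y_foil == y_slit",
                        class = c("slitfov_geometry_error", "error", "condition")))
  rs <- geom$y_foil / geom$y_source
  (x_fov * (1 - rs) - rf * geom$x_slit + rs * geom$x_source) / (1 - rf)
}

#' Scale a distance measured above the detector to the detector plane
#'
#' Distances read on an elevated plane (for example the top of the breast
#' support) subtend a larger span at the detector plane by the source
#' magnification SID / (SID - h).
#'
#' @param distance Distance(s) measured at height `h`, mm.
#' @param h Height of the measurement plane above the detector, mm.
#' @param sid Source-to-image-detector distance, mm.
#' @return Distance(s) at the detector plane, mm.
#' @examples
#' project_to_plane(11.2, h = 25, sid = 661.2)  # 11.64 mm
#' @export
project_to_plane <- function(distance, h, sid) {
  if (!is.numeric(h) || !is.numeric(sid) || h < 0 || sid <= 0 || h >= sid)
    stop(errorCondition("need 0 <= h < sid",
                        class = c("slitfov_geometry_error", "error", "condition")))
  distance * sid / (sid - h)
}
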