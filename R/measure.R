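# End-to-end field measurement: image -> profile -> edge fit -> boundary.

#' Field measurement record
#'
#' @param view View label, e.g. `"Mammo., 24 x 29"` or `"DBT proj., +7.5"`.
#' @param x_edge Fluorescence edge position in the image, mm.
#' @param x_fov Field boundary position, mm (negative = beyond detector).
#' @param side Detector side measured.
#' @param fit Optional [fit_edge()] result.
#' @param profile Optional `line_profile` used for the fit.
#' @return An object of class `field_measurement`.
#' @export
field_measurement <- function(view, x_edge, x_fov,
                              side = c("chest_wall", "left", "right", "nipple"),
                              fit = NULL, profile = NULL) {
  side <- match.arg(side)
  if (!is.finite(x_edge) && !is.finite(x_fov))
    stop("at least one of `x_edge`, `x_fov` must be finite")
  structure(list(view = view, x_edge = x_edge, x_fov = x_fov, side = side,
                 fit = fit, profile = profile),
            class = "field_measurement")
}

#' @export
print.field_measurement <- function(x, ...) {
  cat(sprintf("<field_measurement> %s (%s side)\n", x$view, x$side))
  cat(sprintf("  x_edge = %.2f mm, X_FOV = %.2f mm%s\n", x$x_edge, x$x_fov,
              if (is.finite(x$x_fov) && x$x_fov < 0) " (beyond detector)" else ""))
  if (!is.null(x$fit))
    cat(sprintf("  edge fit R^2 = %.3f\n", x$fit$r_squared))
  invisible(x)
}

#' Measure the X-ray field boundary from a slit-camera image
#'
#' Runs the full measurement pipeline: ROI integration
#' ([extract_profile()]), mean-filter smoothing ([smooth_profile()]),
#' normalization to the in-camera minimum ([normalize_profile()]), edge
#' localization by linear-fit extrapolation ([fit_edge()]), and conversion
#' of the edge position to the field boundary with the projection relation
#' ([fov_boundary()]).
#'
#' @param image A [projection_image()].
#' @param geom The [slit_geometry()] of the acquisition.
#' @param config A [profile_config()].
#' @param view View label stored in the result.
#' @return A [field_measurement()] carrying `x_edge`, `x_fov`, the edge fit
#'   and the processed profile.
#' @export
measure_field <- function(image, geom, config = profile_config(),
                          view = "unlabelled") {
  stopifnot(inherits(image, "projection_image"),
            inherits(geom, "slit_geometry"),
            inherits(config, "profile_config"))
  prof <- extract_profile(image, config)
  prof <- smooth_profile(prof, config$smooth_width)
  prof <- normalize_profile(prof, config$camera_window)
  fit <- fit_edge(prof, config)
  field_measurement(view = view, x_edge = fit$x_edge,
                    x_fov = fov_boundary(geom, fit$x_edge),
                    side = geom$side, fit = fit, profile = prof)
}
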