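# Integrated line profiles: ROI integration, mean-filter smoothing and
# normalization to the minimum intensity inside the camera.

#' Profile-extraction and edge-fit configuration
#'
#' @param roi_width Number of pixels integrated across the profile direction
#'   (along the slit), default 500.
#' @param roi_center Centre of the integration band in pixels across the
#'   profile direction; default the image centre.
#' @param smooth_width Width of the mean filter in pixels (odd, default 5).
#' @param camera_window Position interval in mm defining "inside the camera",
#'   used for the normalization minimum.
#' @param fit_fraction_low,fit_fraction_high Fractional heights of the
#'   plateau-to-baseline drop delimiting the points used for the linear edge
#'   fit (defaults 0.15 and 0.85).
#' @param min_contrast Minimum normalized plateau contrast (plateau - 1)
#'   required before an edge fit is attempted (default 0.05).
#' @param search_direction Direction along increasing position in which the
#'   fluorescence band falls off to baseline: `"increasing"` (edge at larger
#'   positions than the plateau, the usual camera layout) or `"decreasing"`.
#' @return An object of class `profile_config`.
#' @export
profile_config <- function(roi_width = 500, roi_center = NULL,
                           smooth_width = 5, camera_window = c(5, 95),
                           fit_fraction_low = 0.15, fit_fraction_high = 0.85,
                           min_contrast = 0.05,
                           search_direction = c("increasing", "decreasing")) {
  search_direction <- match.arg(search_direction)
  if (roi_width < 1) stop("`roi_width` must be >= 1")
  if (smooth_width < 1 || smooth_width %% 2 == 0)
    stop("`smooth_width` must be odd and >= 1")
  if (!(fit_fraction_low >= 0 && fit_fraction_low < fit_fraction_high &&
        fit_fraction_high <= 1))
    stop("need 0 <= fit_fraction_low < fit_fraction_high <= 1")
  if (length(camera_window) != 2L || camera_window[1] >= camera_window[2])
    stop("`camera_window` must be an increasing mm interval")
  structure(list(roi_width = roi_width, roi_center = roi_center,
                 smooth_width = smooth_width, camera_window = camera_window,
                 fit_fraction_low = fit_fraction_low,
                 fit_fraction_high = fit_fraction_high,
                 min_contrast = min_contrast,
                 search_direction = search_direction),
            class = "profile_config")
}

new_line_profile <- function(position_mm, raw, normalized = NULL,
                             pixel_pitch = NA_real_) {
  o <- order(position_mm)
  structure(list(position_mm = position_mm[o], raw = raw[o],
                 normalized = if (is.null(normalized)) NULL else normalized[o],
                 pixel_pitch = pixel_pitch),
            class = "line_profile")
}

#' Extract an integrated line profile from a projection image
#'
#' Sums `roi_width` pixels across the measurement direction at each position
#' along it, mirroring the region-of-interest integration used to read the
#' faint fluorescence band out of the raw image.  Positions are pixel
#' centres in mm from the detector-side origin defined by the image
#' orientation.
#'
#' @param image A [projection_image()].
#' @param config A [profile_config()].
#' @return An object of class `line_profile` with fields `position_mm` and
#'   `raw` (summed ADU).
#' @export
extract_profile <- function(image, config = profile_config()) {
  stopifnot(inherits(image, "projection_image"),
            inherits(config, "profile_config"))
  px <- image$pixels
  along_cols <- image$orientation %in% c("left", "right")
  n_across <- if (along_cols) nrow(px) else ncol(px)
  n_along <- if (along_cols) ncol(px) else nrow(px)
  center <- config$roi_center %||% ((n_across + 1) / 2)
  half <- (config$roi_width - 1) / 2
  lo <- ceiling(center - half)
  hi <- lo + config$roi_width - 1L
  if (lo < 1 || hi > n_across)
    stop(errorCondition(
      sprintf("ROI rows %d-%d outside image (1-%d)", lo, hi, n_across),
      class = c("slitfov_geometry_error", "error", "condition")))
  raw <- if (along_cols) colSums(px[lo:hi, , drop = FALSE])
         else rowSums(px[, lo:hi, drop = FALSE])
  idx <- seq_len(n_along)
  pos <- switch(image$orientation,
    left = , top = (idx - 0.5) * image$pixel_pitch,
    right = , bottom = (n_along - idx + 0.5) * image$pixel_pitch)
  new_line_profile(pos, raw, pixel_pitch = image$pixel_pitch)
}

#' Smooth a profile with a mean filter
#'
#' Moving mean of odd width; at the array ends the window is truncated (no
#' reflection), so no signal is invented beyond the detector edge.
#'
#' @param profile A `line_profile`.
#' @param width Filter width in samples (odd, default 5).
#' @return The smoothed `line_profile` (positions unchanged).
#' @export
smooth_profile <- function(profile, width = 5) {
  stopifnot(inherits(profile, "line_profile"))
  if (width < 1 || width %% 2 == 0)
    stop(errorCondition("mean-filter width must be odd",
                        class = c("slitfov_config_error", "error", "condition")))
  run <- function(v) {
    n <- length(v)
    half <- (width - 1) / 2
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - half, 1)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  out <- profile
  out$raw <- run(profile$raw)
  if (!is.null(profile$normalized)) out$normalized <- run(profile$normalized)
  out
}

#' Normalize a profile to its minimum inside the camera
#'
#' Divides the profile by its minimum value within the camera window, so the
#' scattered-background baseline inside the camera sits at exactly 1.  This
#' compensates for exposure and incidence-angle differences between views.
#'
#' @param profile A `line_profile`.
#' @param camera_window Position interval (mm) defining "inside the camera".
#' @return The `line_profile` with a `normalized` field (minimum inside the
#'   window equal to 1).
#' @export
normalize_profile <- function(profile, camera_window = c(5, 95)) {
  stopifnot(inherits(profile, "line_profile"))
  inside <- profile$position_mm >= camera_window[1] &
            profile$position_mm <= camera_window[2]
  if (!any(inside))
    stop(errorCondition("camera window does not overlap the profile",
                        class = c("slitfov_config_error", "error", "condition")))
  m <- min(profile$raw[inside])
  if (!is.finite(m) || m <= 0)
    stop(errorCondition("non-positive minimum inside the camera window (dead ROI?)",
                        class = c("slitfov_data_error", "error", "condition")))
  out <- profile
  out$normalized <- profile$raw / m
  out
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %d samples, %.2f-%.2f mm%s\n",
              length(x$position_mm), min(x$position_mm), max(x$position_mm),
              if (is.null(x$normalized)) "" else " (normalized)"))
  invisible(x)
}

#' @export
plot.line_profile <- function(x, ...) {
  y <- if (is.null(x$normalized)) x$raw else x$normalized
  graphics::plot(x$position_mm, y, type = "l",
                 xlab = "position from detector edge [mm]",
                 ylab = if (is.null(x$normalized)) "integrated signal [ADU]"
                        else "normalized signal", ...)
  if (!is.null(x$normalized)) graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Export a profile as CSV
#'
#' @param profile A `line_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "line_profile"))
  df <- data.frame(position_mm = profile$position_mm, raw = profile$raw)
  if (!is.null(profile$normalized)) df$normalized <- profile$normalized
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
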