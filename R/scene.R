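# Synthetic slit-camera scenes with known ground truth.
#
# The renderer reproduces the structure of a raw slit-camera acquisition:
# a 14-bit detector offset, a brighter scattered background outside the
# camera shadow, a reduced background under the brass plates, and the faint
# fluorescence band running from the slit projection up to the projected
# field edge, with a linear flank whose extrapolation foot sits exactly at
# the true edge position.  Pixel noise is Poisson on the expected signal
# above the (deterministic) detector offset.

#' Synthetic scene configuration
#'
#' @param geom A [slit_geometry()].
#' @param x_fov_true Ground-truth field boundary, mm (negative = beyond the
#'   detector).
#' @param image_shape Image size in pixels, `c(rows, cols)`.
#' @param pixel_pitch Pixel pitch in mm (default 0.070).
#' @param plateau Expected ADU level inside the fluorescence band (default 150).
#' @param background Expected ADU level inside the camera shadow without
#'   fluorescence (default 100).
#' @param offset Deterministic detector offset in ADU (default 50).
#' @param bit_depth Detector bit depth (default 14).
#' @param focal_spot Focal-spot size in mm (default 0.35).
#' @param aperture_mm Slit aperture size in mm (default 1).
#' @param y_collimator Height of the beam-defining collimator edge above the
#'   detector, mm; default `y_source - 100`.
#' @param camera_extent Position interval (mm) shadowed by the camera top
#'   plate.
#' @param band_start_mm Position where the fluorescence band begins
#'   (default `x_slit + 2`).
#' @param brass_transmission Ratio of in-camera to open scatter background
#'   (default 0.5; chosen so the in-camera baseline is ~100 ADU when the
#'   open background is ~150 ADU over the 50 ADU offset).
#' @param artifacts List of toggles: `foil_end_step` (transmission step where
#'   the foil ends) and `direct_slit_transmission` (primary beam through the
#'   slit at large DBT angles).
#' @param foil_end_mm,step_adu,slit_bump_adu Artifact geometry/amplitudes.
#' @param orientation Detector-side origin edge of the rendered image.
#' @param seed Integer seed making the render bit-reproducible.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(geom, x_fov_true,
                            image_shape = c(520, 1500),
                            pixel_pitch = 0.070,
                            plateau = 150, background = 100, offset = 50,
                            bit_depth = 14, focal_spot = 0.35,
                            aperture_mm = 1, y_collimator = NULL,
                            camera_extent = c(0, 100), band_start_mm = NULL,
                            brass_transmission = 0.5,
                            artifacts = list(foil_end_step = FALSE,
                                             direct_slit_transmission = FALSE),
                            foil_end_mm = 80, step_adu = 25,
                            slit_bump_adu = 300,
                            orientation = "left", seed = 1L) {
  stopifnot(inherits(geom, "slit_geometry"))
  if (!(plateau > background && background > offset && offset >= 0))
    stop("need plateau > background > offset >= 0")
  if (focal_spot < 0) stop("`focal_spot` must be non-negative")
  if (brass_transmission <= 0 || brass_transmission > 1)
    stop("`brass_transmission` must be in (0, 1]")
  structure(list(
    geom = geom, x_fov_true = x_fov_true, image_shape = image_shape,
    pixel_pitch = pixel_pitch, plateau = plateau, background = background,
    offset = offset, bit_depth = bit_depth, focal_spot = focal_spot,
    aperture_mm = aperture_mm,
    y_collimator = y_collimator %||% (geom$y_source - 100),
    camera_extent = camera_extent,
    band_start_mm = band_start_mm %||% (geom$x_slit + 2),
    brass_transmission = brass_transmission,
    artifacts = utils::modifyList(list(foil_end_step = FALSE,
                                       direct_slit_transmission = FALSE),
                                  artifacts),
    foil_end_mm = foil_end_mm, step_adu = step_adu,
    slit_bump_adu = slit_bump_adu,
    orientation = orientation, seed = as.integer(seed)),
    class = "scenario_config")
}

#' Penumbra width of the projected field edge
#'
#' Geometric blur of the fluorescence edge in the camera image caused by the
#' finite focal spot: the field boundary cast on the foil plane by a
#' collimator edge at height `y_collimator` moves with the source point, and
#' the slit projects that motion onto the detector.  By similar triangles
#' the full width is
#' `focal_spot * (y_c - y_foil)/(y_source - y_c) * y_slit/(y_foil - y_slit)`.
#'
#' @param geom A [slit_geometry()] with `y_foil > y_slit > 0`.
#' @param focal_spot Focal-spot size, mm.
#' @param y_collimator Collimator-edge height above the detector, mm
#'   (default `y_source - 100`).
#' @return Penumbra full width at the detector plane, mm.
#' @export
penumbra_width <- function(geom, focal_spot, y_collimator = NULL) {
  stopifnot(inherits(geom, "slit_geometry"))
  if (focal_spot < 0) stop("`focal_spot` must be non-negative")
  y_c <- y_collimator %||% (geom$y_source - 100)
  if (geom$y_foil <= geom$y_slit || y_c <= geom$y_foil || y_c >= geom$y_source)
    stop(errorCondition("degenerate geometry for penumbra computation",
                        class = c("slitfov_geometry_error", "error", "condition")))
  focal_spot * (y_c - geom$y_foil) / (geom$y_source - y_c) *
    geom$y_slit / (geom$y_foil - geom$y_slit)
}

#' Slit-aperture blur of the projected edge
#'
#' A point on the foil plane is imaged through the finite slit aperture as a
#' band of width `aperture * y_foil / (y_foil - y_slit)` on the detector.
#'
#' @param geom A [slit_geometry()].
#' @param aperture_mm Slit aperture size, mm (default 1).
#' @return Blur full width at the detector plane, mm.
#' @export
slit_blur_width <- function(geom, aperture_mm = 1) {
  stopifnot(inherits(geom, "slit_geometry"))
  if (geom$y_foil <= geom$y_slit)
    stop(errorCondition("degenerate geometry for slit blur computation",
                        class = c("slitfov_geometry_error", "error", "condition")))
  aperture_mm * geom$y_foil / (geom$y_foil - geom$y_slit)
}

# expected-value 1D profile (ADU per pixel) along the measurement axis
scene_expected_profile <- function(config) {
  n_along <- config$image_shape[2]
  pos <- (seq_len(n_along) - 0.5) * config$pixel_pitch
  geom <- config$geom
  x_edge <- invert_fov_boundary(geom, config$x_fov_true)
  w_pen <- penumbra_width(geom, config$focal_spot, config$y_collimator)
  w_slit <- slit_blur_width(geom, config$aperture_mm)
  w <- w_pen + w_slit

  if (x_edge - w <= config$band_start_mm ||
      x_edge > config$camera_extent[2] ||
      x_edge > max(pos))
    stop(errorCondition(
      sprintf("fluorescence band [%.1f, %.1f] mm does not fit the scene",
              config$band_start_mm, x_edge),
      class = c("slitfov_config_error", "error", "condition")))

  inside <- pos >= config$camera_extent[1] & pos <= config$camera_extent[2]
  scatter_open <- (config$background - config$offset) / config$brass_transmission
  e <- config$offset + ifelse(inside, config$background - config$offset,
                              scatter_open)

  # fluorescence band: the falling flank is a single linear ramp of width
  # penumbra + slit blur whose extrapolation foot (signal = baseline) sits
  # exactly at the true edge position
  rise <- pmin(pmax((pos - (config$band_start_mm - 1)) / 1, 0), 1)
  fall <- pmin(pmax((x_edge - pos) / w, 0), 1)
  band <- pmin(rise, fall)
  amp <- config$plateau - config$background
  e <- e + amp * band * inside

  if (isTRUE(config$artifacts$foil_end_step))
    e <- e + config$step_adu * (pos >= config$foil_end_mm) * inside
  if (isTRUE(config$artifacts$direct_slit_transmission))
    e <- e + config$slit_bump_adu *
      exp(-0.5 * ((pos - geom$x_slit) / 1)^2) * inside

  pmin(pmax(e, 0), 2^config$bit_depth - 1)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Expected-value image of a scenario (noise-free path)
#'
#' @param config A [scenario_config()].
#' @return A `projection_image` holding the expected ADU values.
#' @export
scene_expected <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  e <- scene_expected_profile(config)
  px <- matrix(e, nrow = config$image_shape[1], ncol = config$image_shape[2],
               byrow = TRUE)
  if (config$orientation %in% c("right", "bottom"))
    px <- px[, rev(seq_len(ncol(px))), drop = FALSE]
  if (config$orientation %in% c("top", "bottom")) px <- t(px)
  projection_image(px, pixel_pitch = config$pixel_pitch,
                   bit_depth = config$bit_depth,
                   orientation = config$orientation)
}

#' Render a synthetic slit-camera scene
#'
#' Draws each pixel as `offset + Poisson(expected - offset)`, clipped to the
#' bit depth; the offset is deterministic.  The render is bit-identical for
#' identical configurations (including the seed).
#'
#' @param config A [scenario_config()].
#' @return A list with components `image` (a [projection_image()]) and
#'   `audit` (ground truth: `x_edge_true`, blur widths, expected region
#'   means, seed).
#' @export
render_scene <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  expected <- scene_expected(config)
  lambda <- pmax(expected$pixels - config$offset, 0)
  px <- with_seed(config$seed, {
    matrix(stats::rpois(length(lambda), lambda), nrow = nrow(lambda))
  })
  px <- pmin(config$offset + px, 2^config$bit_depth - 1)
  storage.mode(px) <- "double"
  image <- projection_image(px, pixel_pitch = config$pixel_pitch,
                            bit_depth = config$bit_depth,
                            orientation = config$orientation)
  geom <- config$geom
  audit <- list(
    x_fov_true = config$x_fov_true,
    x_edge_true = invert_fov_boundary(geom, config$x_fov_true),
    penumbra_width = penumbra_width(geom, config$focal_spot, config$y_collimator),
    slit_blur = slit_blur_width(geom, config$aperture_mm),
    region_means = c(offset = config$offset,
                     open_background = config$offset +
                       (config$background - config$offset) / config$brass_transmission,
                     camera_baseline = config$background,
                     fluorescence_band = config$plateau),
    seed = config$seed
  )
  list(image = image, audit = audit)
}

#' Render a set of views as normalized line profiles
#'
#' Renders each scenario and reduces it to a normalized line profile with
#' the shared profile configuration, mirroring multi-view acquisitions
#' (mammography plus DBT projections) processed under a common contract.
#'
#' @param configs List of [scenario_config()] objects (same detector side).
#' @param profile_cfg A [profile_config()] applied to every view.
#' @return A list of normalized `line_profile` objects.
#' @export
render_profile_set <- function(configs, profile_cfg = profile_config()) {
  sides <- vapply(configs, function(c) c$geom$side, "")
  if (length(unique(sides)) != 1L)
    stop(errorCondition("all scenarios must share the same detector side",
                        class = c("slitfov_config_error", "error", "condition")))
  lapply(configs, function(cfg) {
    img <- render_scene(cfg)$image
    prof <- extract_profile(img, profile_cfg)
    prof <- smooth_profile(prof, profile_cfg$smooth_width)
    normalize_profile(prof, profile_cfg$camera_window)
  })
}
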