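# Depth-resolved fluorescence-signal model for foil optimization.
#
# A foil of thickness t is irradiated at normal incidence.  Primary photons
# of energy E are absorbed in the K shell at depth z with probability density
# mu_K(E) exp(-mu_p(E) z); the resulting K-alpha photon must escape downward
# through the remaining t - z of foil and then through the listed path
# materials to reach the scoring region inside the camera.  Integrating over
# depth gives, per primary photon,
#
#   D(t, E) = mu_K(E) * (exp(-mu_f t) - exp(-mu_p(E) t)) / (mu_p(E) - mu_f)
#
# with mu_p the foil total attenuation at E and mu_f at its own K-alpha
# energy.  The expected in-camera energy signal is the spectrum-weighted sum
# of omega_Kalpha * E_Kalpha * D(t, E) * T_path.

#' Fluorescent foil specification
#'
#' @param element Element symbol (must have bundled K-fluorescence data).
#' @param thickness_um Foil thickness in micrometres (> 0).
#' @param density Optional density override in g/cm^3.
#' @return An object of class `foil_spec`.
#' @export
foil_spec <- function(element, thickness_um, density = NULL) {
  el <- element_constants(element)
  if (is.na(el$k_alpha))
    stop(errorCondition(
      sprintf("element '%s' has no bundled K-fluorescence data", element),
      class = c("slitfov_lookup_error", "error", "condition")))
  if (!is.numeric(thickness_um) || length(thickness_um) != 1L || thickness_um <= 0)
    stop("`thickness_um` must be a single positive number")
  structure(list(element = element, thickness_um = thickness_um,
                 density = if (is.null(density)) el$density else density),
            class = "foil_spec")
}

#' Default escape path for the mammography setup
#'
#' The K-alpha photons leaving the foil downward cross the 2.5 mm
#' polycarbonate breast support and the air gap between foil and detector
#' before reaching the scoring region; the slit aperture itself is open, so
#' no brass lies on the escape path.
#'
#' @param air_mm Air gap in millimetres (default 61, foil plane to detector
#'   minus the support plate).
#' @return A list of [filter_layer()] entries.
#' @export
mammo_escape_path <- function(air_mm = 61) {
  list(filter_layer(polycarbonate(), 2500),
       filter_layer(air_material(), air_mm * 1000))
}

path_transmission <- function(path_materials, energy_keV) {
  t <- 1
  for (p in path_materials)
    t <- t * exp(-mu_linear(p$material, energy_keV, "total") * p$thickness_um * 1e-4)
  t
}

depth_factor <- function(mu_p, mu_f, t_cm) {
  # closed-form depth integral; the mu_p == mu_f limit is t exp(-mu t)
  d <- mu_p - mu_f
  ifelse(abs(d) < 1e-9 * pmax(mu_p, mu_f),
         t_cm * exp(-mu_p * t_cm),
         (exp(-mu_f * t_cm) - exp(-mu_p * t_cm)) / d)
}

#' Relative in-camera fluorescence signal of a foil
#'
#' Evaluates the closed-form depth-integrated K-alpha signal model for a
#' foil under a given spectrum: K-shell photoelectric absorption times the
#' K-alpha radiative yield and energy, weighted by the downward escape
#' probability through the foil and the listed path materials.  The result
#' is a relative (dimensionless) signal: homogeneous of degree 1 in the
#' spectrum weights and suitable for comparing thicknesses and materials.
#'
#' @param foil A [foil_spec()].
#' @param spectrum An [xray_spectrum()].
#' @param path_materials List of [filter_layer()] entries between the foil
#'   exit surface and the scoring region (default [mammo_escape_path()]).
#' @return Relative signal (single non-negative number).  Zero when the
#'   spectrum has no support above the foil K-edge or the thickness tends
#'   to zero.
#' @export
fluorescence_signal <- function(foil, spectrum,
                                path_materials = mammo_escape_path()) {
  stopifnot(inherits(foil, "foil_spec"), inherits(spectrum, "xray_spectrum"))
  el <- element_constants(foil$element)
  edge_kev <- el$k_edge / 1000
  kalpha_kev <- el$k_alpha / 1000
  keep <- spectrum$energy_keV >= edge_kev
  if (!any(keep)) return(0)
  e <- spectrum$energy_keV[keep]
  w <- spectrum$fluence[keep]
  t_cm <- foil$thickness_um * 1e-4
  mu_f <- foil$density * mu_over_rho(foil$element, kalpha_kev, "total")
  mu_p <- foil$density * mu_over_rho(foil$element, e, "total")
  mu_k <- k_shell_mu(foil$element, e, density = foil$density)
  t_path <- path_transmission(path_materials, kalpha_kev)
  sum(w * el$k_yield * kalpha_kev * mu_k * depth_factor(mu_p, mu_f, t_cm)) * t_path
}

#' Optimal foil thickness over a grid
#'
#' Evaluates [fluorescence_signal()] over a thickness grid and returns the
#' grid member with the maximum signal (ties broken toward the thinner
#' foil), together with the signal curve normalized to its maximum.
#'
#' @param element Foil element symbol.
#' @param spectrum An [xray_spectrum()].
#' @param grid_um Numeric vector of candidate thicknesses in micrometres.
#' @param path_materials Escape path, as in [fluorescence_signal()].
#' @return An object of class `foil_optimization` with fields `element`,
#'   `grid_um`, `signal` (raw), `signal_norm` (max = 1) and `best_um`.
#' @examples
#' s39 <- xray_spectrum(39, filters = list(filter_layer("Ag", 60)))
#' optimize_thickness("Mo", s39, c(5, 10, 25, 50, 100, 250))
#' @export
optimize_thickness <- function(element, spectrum, grid_um,
                               path_materials = mammo_escape_path()) {
  if (!is.numeric(grid_um) || !length(grid_um) || any(grid_um <= 0))
    stop(errorCondition("`grid_um` must be a non-empty vector of positive thicknesses",
                        class = c("slitfov_config_error", "error", "condition")))
  grid_um <- sort(grid_um)
  sig <- vapply(grid_um, function(t)
    fluorescence_signal(foil_spec(element, t), spectrum, path_materials), 0)
  best <- grid_um[which.max(sig)]  # which.max takes the first (thinner) tie
  structure(
    list(element = element, grid_um = grid_um, signal = sig,
         signal_norm = if (max(sig) > 0) sig / max(sig) else sig,
         best_um = best, provenance = spectrum$provenance),
    class = "foil_optimization"
  )
}

#' @export
print.foil_optimization <- function(x, ...) {
  cat(sprintf("<foil_optimization> %s under %s\n", x$element, x$provenance))
  cat(sprintf("  best thickness: %g um\n", x$best_um))
  tab <- data.frame(thickness_um = x$grid_um,
                    relative_signal = round(x$signal_norm, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
plot.foil_optimization <- function(x, ...) {
  graphics::plot(x$grid_um, x$signal_norm, type = "b", log = "x",
                 xlab = "foil thickness [um]", ylab = "relative signal (max = 1)",
                 main = sprintf("%s foil, %s", x$element, x$provenance), ...)
  graphics::abline(v = x$best_um, lty = 2)
  invisible(x)
}
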