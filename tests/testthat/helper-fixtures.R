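# Shared fixtures: the prototype camera geometries, the published per-view
# edge positions used as regression inputs, and small builders.

chest_geom <- function() {
  slit_geometry(y_foil = 63.5, y_slit = 31.35, x_slit = 33.0,
                y_source = 661.2, x_source = 23.6, side = "chest_wall")
}

right_geom <- function() {
  slit_geometry(y_foil = 63.5, y_slit = 31.35, x_slit = 50.0,
                y_source = 661.2, x_source = 133.7, side = "right")
}

# measured per-view edge positions and the corresponding published field
# boundaries (mm), chest-wall and right-side camera orientations
table2 <- list(
  chest = data.frame(
    view = c("Mammo., 24 x 29", "DBT -6.4", "DBT -4.3", "DBT -2.1",
             "DBT 0", "DBT +2.1", "DBT +4.3", "DBT +7.5"),
    x_edge = c(69.74, 69.49, 69.37, 69.47, 69.36, 69.31, 69.44, 69.22),
    x_fov = c(-7.68, -7.41, -7.27, -7.38, -7.25, -7.20, -7.35, -7.10)),
  right = data.frame(
    view = c("Mammo., 24 x 29", "Mammo., 18 x 24", "DBT -6.4", "DBT -4.3",
             "DBT -2.1", "DBT 0", "DBT +2.1", "DBT +4.3", "DBT +7.5"),
    x_edge = c(94.14, 67.89, 89.02, 90.01, 92.35, 94.40, 96.21, 98.59, 100.15),
    x_fov = c(-8.97, 20.82, -3.16, -4.28, -6.94, -9.26, -11.32, -14.02, -15.78))
)

# arbitrary tabulated spectrum (e.g. monoenergetic) via the file loader
make_spectrum <- function(energies, weights) {
  f <- tempfile(fileext = ".txt")
  writeLines(sprintf("%.6f %.8f", energies, weights), f)
  on.exit(unlink(f))
  read_spectrum(f)
}

spectrum_39kvp <- function() {
  xray_spectrum(39, target = "W", filters = list(filter_layer("Ag", 60)))
}

spectrum_100kvp <- function() {
  xray_spectrum(100, target = "W", filters = list(filter_layer("Al", 2500)))
}

# independent depth-quadrature oracle for the fluorescence signal:
# trapezoidal integration of mu_K exp(-mu_p z) exp(-mu_f (t - z)) over depth
quadrature_signal <- function(element, thickness_um, spectrum,
                              path = mammo_escape_path(), n_steps = 2000) {
  el <- element_constants(element)
  edge_kev <- el$k_edge / 1000
  kalpha_kev <- el$k_alpha / 1000
  rho <- el$density
  t_cm <- thickness_um * 1e-4
  mu_f <- rho * mu_over_rho(element, kalpha_kev, "total")
  t_path <- 1
  for (p in path)
    t_path <- t_path * exp(-mu_linear(p$material, kalpha_kev, "total") *
                             p$thickness_um * 1e-4)
  z <- seq(0, t_cm, length.out = n_steps + 1)
  total <- 0
  for (i in seq_along(spectrum$energy_keV)) {
    e <- spectrum$energy_keV[i]
    if (e < edge_kev) next
    mu_p <- rho * mu_over_rho(element, e, "total")
    mu_k <- k_shell_mu(element, e)
    integrand <- mu_k * exp(-mu_p * z) * exp(-mu_f * (t_cm - z))
    depth <- sum((integrand[-1] + integrand[-length(integrand)]) / 2) *
      (t_cm / n_steps)
    total <- total + spectrum$fluence[i] * el$k_yield * kalpha_kev * depth
  }
  total * t_path
}

default_scene <- function(x_fov_true = -7.68, seed = 1, ...) {
  scenario_config(chest_geom(), x_fov_true = x_fov_true, seed = seed, ...)
}
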