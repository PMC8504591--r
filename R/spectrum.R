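# X-ray tube spectra: a semi-empirical bremsstrahlung model plus filtration,
# and a loader for externally computed two-column spectra.

new_spectrum <- function(energy_keV, fluence, provenance) {
  if (length(energy_keV) != length(fluence))
    stop("energy and fluence grids must have equal length")
  if (any(fluence < 0) || !any(fluence > 0))
    stop("fluence weights must be non-negative with at least one positive")
  o <- order(energy_keV)
  structure(
    list(energy_keV = energy_keV[o], fluence = fluence[o] / sum(fluence),
         provenance = provenance),
    class = "xray_spectrum"
  )
}

#' Filter layer specification
#'
#' @param mat Material (an [material()] object, element symbol, or preset
#'   name such as `"brass"`).
#' @param thickness_um Thickness in micrometres.
#' @return A list usable in the `filters` argument of [xray_spectrum()].
#' @export
filter_layer <- function(mat, thickness_um) {
  if (!is.numeric(thickness_um) || thickness_um <= 0)
    stop("`thickness_um` must be positive")
  list(material = as_material(mat), thickness_um = thickness_um)
}

#' Generate a filtered tube spectrum
#'
#' Semi-empirical bremsstrahlung model on a 0.5 keV grid: unfiltered fluence
#' proportional to (E_max - E)/E (a Kramers-type shape), attenuated by the
#' listed filter layers and normalized to unit total weight.  Characteristic
#' anode lines are not modelled; the shape is adequate for the
#' spectrum-weighted quantities computed by the fluorescence model, and a
#' measured spectrum can be substituted via [read_spectrum()].
#'
#' @param kvp Tube potential in kV (20-150).
#' @param target Anode element symbol, recorded in the provenance label.
#' @param filters List of [filter_layer()] specifications.
#' @return An object of class `xray_spectrum` with fields `energy_keV`
#'   (bin centres), `fluence` (relative weights summing to 1) and
#'   `provenance`.
#' @examples
#' s <- xray_spectrum(39, filters = list(filter_layer("Ag", 60)))
#' mean_energy(s)
#' @export
xray_spectrum <- function(kvp, target = "W", filters = list()) {
  if (!is.numeric(kvp) || length(kvp) != 1L || kvp < 20 || kvp > 150)
    stop(errorCondition("`kvp` must lie in 20-150 kV",
                        class = c("slitfov_range_error", "error", "condition")))
  # bin centres offset from integer/half-integer energies so that absorption
  # edges in the filter materials are never sampled exactly on an edge row
  e <- seq(1.25, kvp - 1e-9, by = 0.5)
  w <- (kvp - e) / e
  spec <- new_spectrum(e, w, provenance = sprintf("%g kVp %s (generated)", kvp, target))
  for (f in filters) spec <- apply_filtration(spec, f$material, f$thickness_um)
  spec$provenance <- sprintf(
    "%g kVp %s%s (generated)", kvp, target,
    if (length(filters))
      paste0(" + ", paste(vapply(filters, function(f)
        sprintf("%g um %s", f$thickness_um, f$material$name), ""), collapse = " + "))
    else ""
  )
  spec
}

#' Attenuate a spectrum by a filter layer
#'
#' @param spectrum An `xray_spectrum`.
#' @param mat Filter material.
#' @param thickness_um Filter thickness in micrometres.
#' @return The filtered, re-normalized `xray_spectrum`.
#' @export
apply_filtration <- function(spectrum, mat, thickness_um) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  mu <- mu_linear(as_material(mat), spectrum$energy_keV, "total")
  new_spectrum(spectrum$energy_keV,
               spectrum$fluence * exp(-mu * thickness_um * 1e-4),
               spectrum$provenance)
}

#' Fluence-weighted mean energy of a spectrum
#'
#' @param spectrum An `xray_spectrum`.
#' @return Mean energy in keV.
#' @export
mean_energy <- function(spectrum) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  sum(spectrum$energy_keV * spectrum$fluence)
}

#' Read a tabulated spectrum from a text file
#'
#' Two whitespace- or comma-separated columns (energy keV, relative fluence);
#' lines starting with `#` are comments.
#'
#' @param path File path.
#' @return An `xray_spectrum`.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(sprintf("spectrum file not found: %s", path),
                        class = c("slitfov_io_error", "error", "condition")))
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(gsub(",", " ", lines), "[[:space:]]+")
  m <- vapply(parts, function(p) as.numeric(p[1:2]), numeric(2))
  if (any(!is.finite(m)))
    stop(errorCondition(sprintf("malformed spectrum file: %s", path),
                        class = c("slitfov_io_error", "error", "condition")))
  new_spectrum(m[1, ], m[2, ], provenance = sprintf("file:%s", basename(path)))
}

#' Write a spectrum as two-column text
#'
#' @param spectrum An `xray_spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", spectrum$provenance), con)
  writeLines(sprintf("%.6g %.8g", spectrum$energy_keV, spectrum$fluence), con)
  invisible(path)
}

#' @export
print.xray_spectrum <- function(x, ...) {
  cat(sprintf("<xray_spectrum> %s\n", x$provenance))
  cat(sprintf("  %d bins, %.3g-%.3g keV, mean energy %.2f keV\n",
              length(x$energy_keV), min(x$energy_keV), max(x$energy_keV),
              mean_energy(x)))
  invisible(x)
}
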