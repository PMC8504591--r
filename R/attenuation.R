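# Mass attenuation coefficients from the packaged tables (1-150 keV).
#
# The tables ship as plain CSV in inst/extdata with log-log interpolation
# between grid points.  Absorption-edge discontinuities are preserved by
# duplicated grid points just below and just above each edge; interpolation
# never bridges an edge pair (queries falling inside a pair resolve to the
# above-edge branch).

.attenuation_cache <- new.env(parent = emptyenv())

attenuation_table <- function(element) {
  if (is.null(.attenuation_cache$tables)) {
    path <- system.file("extdata", "attenuation_tables.csv", package = "slitfov",
                        mustWork = TRUE)
    raw <- utils::read.csv(path, stringsAsFactors = FALSE)
    .attenuation_cache$tables <- split(raw[-1], raw$element)
  }
  tab <- .attenuation_cache$tables[[element]]
  if (is.null(tab))
    stop(errorCondition(sprintf("no attenuation table for element '%s'", element),
                        class = c("slitfov_lookup_error", "error", "condition")))
  tab
}

# relative grid spacing below which two adjacent rows are treated as an edge pair
.EDGE_PAIR_TOL <- 3e-3

#' Mass attenuation coefficient of a pure element
#'
#' Log-log interpolation of the packaged attenuation tables.  Queries that
#' fall between the duplicated grid points of an absorption edge return the
#' above-edge value, so interpolation never bridges a discontinuity.
#'
#' @param element Element symbol.
#' @param energy Photon energy in keV (vectorized); must lie in 1-150 keV.
#' @param channel `"total"` or `"photoelectric"`.
#' @return Mass attenuation coefficient(s) mu/rho in cm^2/g.
#' @export
mu_over_rho <- function(element, energy, channel = c("total", "photoelectric")) {
  channel <- match.arg(channel)
  tab <- attenuation_table(element)
  if (any(!is.finite(energy)) || any(energy < min(tab$energy_keV)) ||
      any(energy > max(tab$energy_keV)))
    stop(errorCondition(
      sprintf("energy out of table range [%.3g, %.3g] keV",
              min(tab$energy_keV), max(tab$energy_keV)),
      class = c("slitfov_range_error", "error", "condition")))
  val <- if (channel == "total") tab$mu_over_rho_total else tab$mu_over_rho_photoelectric
  e <- tab$energy_keV
  i <- findInterval(energy, e, rightmost.closed = TRUE)
  i[i < 1L] <- 1L
  i[i >= length(e)] <- length(e) - 1L
  lo <- e[i]; hi <- e[i + 1L]
  pairish <- (hi - lo) / hi < .EDGE_PAIR_TOL
  f <- ifelse(pairish, 1, (log(energy) - log(lo)) / (log(hi) - log(lo)))
  exp((1 - f) * log(val[i]) + f * log(val[i + 1L]))
}

#' Linear attenuation coefficient of a material
#'
#' Mixture rule: the mass-weighted sum of the constituent elements'
#' mass attenuation coefficients, times the bulk density.
#'
#' @param mat An [material()] object (or a symbol/preset name coercible to one).
#' @param energy Photon energy in keV (vectorized).
#' @param channel `"total"` or `"photoelectric"`.
#' @return Linear attenuation coefficient(s) in 1/cm.
#' @examples
#' mu_linear(brass(), 17.479, "photoelectric")
#' @export
mu_linear <- function(mat, energy, channel = c("total", "photoelectric")) {
  channel <- match.arg(channel)
  mat <- as_material(mat)
  mr <- rep(0, length(energy))
  for (sym in names(mat$constituents))
    mr <- mr + mat$constituents[[sym]] * mu_over_rho(sym, energy, channel)
  mat$density * mr
}

#' Mean free path in a material
#'
#' @inheritParams mu_linear
#' @return Mean free path(s) in micrometres (1e4 / mu_linear).
#' @examples
#' mean_free_path(brass(), 17.479, "photoelectric")  # ~22 um at the Mo K-alpha
#' @export
mean_free_path <- function(mat, energy, channel = c("total", "photoelectric")) {
  1e4 / mu_linear(mat, energy, channel)
}

#' K-edge jump ratio of an element
#'
#' Ratio of the photoelectric coefficient just above to just below the
#' K-edge, taken from the duplicated edge rows of the packaged table.
#'
#' @param element Element symbol with a tabulated K-edge.
#' @return Dimensionless jump ratio J_K > 1.
#' @export
k_jump_ratio <- function(element) {
  el <- element_constants(element)
  if (is.na(el$k_edge))
    stop(errorCondition(sprintf("element '%s' has no bundled K-edge", element),
                        class = c("slitfov_lookup_error", "error", "condition")))
  edge <- el$k_edge / 1000
  tab <- attenuation_table(element)
  rel <- (tab$energy_keV - edge) / edge
  below <- which(rel < 0 & rel > -5e-3)
  above <- which(rel > 0 & rel < 5e-3)
  if (!length(below) || !length(above))
    stop(sprintf("no edge pair found for '%s' at %.3f keV", element, edge))
  tab$mu_over_rho_photoelectric[above[1L]] /
    tab$mu_over_rho_photoelectric[max(below)]
}

#' K-shell linear photoelectric coefficient
#'
#' Partitions the photoelectric coefficient into its K-shell share using the
#' jump-ratio approximation mu_K = mu_PE * (1 - 1/J_K), where J_K is the
#' K-edge jump ratio.  Returns 0 below the K-edge.
#'
#' @param element Element symbol with a tabulated K-edge.
#' @param energy Photon energy in keV (vectorized).
#' @param density Optional density override in g/cm^3.
#' @return Linear attenuation coefficient(s) in 1/cm.
#' @export
k_shell_mu <- function(element, energy, density = NULL) {
  el <- element_constants(element)
  if (is.na(el$k_edge))
    stop(errorCondition(sprintf("element '%s' has no bundled K-edge", element),
                        class = c("slitfov_lookup_error", "error", "condition")))
  rho <- if (is.null(density)) el$density else density
  edge_kev <- el$k_edge / 1000
  out <- numeric(length(energy))
  above <- energy >= edge_kev
  if (any(above)) {
    share <- 1 - 1 / k_jump_ratio(element)
    out[above] <- rho * mu_over_rho(element, energy[above], "photoelectric") * share
  }
  out
}
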