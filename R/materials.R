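# Material compositions: mixtures of elements by mass fraction with a bulk
# density, for attenuation via the mixture rule.

#' Define a material as a mixture of elements
#'
#' @param constituents Named numeric vector of mass fractions (names are
#'   element symbols).  Must sum to 1 within 1e-9.
#' @param density Bulk density in g/cm^3.
#' @param name Optional label.
#' @return An object of class `xray_material`.
#' @examples
#' material(c(Cu = 0.615, Zn = 0.355, Pb = 0.03), density = 8.5, name = "brass")
#' @export
material <- function(constituents, density, name = NULL) {
  if (is.null(names(constituents)) || any(!nzchar(names(constituents))))
    stop("`constituents` must be a named vector of mass fractions")
  for (sym in names(constituents)) element_constants(sym)  # validates symbols
  if (any(constituents < 0)) stop("mass fractions must be non-negative")
  if (abs(sum(constituents) - 1) > 1e-9)
    stop("mass fractions must sum to 1 (within 1e-9)")
  if (!is.numeric(density) || length(density) != 1L || density <= 0)
    stop("`density` must be a single positive number")
  structure(
    list(constituents = constituents, density = density,
         name = if (is.null(name)) paste(names(constituents), collapse = "-") else name),
    class = "xray_material"
  )
}

#' @export
print.xray_material <- function(x, ...) {
  cat(sprintf("<xray_material> %s (%.4g g/cm^3)\n", x$name, x$density))
  frac <- sprintf("%s %.4g%%", names(x$constituents), 100 * x$constituents)
  cat(" ", paste(frac, collapse = ", "), "\n")
  invisible(x)
}

#' Single-element material
#'
#' @param symbol Element symbol.
#' @param density Optional density override in g/cm^3 (defaults to the
#'   elemental density).
#' @return An `xray_material` with one constituent.
#' @export
pure_element <- function(symbol, density = NULL) {
  el <- element_constants(symbol)
  material(stats::setNames(1, symbol),
           density = if (is.null(density)) el$density else density,
           name = symbol)
}

#' Brass alloy 360 preset
#'
#' The slit-camera plate material: 61.5% Cu, 35.5% Zn, 3% Pb by mass,
#' density 8.5 g/cm^3.
#'
#' @return An `xray_material`.
#' @export
brass <- function() {
  material(c(Cu = 0.615, Zn = 0.355, Pb = 0.03), density = 8.5, name = "brass")
}

#' Polycarbonate preset (breast support plate)
#'
#' Bisphenol-A polycarbonate (C16 H14 O3), density 1.20 g/cm^3.
#'
#' @return An `xray_material`.
#' @export
polycarbonate <- function() {
  # mass fractions from the C16H14O3 repeat unit
  m <- c(H = 14 * 1.008, C = 16 * 12.011, O = 3 * 15.999)
  material(m / sum(m), density = 1.20, name = "polycarbonate")
}

#' Dry air preset
#'
#' @return An `xray_material` (N/O/Ar, density 1.205e-3 g/cm^3 at 20 C).
#' @export
air_material <- function() {
  material(c(N = 0.7553, O = 0.2318, Ar = 0.0129),
           density = 1.205e-3, name = "air")
}

as_material <- function(x) {
  if (inherits(x, "xray_material")) return(x)
  if (is.character(x) && length(x) == 1L) {
    switch(x,
           brass = return(brass()),
           polycarbonate = return(polycarbonate()),
           air = return(air_material()))
    return(pure_element(x))
  }
  stop("cannot interpret material specification")
}
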