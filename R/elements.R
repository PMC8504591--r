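# Atomic constants used by the fluorescence model and attenuation tables.
#
# K-shell data (K-edge, K-alpha energy, total K-alpha radiative yield) are the
# NIST reference values for the candidate foil and filter elements.  The yield
# is the probability, per K-shell vacancy, that a K-alpha photon is emitted
# (fluorescence yield times K-alpha branching, combined).

.element_db <- local({
  db <- data.frame(
    symbol  = c("H", "C", "N", "O", "Al", "Ar", "Cu", "Zn",
                "Zr", "Mo", "Ag", "Sn", "Pb"),
    z       = c(1L, 6L, 7L, 8L, 13L, 18L, 29L, 30L,
                40L, 42L, 47L, 50L, 82L),
    density = c(8.375e-5, 2.267, 1.165e-3, 1.332e-3, 2.699, 1.662e-3,
                8.96, 7.14, 6.51, 10.22, 10.50, 7.31, 11.35),
    k_edge  = c(NA, NA, NA, NA, NA, NA, 8981, 9659,
                17996, 20000, 25516, 29200, 88005),
    k_alpha = c(NA, NA, NA, NA, NA, NA, 8048, NA,
                15775, 17479, 22163, 25271, NA),
    k_yield = c(NA, NA, NA, NA, NA, NA, 0.454, NA,
                0.734, 0.767, 0.831, 0.860, NA),
    stringsAsFactors = FALSE
  )
  rownames(db) <- db$symbol
  db
})

#' Atomic and K-fluorescence constants for an element
#'
#' Returns the constants used throughout the fluorescence model: atomic
#' number, elemental density, K-shell binding energy (K-edge), K-alpha
#' emission energy, and the total radiative yield of the K-alpha emission per
#' K-shell vacancy.  Fluorescence data are available for the candidate foil
#' and filter elements (Cu, Zr, Mo, Ag, Sn); other bundled elements carry
#' only density and atomic number.
#'
#' @param symbol Element symbol, e.g. `"Mo"`.
#' @return A list with components `symbol`, `z` (atomic number), `density`
#'   (g/cm^3), `k_edge` (eV), `k_alpha` (eV) and `k_yield` (dimensionless
#'   fraction in (0, 1]).  `k_edge`, `k_alpha` and `k_yield` are `NA` for
#'   elements without bundled K-fluorescence data.
#' @examples
#' element_constants("Mo")$k_alpha  # 17479 eV
#' @export
element_constants <- function(symbol) {
  if (!is.character(symbol) || length(symbol) != 1L)
    stop("`symbol` must be a single element symbol")
  if (!symbol %in% rownames(.element_db))
    stop(errorCondition(sprintf("unknown element '%s'", symbol),
                        class = c("slitfov_lookup_error", "error", "condition")))
  as.list(.element_db[symbol, ])
}

#' Elements with bundled K-fluorescence constants
#'
#' @return Character vector of element symbols usable as fluorescent foils.
#' @export
fluorescent_elements <- function() {
  db <- .element_db
  db$symbol[!is.na(db$k_alpha)]
}
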