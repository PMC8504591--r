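# Regulatory compliance checks on measured field boundaries.
#
# Rulesets:
#  - CFR:  on every measured side, the field boundary must lie within
#          sid_fraction * SID of the detector edge.
#  - MQSA: the CFR rule, plus the requirement that the beam extends beyond
#          the chest wall edge (x_fov < 0 on the chest_wall side).
#  - EU:   the field must not extend more than eu_limit (default 5 mm)
#          outside the detector on any side.

#' Compliance limits
#'
#' @param sid_fraction Fraction of SID allowed for the field boundary offset
#'   under the CFR/MQSA rules (default 0.02).
#' @param eu_limit Maximum field extension beyond the detector under the EU
#'   guidelines, mm (default 5).
#' @param congruence_sid_fraction Fraction of SID allowed for the summed
#'   light/X-ray field misalignments (default 0.02).
#' @return An object of class `compliance_limits`.
#' @export
compliance_limits <- function(sid_fraction = 0.02, eu_limit = 5.0,
                              congruence_sid_fraction = 0.02) {
  vals <- c(sid_fraction, eu_limit, congruence_sid_fraction)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all limits must be positive")
  structure(list(sid_fraction = sid_fraction, eu_limit = eu_limit,
                 congruence_sid_fraction = congruence_sid_fraction),
            class = "compliance_limits")
}

#' Check measured field boundaries against a ruleset
#'
#' @param measurements A data frame with columns `side` and `x_fov` (mm,
#'   negative = beyond the detector), or a list of [field_measurement()]
#'   objects carrying a `side`.
#' @param sid Source-to-image-detector distance, mm.
#' @param limits A [compliance_limits()].
#' @param ruleset One of `"MQSA"`, `"CFR"`, `"EU"`.
#' @return An object of class `compliance_check`: a data frame of per-side
#'   verdicts (`side`, `x_fov`, `criterion`, `limit_mm`, `pass`) with the
#'   ruleset and computed limits attached as attributes.
#' @examples
#' m <- data.frame(side = "chest_wall", x_fov = -7.68)
#' check_compliance(m, sid = 661.2, ruleset = "MQSA")
#' @export
check_compliance <- function(measurements, sid, limits = compliance_limits(),
                             ruleset = c("MQSA", "CFR", "EU")) {
  ruleset <- match.arg(ruleset)
  if (!is.numeric(sid) || sid <= 0) stop("`sid` must be positive")
  stopifnot(inherits(limits, "compliance_limits"))
  if (is.list(measurements) && !is.data.frame(measurements) &&
      all(vapply(measurements, inherits, TRUE, "field_measurement"))) {
    measurements <- data.frame(
      side = vapply(measurements, function(m) m$side, ""),
      x_fov = vapply(measurements, function(m) m$x_fov, 0))
  }
  if (!is.data.frame(measurements) ||
      !all(c("side", "x_fov") %in% names(measurements)))
    stop(errorCondition("`measurements` needs columns `side` and `x_fov`",
                        class = c("slitfov_config_error", "error", "condition")))
  if (ruleset == "MQSA" && !"chest_wall" %in% measurements$side)
    stop(errorCondition("MQSA ruleset requires a chest_wall measurement",
                        class = c("slitfov_config_error", "error", "condition")))

  sid_limit <- limits$sid_fraction * sid
  rows <- list()
  for (i in seq_len(nrow(measurements))) {
    side <- measurements$side[i]
    xf <- measurements$x_fov[i]
    overhang <- max(-xf, 0)  # mm beyond the detector
    if (ruleset %in% c("MQSA", "CFR")) {
      rows[[length(rows) + 1L]] <- data.frame(
        side = side, x_fov = xf,
        criterion = sprintf("|x_fov| <= %.1f%% SID", 100 * limits$sid_fraction),
        limit_mm = sid_limit, pass = abs(xf) <= sid_limit)
      if (ruleset == "MQSA" && side == "chest_wall")
        rows[[length(rows) + 1L]] <- data.frame(
          side = side, x_fov = xf,
          criterion = "beam extends beyond chest wall edge (x_fov < 0)",
          limit_mm = 0, pass = xf < 0)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        side = side, x_fov = xf,
        criterion = sprintf("overhang <= %.1f mm", limits$eu_limit),
        limit_mm = limits$eu_limit, pass = overhang <= limits$eu_limit)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, ruleset = ruleset, sid = sid, limits = limits,
            class = c("compliance_check", "data.frame"))
}

#' @export
print.compliance_check <- function(x, ...) {
  cat(sprintf("Compliance check (%s ruleset, SID %.1f mm)\n",
              attr(x, "ruleset"), attr(x, "sid")))
  cat("Sign convention: negative x_fov = field extends beyond the detector.\n")
  df <- as.data.frame(x)
  df$verdict <- ifelse(df$pass, "pass", "FAIL")
  print(df[c("side", "x_fov", "criterion", "limit_mm", "verdict")],
        row.names = FALSE)
  cat(if (all(x$pass)) "Overall: PASS\n" else "Overall: FAIL\n")
  invisible(x)
}

#' Light-field marker position
#'
#' @param x_light Light-field edge position, mm (at the marker plane).
#' @param height Height of the marker above the detector plane, mm (0 when
#'   the marker is read directly off the image at the detector plane).
#' @return An object of class `light_marker`.
#' @export
light_marker <- function(x_light, height = 0) {
  if (!is.finite(x_light) || !is.finite(height) || height < 0)
    stop("`x_light` must be finite and `height` non-negative")
  structure(list(x_light = x_light, height = height), class = "light_marker")
}

#' Misalignment between the X-ray field and the light field on one side
#'
#' Markers placed above the detector plane are first scaled to the detector
#' plane with [project_to_plane()].
#'
#' @param x_fov Measured X-ray field boundary, mm at the detector plane.
#' @param marker A [light_marker()].
#' @param sid Source-to-image-detector distance, mm.
#' @return Misalignment in mm (non-negative).
#' @export
light_xray_misalignment <- function(x_fov, marker, sid) {
  stopifnot(inherits(marker, "light_marker"))
  xl <- if (marker$height > 0)
    project_to_plane(marker$x_light, marker$height, sid) else marker$x_light
  abs(x_fov - xl)
}

#' MQSA light/X-ray congruence verdict
#'
#' Sums the per-side misalignments and compares against the congruence
#' fraction of the SID.
#'
#' @param misalignments Numeric vector of per-side misalignments, mm.
#' @param sid Source-to-image-detector distance, mm.
#' @param limits A [compliance_limits()].
#' @return A list with `total_mm`, `limit_mm`, `pass`.
#' @export
congruence_verdict <- function(misalignments, sid, limits = compliance_limits()) {
  stopifnot(inherits(limits, "compliance_limits"))
  total <- sum(abs(misalignments))
  lim <- limits$congruence_sid_fraction * sid
  list(total_mm = total, limit_mm = lim, pass = total <= lim)
}
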