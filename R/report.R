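# QC reports: a per-view measurement table in the style of a collimation
# test record, with differences to a reference view and ruleset verdicts.

#' Assemble a QC report from field measurements
#'
#' Builds a per-view table (view, side, x_edge, x_fov, difference to the
#' reference view) and, when a ruleset is given, attaches the per-side
#' compliance verdicts.  The default reference is the first view whose
#' label contains "mammo" (the full-field mammogram); with no reference the
#' difference column is omitted with a warning.
#'
#' @param measurements List of [field_measurement()] objects.
#' @param sid Source-to-image-detector distance, mm.
#' @param limits A [compliance_limits()].
#' @param ruleset `"MQSA"`, `"CFR"`, `"EU"`, or `NULL` to skip verdicts.
#' @param reference View label of the reference, or `NULL` for the default.
#' @return An object of class `qc_report`.
#' @export
qc_report <- function(measurements, sid, limits = compliance_limits(),
                      ruleset = "MQSA", reference = NULL) {
  if (inherits(measurements, "field_measurement"))
    measurements <- list(measurements)
  if (!length(measurements) ||
      !all(vapply(measurements, inherits, TRUE, "field_measurement")))
    stop(errorCondition("`measurements` must be field_measurement objects",
                        class = c("slitfov_config_error", "error", "condition")))
  tab <- data.frame(
    view = vapply(measurements, function(m) m$view, ""),
    side = vapply(measurements, function(m) m$side, ""),
    x_edge = vapply(measurements, function(m) m$x_edge, 0),
    x_fov = vapply(measurements, function(m) m$x_fov, 0),
    r_squared = vapply(measurements, function(m)
      if (is.null(m$fit)) NA_real_ else m$fit$r_squared, 0),
    stringsAsFactors = FALSE
  )
  ref_idx <- if (!is.null(reference)) {
    match(reference, tab$view)
  } else {
    grep("mammo", tab$view, ignore.case = TRUE)[1]
  }
  if (is.na(ref_idx) || !length(ref_idx)) {
    warning("no reference view identified; difference column omitted")
    ref_view <- NA_character_
  } else {
    ref_view <- tab$view[ref_idx]
    tab$difference_mm <- tab$x_fov - tab$x_fov[ref_idx]
  }
  compliance <- if (!is.null(ruleset))
    check_compliance(tab[c("side", "x_fov")], sid = sid, limits = limits,
                     ruleset = ruleset)
  structure(list(table = tab, reference = ref_view, sid = sid,
                 ruleset = ruleset, compliance = compliance,
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 package_version = as.character(utils::packageVersion("slitfov"))),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Slit-camera X-ray field QC report\n")
  cat(sprintf("SID %.1f mm | reference view: %s\n", x$sid,
              if (is.na(x$reference)) "(none)" else x$reference))
  cat("Distances in mm; negative X_FOV = field boundary beyond the detector.\n\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, 2)
  print(tab, row.names = FALSE)
  if (!is.null(x$compliance)) {
    cat("\n")
    print(x$compliance)
  }
  invisible(x)
}

#' Write a QC report as JSON
#'
#' Numeric fields are written at full precision so that a re-loaded report
#' reproduces them exactly.
#'
#' @param report A [qc_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  out <- list(
    kind = "slitfov_qc_report",
    sid = report$sid,
    reference = report$reference,
    ruleset = report$ruleset,
    created = report$created,
    package_version = report$package_version,
    sign_convention = "negative X_FOV = field boundary beyond the detector",
    table = report$table,
    compliance = if (!is.null(report$compliance))
      as.data.frame(report$compliance)
  )
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns", null = "null", na = "null")
  invisible(path)
}

#' Read a QC report back from JSON
#'
#' @param path JSON file written by [write_report()].
#' @return A `qc_report`.
#' @export
read_report <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(sprintf("report file not found: %s", path),
                        class = c("slitfov_io_error", "error", "condition")))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(raw$kind, "slitfov_qc_report"))
    stop(errorCondition("not a slitfov QC report",
                        class = c("slitfov_io_error", "error", "condition")))
  compliance <- NULL
  if (!is.null(raw$compliance) && length(raw$compliance)) {
    compliance <- as.data.frame(raw$compliance)
    class(compliance) <- c("compliance_check", "data.frame")
    attr(compliance, "ruleset") <- raw$ruleset
    attr(compliance, "sid") <- raw$sid
  }
  structure(list(table = as.data.frame(raw$table),
                 reference = raw$reference, sid = raw$sid,
                 ruleset = raw$ruleset, compliance = compliance,
                 created = raw$created, package_version = raw$package_version),
            class = "qc_report")
}
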