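# Edge localization: ordinary least squares on the steep intensity fall of
# the normalized profile, extrapolated to the baseline value of 1.
#
# The fluorescence band inside the camera sits at a plateau level L_p > 1
# over the normalized baseline of 1.  The fit window collects the contiguous
# samples on the falling flank whose normalized value lies between
# 1 + f_lo (L_p - 1) and 1 + f_hi (L_p - 1); the fitted line solved for
# y = 1 defines the edge position x_edge.

#' Locate the fluorescence edge by linear-fit extrapolation
#'
#' @param profile A normalized `line_profile` (see [normalize_profile()]).
#' @param config A [profile_config()]; `fit_fraction_low`/`high` select the
#'   fractional-height band of the flank used for the fit.
#' @param search_direction Overrides `config$search_direction` when given.
#' @return An object of class `edge_fit` with components `x_edge` (mm),
#'   `slope` (1/mm), `intercept`, `r_squared`, `plateau` (level L_p),
#'   `window` (indices of the fitted samples) and the fitted sample
#'   coordinates.  Supports `print`, `summary`, `coef`, `predict` and
#'   `plot`.
#' @export
fit_edge <- function(profile, config = profile_config(),
                     search_direction = NULL) {
  stopifnot(inherits(profile, "line_profile"))
  if (is.null(profile$normalized))
    stop("profile must be normalized first (see normalize_profile())")
  direction <- search_direction %||% config$search_direction
  # the plateau and flank live inside the camera shadow; the open-field
  # region beyond it is brighter and must not be mistaken for the plateau
  keep <- which(profile$position_mm >= config$camera_window[1] &
                profile$position_mm <= config$camera_window[2])
  if (length(keep) < 3L)
    stop(errorCondition("camera window contains too few samples",
                        class = c("slitfov_data_error", "error", "condition")))
  x <- profile$position_mm[keep]
  v <- profile$normalized[keep]
  ord <- if (direction == "increasing") seq_along(v) else rev(seq_along(v))
  u <- v[ord]

  l_max <- as.numeric(stats::quantile(u, 0.99, names = FALSE))
  if (l_max - 1 < config$min_contrast)
    stop(errorCondition("no fluorescence edge found: profile is flat",
                        class = c("slitfov_noedge_error", "error", "condition")))

  # plateau: longest contiguous run above half the maximum contrast
  above <- u >= 1 + 0.5 * (l_max - 1)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs))
    stop(errorCondition("no fluorescence plateau found",
                        class = c("slitfov_noedge_error", "error", "condition")))
  main <- runs[which.max(r$lengths[runs])]
  plateau_idx <- starts[main]:ends[main]
  l_p <- stats::median(u[plateau_idx])

  # falling flank: walk beyond the plateau run until the signal reaches the
  # lower fractional height (or the profile ends / rises again)
  y_lo <- 1 + config$fit_fraction_low * (l_p - 1)
  y_hi <- 1 + config$fit_fraction_high * (l_p - 1)
  start <- ends[main]
  n <- length(u)
  stop_at <- n
  min_seen <- u[start]
  for (j in seq(start, n)) {
    min_seen <- min(min_seen, u[j])
    if (u[j] <= y_lo) { stop_at <- j; break }
    # a clear rise after descending into the fit band signals an artifact
    # (e.g. transmission step at the foil end), not the edge
    if (min_seen < y_hi && u[j] > min_seen + 0.25 * (l_p - 1)) {
      stop_at <- max(j - 1L, start)
      break
    }
  }
  seg <- start:stop_at
  win_local <- seg[u[seg] >= y_lo & u[seg] <= y_hi]
  if (length(win_local) < 3L)
    stop(errorCondition(
      sprintf("only %d samples in the edge-fit window (need >= 3)", length(win_local)),
      class = c("slitfov_data_error", "error", "condition")))

  win <- keep[ord[win_local]]
  xr <- profile$position_mm[win]; yr <- profile$normalized[win]
  a <- stats::cov(xr, yr) / stats::var(xr)
  b <- mean(yr) - a * mean(xr)
  fitted <- a * xr + b
  ss_res <- sum((yr - fitted)^2)
  ss_tot <- sum((yr - mean(yr))^2)
  r2 <- if (ss_tot > 0) max(0, 1 - ss_res / ss_tot) else 1
  if (a == 0)
    stop(errorCondition("degenerate flank: zero slope",
                        class = c("slitfov_noedge_error", "error", "condition")))
  x_edge <- (1 - b) / a

  structure(list(x_edge = x_edge, slope = a, intercept = b, r_squared = r2,
                 plateau = l_p, window = sort(win),
                 x = xr, y = yr, direction = direction,
                 profile = profile),
            class = "edge_fit")
}

#' @export
print.edge_fit <- function(x, ...) {
  cat(sprintf("<edge_fit> x_edge = %.2f mm (R^2 = %.3f)\n", x$x_edge, x$r_squared))
  invisible(x)
}

#' @export
summary.edge_fit <- function(object, ...) {
  cat(sprintf("Edge fit (%s position direction)\n", object$direction))
  cat(sprintf("  plateau level     : %.3f (normalized)\n", object$plateau))
  cat(sprintf("  fit window        : %d samples, %.2f-%.2f mm\n",
              length(object$window), min(object$x), max(object$x)))
  cat(sprintf("  line              : y = %.4f x + %.4f\n",
              object$slope, object$intercept))
  cat(sprintf("  R^2               : %.4f\n", object$r_squared))
  cat(sprintf("  x_edge (y = 1)    : %.2f mm\n", object$x_edge))
  invisible(object)
}

#' @export
coef.edge_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @export
predict.edge_fit <- function(object, newdata = NULL, ...) {
  pos <- if (is.null(newdata)) object$x else newdata
  object$slope * pos + object$intercept
}

#' @export
residuals.edge_fit <- function(object, ...) {
  object$y - predict(object)
}

#' @export
plot.edge_fit <- function(x, ...) {
  p <- x$profile
  graphics::plot(p$position_mm, p$normalized, type = "l",
                 xlab = "position from detector edge [mm]",
                 ylab = "normalized signal", ...)
  graphics::abline(h = 1, lty = 3)
  graphics::points(x$x, x$y, col = "red", pch = 16, cex = 0.5)
  graphics::abline(a = x$intercept, b = x$slope, col = "red", lty = 2)
  graphics::abline(v = x$x_edge, col = "blue", lty = 2)
  invisible(x)
}
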