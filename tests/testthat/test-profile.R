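# Profile extraction, smoothing, normalization and edge fitting.

flat_image <- function(value = 100, nrow = 520, ncol = 300, pitch = 0.07,
                       orientation = "left") {
  projection_image(matrix(value, nrow, ncol), pixel_pitch = pitch,
                   orientation = orientation)
}

# noiseless profile with a plateau and a linear flank reaching baseline
ramp_profile <- function(pitch = 0.02, plateau = 1.5, x_plateau_end = 10,
                         x_foot = 12, x_max = 20) {
  pos <- seq(pitch / 2, x_max, by = pitch)
  v <- ifelse(pos < x_plateau_end, plateau,
              pmax(1, plateau - (plateau - 1) * (pos - x_plateau_end) /
                     (x_foot - x_plateau_end)))
  raw <- v * 1000
  p <- slitfov:::new_line_profile(pos, raw, pixel_pitch = pitch)
  normalize_profile(p, camera_window = c(0, x_max))
}

test_that("a constant image integrates to roi_width times the pixel value", {
  img <- flat_image(7)
  prof <- extract_profile(img, profile_config(roi_width = 500))
  expect_true(all(prof$raw == 500 * 7))
  expect_equal(length(prof$raw), 300)
  expect_equal(prof$position_mm[1], 0.035)
  expect_equal(diff(prof$position_mm)[1], 0.07)
})

test_that("positions scale with the pixel pitch and honour the orientation", {
  img_m <- flat_image(pitch = 0.07)
  img_d <- flat_image(pitch = 0.14)
  pm <- extract_profile(img_m, profile_config())
  pd <- extract_profile(img_d, profile_config())
  expect_equal(pd$position_mm, 2 * pm$position_mm)
  # right-origin images count positions from the other side
  px <- matrix(100, 520, 300)
  px[, 300] <- 200  # hot column at the detector-side origin for "right"
  pr <- extract_profile(projection_image(px, 0.07, orientation = "right"),
                        profile_config())
  expect_equal(pr$position_mm[which.max(pr$raw)], 0.035)
})

test_that("the ROI must fit inside the image", {
  img <- flat_image(nrow = 100)
  expect_error(extract_profile(img, profile_config(roi_width = 500)),
               class = "slitfov_geometry_error")
})

test_that("mean filter spreads an impulse, keeps constants, conserves mass", {
  n <- 51
  raw <- numeric(n); raw[26] <- 1
  p <- slitfov:::new_line_profile(seq_len(n) * 0.1, raw)
  sm <- smooth_profile(p, 5)
  expect_equal(sm$raw[24:28], rep(0.2, 5))
  expect_equal(sum(sm$raw), 1)            # interior-supported: mass conserved
  const <- smooth_profile(slitfov:::new_line_profile(seq_len(n), rep(3, n)), 5)
  expect_equal(const$raw, rep(3, n))
  expect_error(smooth_profile(p, 4), class = "slitfov_config_error")
})

test_that("truncated end windows do not invent signal beyond the array", {
  raw <- c(10, rep(0, 20))
  p <- slitfov:::new_line_profile(seq_along(raw), raw)
  sm <- smooth_profile(p, 5)
  expect_equal(sm$raw[1], 10 / 3)  # window truncated to 3 samples at the end
  expect_equal(sm$raw[2], 10 / 4)
})

test_that("normalization pins the in-window minimum at exactly one", {
  set.seed(3)
  raw <- 1000 + 200 * stats::runif(100)
  p <- slitfov:::new_line_profile(seq_len(100) * 0.5, raw)
  np <- normalize_profile(p, camera_window = c(5, 45))
  inside <- np$position_mm >= 5 & np$position_mm <= 45
  expect_identical(min(np$normalized[inside]), 1)
  # scale invariance
  p3 <- slitfov:::new_line_profile(seq_len(100) * 0.5, 3 * raw)
  np3 <- normalize_profile(p3, camera_window = c(5, 45))
  expect_equal(np3$normalized, np$normalized, tolerance = 1e-12)
  # a window excluding the global minimum normalizes to the windowed minimum
  raw2 <- raw; raw2[95] <- 1  # global minimum outside the window
  np2 <- normalize_profile(slitfov:::new_line_profile(seq_len(100) * 0.5, raw2),
                           camera_window = c(5, 45))
  expect_identical(min(np2$normalized[inside]), 1)
  expect_lt(min(np2$normalized), 1)
  expect_error(
    normalize_profile(slitfov:::new_line_profile(1:10, rep(0, 10)), c(1, 10)),
    class = "slitfov_data_error")
})

test_that("a noiseless linear flank is recovered exactly", {
  np <- ramp_profile()
  fit <- fit_edge(np, profile_config(camera_window = c(0, 20)))
  expect_equal(fit$x_edge, 12.0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$plateau, 1.5, tolerance = 1e-9)
  # the fitted line predicts the baseline value at the edge
  expect_equal(unname(predict(fit, newdata = fit$x_edge)), 1, tolerance = 1e-12)
  expect_equal(unname(coef(fit)["slope"]), -0.25, tolerance = 1e-9)
  expect_equal(residuals(fit), rep(0, length(fit$x)), tolerance = 1e-12)
})

test_that("edge fitting works against the position direction as well", {
  np <- ramp_profile()
  # mirror the profile: plateau at high positions, flank falling toward 0
  mirrored <- slitfov:::new_line_profile(20 - np$position_mm, np$raw)
  mirrored <- normalize_profile(mirrored, c(0, 20))
  fit <- fit_edge(mirrored, profile_config(camera_window = c(0, 20),
                                           search_direction = "decreasing"))
  expect_equal(fit$x_edge, 8.0, tolerance = 1e-9)
})

test_that("flat profiles raise a no-edge error and short flanks a data error", {
  flat <- normalize_profile(
    slitfov:::new_line_profile(seq_len(200) * 0.1, rep(500, 200)), c(1, 19))
  expect_error(fit_edge(flat, profile_config(camera_window = c(1, 19))),
               class = "slitfov_noedge_error")
  # flank so steep that fewer than 3 samples land in the fit band
  steep <- ramp_profile(pitch = 1.5)
  expect_error(fit_edge(steep, profile_config(camera_window = c(0, 20))),
               class = "slitfov_data_error")
})

test_that("fit_edge requires a normalized profile", {
  p <- slitfov:::new_line_profile(1:10, rep(1, 10))
  expect_error(fit_edge(p), "normalized")
})
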