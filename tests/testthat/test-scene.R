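# Synthetic scene renderer: determinism, expected means, blur model.

test_that("identical configurations render bit-identical images", {
  cfg <- default_scene(seed = 42)
  a <- render_scene(cfg)$image$pixels
  b <- render_scene(cfg)$image$pixels
  expect_identical(a, b)
  c2 <- render_scene(default_scene(seed = 43))$image$pixels
  expect_false(identical(a, c2))
})

test_that("rendering does not disturb the global RNG stream", {
  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  invisible(render_scene(default_scene(seed = 1)))
  after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("the expected-value image matches the analytic region means", {
  cfg <- default_scene()
  exp_img <- scene_expected(cfg)
  e <- exp_img$pixels
  pos <- (seq_len(ncol(e)) - 0.5) * cfg$pixel_pitch
  # in-camera baseline (between slit projection and band start, and past the
  # edge but inside the camera): exactly `background`
  baseline_cols <- pos > 75 & pos < 95
  expect_true(all(e[, baseline_cols] == cfg$background))
  band_cols <- pos > 40 & pos < 60
  expect_true(all(e[, band_cols] == cfg$plateau))
  open_cols <- pos > 101
  expect_true(all(e[, open_cols] ==
    cfg$offset + (cfg$background - cfg$offset) / cfg$brass_transmission))
})

test_that("rendered region statistics match their expectations", {
  cfg <- default_scene(seed = 5)
  img <- render_scene(cfg)$image
  px <- img$pixels
  pos <- (seq_len(ncol(px)) - 0.5) * cfg$pixel_pitch
  # an (almost) offset-only acquisition: expected counts above the 50 ADU
  # offset are negligible, so the whole-image mean sits at the offset
  cfg0 <- default_scene(seed = 5, background = 50.001, plateau = 50.002,
                        brass_transmission = 1)
  px0 <- render_scene(cfg0)$image$pixels
  expect_gt(length(px0), 1e4)
  expect_equal(mean(px0), 50, tolerance = 0.01)
  # Poisson means: fluorescence band ~150 ADU, baseline ~100 ADU
  expect_equal(mean(px[, pos > 40 & pos < 60]), 150, tolerance = 0.01)
  expect_equal(mean(px[, pos > 75 & pos < 95]), 100, tolerance = 0.01)
  expect_true(all(px <= 2^14 - 1))
  expect_true(all(px >= cfg$offset))
})

test_that("penumbra width is linear in the focal spot and matches ray sampling", {
  g <- chest_geom()
  expect_identical(penumbra_width(g, 0), 0)
  w1 <- penumbra_width(g, 0.35)
  expect_equal(penumbra_width(g, 0.70), 2 * w1, tolerance = 1e-12)

  # ray-sampling oracle: cast the field edge through a collimator point and
  # the slit for many source positions; the 10-90% span of the resulting
  # edge-position distribution is 80% of the box full width
  y_c <- g$y_source - 100
  x_c <- 40  # lateral position of the collimator edge (drops out of the width)
  set.seed(1)
  s_x <- g$x_source + stats::runif(1e4, -0.35 / 2, 0.35 / 2)
  x_foil <- s_x + (x_c - s_x) * (g$y_source - g$y_foil) / (g$y_source - y_c)
  x_det <- g$x_slit + (g$x_slit - x_foil) * g$y_slit / (g$y_foil - g$y_slit)
  span <- diff(stats::quantile(x_det, c(0.1, 0.9), names = FALSE))
  expect_equal(span / 0.8, w1, tolerance = 0.02)
})

test_that("blur widths demand sane geometry", {
  g0 <- slit_geometry(0, 31.35, 33, 661.2, 23.6)
  expect_error(penumbra_width(g0, 0.35), class = "slitfov_geometry_error")
  expect_error(slit_blur_width(g0), class = "slitfov_geometry_error")
  expect_equal(slit_blur_width(chest_geom(), 1), 63.5 / (63.5 - 31.35))
})

test_that("a band that does not fit the scene is rejected", {
  expect_error(render_scene(default_scene(x_fov_true = -60)),
               class = "slitfov_config_error")
})

test_that("views differing only in the true boundary shift the flank accordingly", {
  profs <- render_profile_set(list(default_scene(-7.68, seed = 2),
                                   default_scene(-3.0, seed = 2)))
  f1 <- fit_edge(profs[[1]], profile_config())
  f2 <- fit_edge(profs[[2]], profile_config())
  predicted_shift <- invert_fov_boundary(chest_geom(), -3.0) -
    invert_fov_boundary(chest_geom(), -7.68)
  expect_equal(f2$x_edge - f1$x_edge, predicted_shift, tolerance = 0.15)
})

test_that("the foil-end transmission step appears at its projected position", {
  cfg_step <- default_scene(seed = 9, x_fov_true = -7.68,
                            artifacts = list(foil_end_step = TRUE),
                            foil_end_mm = 80)
  cfg_plain <- default_scene(seed = 9)
  p_step <- render_profile_set(list(cfg_step))[[1]]
  p_plain <- render_profile_set(list(cfg_plain))[[1]]
  after <- p_step$position_mm > 81 & p_step$position_mm < 95
  before <- p_step$position_mm > 72 & p_step$position_mm < 79
  rise_step <- mean(p_step$raw[after]) - mean(p_step$raw[before])
  rise_plain <- mean(p_plain$raw[after]) - mean(p_plain$raw[before])
  expect_gt(rise_step, 500 * 20)   # ~25 ADU x 500 rows
  expect_lt(abs(rise_plain), 500 * 5)
})

test_that("profile sets require a shared detector side", {
  expect_error(render_profile_set(list(
    default_scene(-7.68), scenario_config(right_geom(), -8.97))),
    class = "slitfov_config_error")
})

test_that("the audit ground truth is self-consistent", {
  cfg <- default_scene(-7.68)
  audit <- render_scene(cfg)$audit
  expect_equal(audit$x_edge_true, invert_fov_boundary(chest_geom(), -7.68),
               tolerance = 1e-9)
  expect_equal(unname(audit$region_means["fluorescence_band"]), 150)
  expect_equal(unname(audit$region_means["camera_baseline"]), 100)
})
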