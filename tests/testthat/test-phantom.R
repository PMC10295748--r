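test_that("ground-truth profiles obey the construction identities", {
  spec <- small_spec()
  zs <- seq(1, 5, by = 0.25)
  gt <- ground_truth_profile(spec, zs)
  expect_equal(gt$D1_mm + gt$D2_mm, gt$dS_mm, tolerance = 1e-12)
  expect_true(all(gt$dS_mm <= gt$dL_mm + 1e-12))
  expect_equal(gt$area_ellipse_mm2, pi / 4 * gt$dL_mm * gt$dS_mm)
  expect_error(ground_truth_profile(spec, 0.5), "extent")

  # constant circular 5 mm lumen: the nominal nitinol area everywhere
  spec5 <- small_spec(
    block_diameter_mm = 14,
    stent_profile = stent_profile_linear(4, dL_mm = c(5, 5),
                                         dS_mm = c(5, 5),
                                         twist_deg_per_mm = 0))
  gt5 <- ground_truth_profile(spec5, c(1, 3, 5))
  expect_equal(gt5$area_ellipse_mm2, rep(pi * 25 / 4, 3))
  expect_equal(round_report(gt5$area_ellipse_mm2), rep(19.6, 3))

  # symmetric split and linear twist are reproduced exactly
  spec_sym <- small_spec(
    stent_extent_mm = c(0, 15), n_planes = 76, block_diameter_mm = 12,
    stent_profile = stent_profile_linear(15, dL_mm = c(3, 4),
                                         dS_mm = c(2, 3),
                                         twist_deg_per_mm = 2,
                                         D1_frac = 0.5))
  gt2 <- ground_truth_profile(spec_sym, c(0, 15))
  expect_equal(gt2$D1_mm, gt2$D2_mm)
  expect_equal(gt2$theta_deg[2] - gt2$theta_deg[1], 30)
})

test_that("phantom specs reject inconsistent geometry", {
  expect_error(small_spec(groove_width_mm = c(0.7, 1.6)), "wider")
  expect_error(small_spec(groove_angle_deg = c(0, 180)), "ambiguous")
  expect_error(small_spec(
    stent_profile = stent_profile_linear(4, dL_mm = c(1, 1),
                                         dS_mm = c(2, 2))), "dS <= dL")
  expect_error(small_spec(
    stent_profile = stent_profile_linear(4, D1_frac = 1.2)), "D1_frac")
})

test_that("rendered sections carry the prescribed lumen geometry", {
  # untilted circular 3 mm lumen: rendered cross-section is a 3 mm circle
  spec <- small_spec(
    tilt_deg = 0,
    stent_profile = stent_profile_linear(4, dL_mm = c(3, 3), dS_mm = c(3, 3),
                                         twist_deg_per_mm = 0))
  sec <- render_section(spec, 10)
  lum <- sec$raster > 170
  d_equiv <- 2 * sqrt(sum(lum) / pi) * spec$pixel_size_mm
  expect_lt(abs(d_equiv - 3), spec$pixel_size_mm)

  # orientation check against a second-moment oracle computed here
  spec30 <- small_spec(
    tilt_deg = 0,
    stent_profile = stent_profile_linear(4, dL_mm = c(3.4, 3.4),
                                         dS_mm = c(1.6, 1.6),
                                         theta0_deg = 30,
                                         twist_deg_per_mm = 0))
  lum30 <- render_section(spec30, 10)$raster > 170
  pts <- which(lum30, arr.ind = TRUE)
  ev <- eigen(cov(pts), symmetric = TRUE)$vectors[, 1]
  theta_moment <- (atan2(ev[2], ev[1]) * 180 / pi) %% 180
  expect_lt(theta_dist(theta_moment, 30), 1)

  # outside the stent extent the tube is collapsed: no bright lumen
  sec_out <- render_section(small_spec(), 30)  # z = 5.8 > extent end 5
  expect_equal(sum(sec_out$raster > 170), 0)
  expect_error(render_section(small_spec(), 31), "outside")
})

test_that("phantom bundles are deterministic and faithful to the reference", {
  spec <- small_spec(n_planes = 8)
  b1 <- build_phantom(spec)
  b2 <- build_phantom(spec)
  expect_identical(b1$stack$sections[[3]]$raster, b2$stack$sections[[3]]$raster)
  expect_identical(
    vapply(b1$truth$transforms, `[[`, numeric(1), "rotation_deg"),
    vapply(b2$truth$transforms, `[[`, numeric(1), "rotation_deg"))

  b3 <- build_phantom(small_spec(n_planes = 8, seed = 43))
  expect_false(identical(
    vapply(b1$truth$transforms, `[[`, numeric(1), "tx_px"),
    vapply(b3$truth$transforms, `[[`, numeric(1), "tx_px")))

  # no perturbation and equal spacings: the stack is the slice-wise
  # reference volume
  clean <- small_spec(n_planes = 8, noise_sigma = 0,
                      misalignment = list(translate_px = 0, rotate_deg = 0))
  bc <- build_phantom(clean)
  for (k in c(1, 4, 8))
    expect_equal(bc$stack$sections[[k]]$raster, bc$reference$raster[, , k],
                 tolerance = 1e-12)
})
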