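test_that("lumen segmentation isolates the brightest class and largest component", {
  # bimodal volume: segmentation equals the generating mask exactly
  spec <- small_spec(n_planes = 10, noise_sigma = 0,
                     misalignment = list(translate_px = 0, rotate_deg = 0))
  truth <- phantom_truth_lumen(spec)
  two_level <- truth
  two_level$raster <- ifelse(truth$raster, 200, 80) * 1
  seg <- segment_lumen(two_level)
  expect_identical(seg$raster, truth$raster)

  # a bright speck far from the lumen is removed by the component rule
  speck <- two_level
  speck$raster[2, 2, 1] <- 200
  expect_identical(segment_lumen(speck)$raster, truth$raster)

  # full intensity model with noise: overlap with truth stays >= 0.98
  noisy_spec <- small_spec(n_planes = 20, noise_sigma = 10,
                           misalignment = list(translate_px = 0,
                                               rotate_deg = 0),
                           stent_extent_mm = c(1, 3.5),
                           stent_profile = stent_profile_linear(
                             2.5, dL_mm = c(2.5, 3.2), dS_mm = c(1.5, 2.2)))
  bundle <- build_phantom(noisy_spec)
  seg2 <- segment_lumen(build_volume(bundle$stack, spacing_mm = 0.2))
  tr <- phantom_truth_lumen(noisy_spec)
  dice <- 2 * sum(seg2$raster & tr$raster) /
    (sum(seg2$raster) + sum(tr$raster))
  expect_gte(dice, 0.98)

  dark <- two_level
  dark$raster <- 255 - dark$raster
  expect_identical(segment_lumen(dark, polarity = "dark")$raster,
                   truth$raster)
  empty <- two_level
  empty$raster[] <- 80
  expect_error(segment_lumen(empty), "class|empty")
})

test_that("the stent axis is the principal line of the plane-wise centroids", {
  cyl0 <- tilted_cylinder(r = 1.2, alpha_deg = 0, nx = 101, nz = 60)
  ax0 <- fit_axis(cyl0)
  expect_lt(acos(abs(ax0$direction[3])) * 180 / pi, 0.5)

  cyl15 <- tilted_cylinder(r = 1.2, alpha_deg = 15, nx = 141, nz = 60)
  ax15 <- fit_axis(cyl15)
  expect_lt(abs(asin(sqrt(1 - ax15$direction[3]^2)) * 180 / pi - 15), 1)

  # orientation hint flips the sign exactly
  ax_rev <- fit_axis(cyl15, orientation_hint = c(0, 0, -1))
  expect_equal(ax_rev$direction, -ax15$direction)

  arr <- array(FALSE, c(5, 5, 5))
  arr[2:4, 2:4, 3] <- TRUE
  expect_error(fit_axis(volume(arr, 0.1, 0.2)), "degenerate")
})

test_that("perpendicular sections of a cylinder keep the true diameter", {
  r <- 1.5
  cyl <- tilted_cylinder(r = r, alpha_deg = 0, px = 0.05, dz = 0.2,
                         nx = 101, nz = 51)
  ax <- fit_axis(cyl)
  secs <- extract_cross_sections(cyl, ax, step_mm = 0.5)
  for (cs in secs) {
    ch <- long_diameter(cs)
    expect_lt(abs(ch$length_mm - 2 * r), 2 * cs$pixel_size_mm)
  }
  # section count: floor(L / step) + 1 on the untilted cylinder
  L <- (51 - 1) * 0.2
  expect_equal(length(extract_cross_sections(cyl, ax, step_mm = 0.2)),
               floor(L / 0.2) + 1)
})

test_that("axis-perpendicular extraction undoes the grinding-plane inflation", {
  # the reason for shifting from the block axis to the stent axis: at 20
  # degrees tilt, grinding planes inflate the tilt-direction diameter by
  # 1/cos(tilt) while perpendicular virtual planes keep 2r
  r <- 1.5; alpha <- 20
  cyl <- tilted_cylinder(r = r, alpha_deg = alpha, px = 0.05, dz = 0.1,
                         nx = 161, nz = 120)
  ax <- fit_axis(cyl)
  expect_lt(abs(asin(sqrt(1 - ax$direction[3]^2)) * 180 / pi - alpha), 1)

  perp <- measure_stent(extract_cross_sections(cyl, ax, step_mm = 0.5))
  expect_lt(max(abs(perp$dL_mm - 2 * r)) / (2 * r), 0.02)
  expect_lt((max(perp$area_pixel_mm2) - min(perp$area_pixel_mm2)) /
              mean(perp$area_pixel_mm2), 0.02)

  grind <- measure_stent(grinding_plane_sections(cyl)[20:100])
  inflated <- 2 * r / cos(alpha * pi / 180)
  expect_lt(abs(median(grind$dL_mm) - inflated) / inflated, 0.02)
  expect_gt(median(grind$dL_mm) / median(perp$dL_mm), 1.04)
})
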