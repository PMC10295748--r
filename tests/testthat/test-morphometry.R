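test_that("the longest diameter is the exact point-set diameter", {
  # circle: length right, any orientation
  circ <- ellipse_section(1.5, 1.5, 1.5, 0, px = 0.02)
  ch <- long_diameter(circ)
  expect_lt(abs(ch$length_mm - 3), 2 * 0.02)

  # ellipse with the 5.5 / 1.8 mm diameters: major axis length and angle
  for (th in c(0, 25, 140)) {
    ell <- ellipse_section(2.75, 0.9, 0.9, th, px = 0.02)
    ch <- long_diameter(ell)
    expect_lt(abs(ch$length_mm - 5.5), 0.05)
    expect_lt(theta_dist(ch$theta_deg, th), 1)
  }

  # random blobs: equality with the brute-force pairwise oracle
  set.seed(101)
  for (rep in 1:5) {
    m <- matrix(FALSE, 40, 40)
    seeds <- cbind(sample(10:30, 4), sample(10:30, 4))
    for (i in seq_len(nrow(seeds))) {
      di <- abs(row(m) - seeds[i, 1]) + abs(col(m) - seeds[i, 2])
      m <- m | di <= sample(3:7, 1)
    }
    cs <- cross_section(m, 0.05, 0)
    pts <- (which(m, arr.ind = TRUE) - 0.5) * 0.05
    brute <- max(stats::dist(pts))
    expect_equal(long_diameter(cs)$length_mm, brute, tolerance = 1e-12)
  }
  expect_error(long_diameter(cross_section(matrix(FALSE, 5, 5), 0.05, 0)),
               "empty mask")
})

test_that("the short diameter splits at the long chord into D1 and D2", {
  # symmetric ellipse: equal halves of the 1.8 mm short diameter
  ell <- ellipse_section(2.75, 0.9, 0.9, 0, px = 0.02)
  sh <- short_diameter(ell, long_diameter(ell))
  expect_lt(abs(sh$dS_mm - 1.8), 0.05)
  expect_lt(abs(sh$D1_mm - 0.9), 0.05)
  expect_lt(abs(sh$D2_mm - 0.9), 0.05)
  expect_false(sh$flagged)

  # ellipse truncated on the cartilage side 0.5 mm from the centre
  n <- 2L * round(4 / 0.02) + 1L
  g <- (seq_len(n) - (n + 1) / 2) * 0.02
  X <- matrix(g, n, n); Y <- matrix(g, n, n, byrow = TRUE)
  trunc <- cross_section((X / 2.75)^2 + (Y / 0.9)^2 <= 1 & Y <= 0.5,
                         0.02, 0, cartilage_side = c(0, 1))
  sh2 <- short_diameter(trunc, long_diameter(trunc))
  expect_lt(abs(sh2$D1_mm - 0.5), 0.05)
  expect_lt(abs(sh2$D2_mm - 0.9), 0.05)

  # D1 + D2 = dS holds to machine precision on arbitrary masks
  set.seed(7)
  for (rep in 1:4) {
    m <- matrix(runif(900) > 0.4, 30, 30)
    m[10:20, 10:20] <- TRUE
    cs <- cross_section(m, 0.05, 0)
    sh3 <- short_diameter(cs, long_diameter(cs))
    expect_identical(sh3$D1_mm + sh3$D2_mm, sh3$dS_mm)
  }

  # chord midpoint outside the lumen: flagged, rays cast from the nearest
  # in-mask chord point
  ring <- (X^2 + Y^2 <= 2^2) & (X^2 + Y^2 >= 1.4^2) & Y <= 0
  csr <- cross_section(ring, 0.02, 0)
  shr <- short_diameter(csr, long_diameter(csr))
  expect_true(shr$flagged)
  expect_identical(shr$D1_mm + shr$D2_mm, shr$dS_mm)
})

test_that("elliptical areas reproduce the reported worked examples", {
  expect_equal(round_report(ellipse_area(3.3, 2.2)), 5.7)
  expect_equal(round_report(ellipse_area(1.9, 1.0)), 1.5)
  expect_equal(round_report(ellipse_area(2, 2)), 3.1)
  expect_equal(ellipse_area(2, 2), pi)
  expect_error(ellipse_area(-1, 0.5), "non-negative")
})

test_that("pixel areas equal count times pixel area", {
  circ <- ellipse_section(1.5, 1.5, 1.5, 0, px = 0.01)
  expect_lt(abs(pixel_area(circ) - pi * 1.5^2) / (pi * 1.5^2), 0.01)
  expect_equal(pixel_area(cross_section(matrix(FALSE, 4, 4), 0.05, 0)), 0)
  set.seed(3)
  m <- matrix(runif(400) > 0.5, 20, 20)
  cs <- cross_section(m, 0.07, 0)
  oracle <- 0
  for (i in 1:20) for (j in 1:20) if (m[i, j]) oracle <- oracle + 0.07^2
  expect_equal(pixel_area(cs), oracle)
})

test_that("rotation profiles accumulate minimal rotations and flag swaps", {
  mk_chord <- function(theta) structure(
    list(p1_mm = c(0, 0), p2_mm = c(cos(theta * pi / 180),
                                    sin(theta * pi / 180)),
         length_mm = 1, theta_deg = theta %% 180), class = "chord")

  const <- lapply(rep(12, 6), mk_chord)
  expect_equal(rotation_profile(const)$theta_rel_deg, rep(0, 6))

  # uniform twist totalling 30 degrees
  twist <- lapply(seq(0, 30, length.out = 16), mk_chord)
  rp <- rotation_profile(twist)
  expect_equal(rp$theta_rel_deg[16], 30, tolerance = 1e-9)
  expect_false(any(rp$swap_flag))

  # twist crossing the 0/180 wrap accumulates through it
  wrap <- lapply(seq(170, 200, length.out = 11), mk_chord)
  expect_equal(rotation_profile(wrap)$theta_rel_deg[11], 30,
               tolerance = 1e-9)

  # engineered diameter swap: 90-degree jump plus dL/dS exchange
  thetas <- c(0, 2, 4, 6, 96, 98, 100)
  dLdS <- rbind(matrix(rep(c(4, 2), 4), 4, 2, byrow = TRUE),
                matrix(rep(c(2.1, 3.9), 3), 3, 2, byrow = TRUE))
  chords <- lapply(thetas, mk_chord)
  rps <- rotation_profile(chords, dLdS = dLdS)
  expect_true(rps$swap_flag[5])
  expect_equal(sum(rps$swap_flag), 1)
  # corrected series continues smoothly; uncorrected keeps the 90 jump
  expect_lt(max(abs(diff(rps$theta_rel_deg))), 10)
  expect_gt(max(abs(diff(rps$theta_rel_raw_deg))), 80)
  expect_equal(rps$theta_rel_deg[7], 10, tolerance = 1e-9)

  # a 90-degree step without a diameter swap is a real rotation
  rp90 <- rotation_profile(lapply(c(0, 88), mk_chord),
                           dLdS = rbind(c(4, 2), c(4, 2)))
  expect_false(any(rp90$swap_flag))
  expect_error(rotation_profile(list(mk_chord(0))), "at least 2")
})

test_that("full profiles recover the phantom ground truth", {
  fx <- pipeline_fixture()
  prof <- fx$profile
  gt <- fx$truth
  px2 <- 2 * fx$spec$pixel_size_mm
  tol <- function(truth) pmax(px2, 0.02 * truth)
  expect_true(all(abs(prof$dL_mm - gt$dL_mm) <= tol(gt$dL_mm)))
  expect_true(all(abs(prof$dS_mm - gt$dS_mm) <= tol(gt$dS_mm)))
  expect_true(all(abs(prof$D1_mm - gt$D1_mm) <= tol(gt$D1_mm)))
  expect_true(all(abs(prof$D2_mm - gt$D2_mm) <= tol(gt$D2_mm)))
  expect_true(all(theta_dist(prof$theta_deg, gt$theta_deg) <= 2))
  # injected uniform twist: accumulated rotation matches within 2 degrees
  span <- max(prof$s_mm) - min(prof$s_mm)
  expect_lt(abs(prof$theta_rel_deg[nrow(prof)] - 3 * span), 2)
  expect_equal(prof$D1_mm + prof$D2_mm, prof$dS_mm, tolerance = 1e-12)
  expect_equal(prof$area_ellipse_mm2, pi / 4 * prof$dL_mm * prof$dS_mm)
  expect_error(measure_stent(list()), "empty")
})

test_that("a constant circular lumen yields the flat polymer-like profile", {
  spec <- small_spec(
    tilt_deg = 4, n_planes = 30, stent_extent_mm = c(1, 5),
    stent_profile = stent_profile_linear(4, dL_mm = c(3.5, 3.5),
                                         dS_mm = c(3.5, 3.5),
                                         twist_deg_per_mm = 0))
  lum <- phantom_truth_lumen(spec)
  prof <- measure_stent(extract_cross_sections(lum, fit_axis(lum),
                                               step_mm = 0.25))
  expect_lt(max(abs(prof$area_ellipse_mm2 - nominal_area(3.5))) /
              nominal_area(3.5), 0.02)
  expect_equal(round_report(median(prof$area_ellipse_mm2)), 9.6)
  expect_lt(max(prof$dL_mm - prof$dS_mm), 0.15)
})

test_that("tapered profiles show the monotone threefold area increase", {
  fx <- pipeline_fixture()
  prof <- fx$profile
  ratio <- max(prof$area_ellipse_mm2) / min(prof$area_ellipse_mm2)
  truth_ratio <- max(fx$truth$area_ellipse_mm2) /
    min(fx$truth$area_ellipse_mm2)
  expect_equal(ratio, truth_ratio, tolerance = 0.1)
  expect_gt(ratio, 2.5)
  # smooth monotone growth up to measurement noise
  expect_gt(cor(prof$s_mm, prof$area_ellipse_mm2), 0.99)
})

test_that("rigid in-plane rotation shifts absolute angles, not relative ones", {
  base <- lapply(seq(0, 24, by = 4), function(th)
    ellipse_section(1.6, 0.8, 1.0, th, px = 0.02, half = 3))
  phi <- 25
  rotated <- lapply(base, function(cs) {
    cross_section(
      rigid_apply_image(cs$mask * 1, rigid_transform(phi, 0, 0),
                        interp = "nearest") > 0.5,
      cs$pixel_size_mm, cs$s_mm, cs$cartilage_side)
  })
  p0 <- measure_stent(base)
  p1 <- measure_stent(rotated)
  expect_true(all(theta_dist(p1$theta_deg, p0$theta_deg + phi) < 1))
  expect_equal(p1$theta_rel_deg, p0$theta_rel_deg, tolerance = 0.5)
})
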