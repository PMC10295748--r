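test_that("stent spans follow the signed-distance conventions", {
  # a 13.1 mm stent starting 0.3 mm beyond the isthmus in a 19.6 mm
  # cartilaginous tube ends 6.2 mm short of the pharynx
  prof <- fake_profile(seq(0, 13.0, by = 0.1), step_mm = 0.1)
  lm <- landmarks(isthmus_s_mm = -0.3, pharynx_s_mm = 19.3)
  sp <- stent_span(prof, lm)
  expect_equal(round_report(sp$stent_length_mm), 13.1)
  expect_equal(round_report(sp$dist_isthmus_mm), 0.3)
  expect_equal(round_report(sp$dist_pharynx_mm), 6.2)
  expect_equal(round_report(sp$cartilaginous_length_mm), 19.6)

  # protrusion into the pharyngeal space: negative distance
  prof2 <- fake_profile(seq(0, 15.7, by = 0.1), step_mm = 0.1)
  lm2 <- landmarks(isthmus_s_mm = -5.4, pharynx_s_mm = 12.8)
  sp2 <- stent_span(prof2, lm2)
  expect_equal(round_report(sp2$dist_pharynx_mm), -3)
  expect_equal(round_report(sp2$dist_isthmus_mm), 5.4)

  # exact isthmus-to-pharynx fit: both distances zero
  prof3 <- fake_profile(seq(0, 9.8, by = 0.2))
  sp3 <- stent_span(prof3, landmarks(0, 10))
  expect_equal(sp3$dist_isthmus_mm, 0)
  expect_equal(sp3$dist_pharynx_mm, 0, tolerance = 1e-12)

  expect_error(landmarks(5, 2), "beyond")
  expect_error(span_metrics(10, 1, 2, cartilaginous_length_mm = 20),
               "identity")
})

test_that("the reported span table satisfies the length identity row-wise", {
  tab <- stent_reference_tables()$positions
  expect_equal(nrow(tab), 6)
  for (i in seq_len(nrow(tab))) {
    sp <- span_metrics(tab$length_mm[i], tab$dist_isthmus_mm[i],
                       tab$dist_pharynx_mm[i],
                       cartilaginous_length_mm = tab$cartilaginous_length_mm[i])
    expect_equal(sp$dist_isthmus_mm + sp$stent_length_mm + sp$dist_pharynx_mm,
                 sp$cartilaginous_length_mm, tolerance = 1e-9)
  }
})

test_that("coverage overlap is the interval intersection of the spans", {
  tab <- stent_reference_tables()$positions
  spans <- lapply(seq_len(nrow(tab)), function(i)
    c(tab$dist_isthmus_mm[i], tab$dist_isthmus_mm[i] + tab$length_mm[i]))
  ov <- coverage_overlap(spans)
  # oracle: direct intersection of the six intervals
  oracle <- c(max(vapply(spans, `[`, numeric(1), 1)),
              min(vapply(spans, `[`, numeric(1), 2)))
  expect_equal(ov$interval, oracle)
  expect_equal(round_report(ov$interval), c(5.4, 12.6))
  expect_equal(round_report(ov$length_mm), 7.2)

  expect_equal(coverage_overlap(list(c(0, 2), c(5, 8)))$length_mm, 0)
  same <- coverage_overlap(list(c(1, 4), c(1, 4), c(1, 4)))
  expect_equal(same$interval, c(1, 4))
  # adding a span never enlarges the intersection
  expect_lte(coverage_overlap(c(spans, list(c(0, 20))))$length_mm,
             ov$length_mm)
})

test_that("nominal areas reproduce the three stent families", {
  expect_equal(round_report(nominal_area(5)), 19.6)
  expect_equal(round_report(nominal_area(3)), 7.1)
  expect_equal(round_report(nominal_area(3.5)), 9.6)
  expect_error(nominal_area(0), "positive")
})

test_that("area agreement statistics compare ellipse against measured areas", {
  s <- seq(0, 2, by = 0.2)
  same <- fake_profile(s, area_ellipse = 5 + s, area_pixel = 5 + s)
  ag <- area_agreement(same)
  expect_equal(c(ag$mean_dev_mm2, ag$min_abs_dev_mm2, ag$max_abs_dev_mm2),
               c(0, 0, 0))

  off <- fake_profile(s, area_ellipse = 5 + s + 0.5, area_pixel = 5 + s)
  expect_equal(area_agreement(off)$mean_dev_mm2, 0.5)

  # elliptical phantom lumens: the ellipse approximation stays within 5%
  fx <- pipeline_fixture()
  agp <- area_agreement(fx$profile)
  expect_lt(agp$max_abs_dev_mm2 / mean(fx$profile$area_pixel_mm2), 0.05)
  expect_true(all(abs(fx$profile$area_ellipse_mm2 -
                        fx$profile$area_pixel_mm2) /
                    fx$profile$area_pixel_mm2 < 0.05))
})

test_that("cartilage-side compression yields D1 below D2", {
  fx <- pipeline_fixture()
  expect_lt(mean(fx$profile$D1_mm), mean(fx$profile$D2_mm))
  expect_true(all(fx$profile$D1_mm < fx$profile$D2_mm))
})

test_that("cohort summaries average spans and profiles", {
  tab <- stent_reference_tables()$positions
  spans <- lapply(seq_len(nrow(tab)), function(i)
    span_metrics(tab$length_mm[i], tab$dist_isthmus_mm[i],
                 tab$dist_pharynx_mm[i], tab$cartilaginous_length_mm[i]))
  sm <- summarize_cohort(spans)
  expect_equal(sm$mean_cartilaginous_length_mm, 22.4)

  one <- summarize_cohort(spans[1], list(a = fake_profile(seq(0, 2, 0.2))))
  expect_equal(one$mean_cartilaginous_length_mm,
               round_report(tab$cartilaginous_length_mm[1]))
  expect_equal(one$per_stent$mean_area_mm2, 4.7)
  expect_error(summarize_cohort(list()), "empty")
})

test_that("profile rows are looked up at isthmus-referenced positions", {
  prof <- fake_profile(seq(0, 10, by = 0.2))
  prof$area_ellipse_mm2 <- 3 + 0.5 * prof$s_mm
  lm <- landmarks(isthmus_s_mm = -2, pharynx_s_mm = 18)
  row <- profile_at_position(prof, lm, at_mm = 6)
  expect_equal(row$x_isthmus_mm, 6)
  expect_equal(row$s_mm, 4)
  expect_equal(row$area_ellipse_mm2, 5)
})
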