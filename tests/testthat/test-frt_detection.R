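test_that("running baseline reproduces the worked example's displayed columns", {
  b <- running_baseline(c(12.7, 16.5, 14.7, 18.9, 17.5))
  expect_equal(round(b$mean, 1), 16.1)
  expect_equal(round(b$sd, 2), 2.42)
  b <- running_baseline(c(12.7, 16.5, 14.7, 18.9, 17.5, 21.5, 19.3, 22.1))
  expect_equal(round(b$mean, 1), 17.9)
  expect_equal(round(b$sd, 2), 3.23)
  b <- running_baseline(c(5, 5, 5, 5))
  expect_equal(b$mean, 5)
  expect_equal(b$sd, 0)
  expect_error(running_baseline(12.7), "insufficient baseline")
})

test_that("the provisional scan finds the worked example's bold stages", {
  sc <- scan_provisional(example_series())
  expect_equal(sc$scan$po_watts[sc$pt1], 100)
  expect_equal(sc$scan$po_watts[sc$pt2], 160)
})

test_that("power-output eligibility is strict: the 60 W stage exceeds its gate but cannot trigger", {
  sc <- scan_provisional(example_series())
  row60 <- which(sc$scan$po_watts == 60)
  expect_gt(sc$scan$excess[row60], sc$scan$gate[row60])
  expect_false(sc$scan$eligible[row60])
  expect_false(sc$scan$triggered[row60])
})

test_that("truncating the test after 140 W leaves the second threshold provisional-less", {
  s <- example_series()
  s8 <- stage_series(po = s$po_watts[1:8], hr = s$hr_bpm[1:8],
                     fr = s$fr_brpm[1:8])
  sc <- scan_provisional(s8)
  expect_equal(sc$scan$po_watts[sc$pt1], 100)
  expect_true(is.na(sc$pt2))
  det <- detect_frt(s8)
  expect_equal(det$frt1$status, "undetermined")
  expect_equal(det$frt1$reason, "no-provisional-T2")
})

test_that("noise-free linear breathing frequency never triggers the 2-SD rule", {
  po <- seq(0, 240, 20)
  s <- stage_series(po = po, hr = 90 + 0.4 * po, fr = 14 + 0.015 * po)
  sc <- scan_provisional(s)
  expect_true(is.na(sc$pt1))
  det <- detect_frt(s)
  expect_equal(det$frt1$status, "undetermined")
  expect_equal(det$frt1$reason, "no-provisional-T1")
  expect_equal(det$frt2$status, "undetermined")
})

test_that("segment fits reproduce the worked example's printed coefficients", {
  det <- detect_frt(example_series())
  expect_equal(round(det$lines$RL1$slope, 4), 0.1399)
  expect_equal(round(det$lines$RL1$intercept, 4), 1.9233)
  expect_equal(round(det$lines$RL2$slope, 4), 0.3333)
  expect_equal(round(det$lines$RL2$intercept, 3), -26.179)
  expect_equal(round(det$lines$RL3$slope, 4), 2.3453)
  expect_equal(round(det$lines$RL3$intercept, 2), -361.17)
})

test_that("fit_line equals the closed-form normal-equations solution", {
  set.seed(31)
  for (i in 1:10) {
    hr <- runif(8, 90, 180)
    fr <- runif(8, 12, 60)
    line <- fit_line(hr, fr)
    slope <- sum((hr - mean(hr)) * (fr - mean(fr))) / sum((hr - mean(hr))^2)
    expect_equal(line$slope, slope, tolerance = 1e-10)
    expect_equal(line$intercept, mean(fr) - slope * mean(hr), tolerance = 1e-10)
    expect_equal(line$sse,
                 sum((fr - line$intercept - line$slope * hr)^2),
                 tolerance = 1e-10)
  }
  two <- fit_line(c(100, 120), c(20, 26))
  expect_equal(two$slope, 0.3)
  expect_equal(two$sse, 0)
  expect_error(fit_line(c(100, 100, 100), c(1, 2, 3)), "degenerate")
})

test_that("line intersections recover the worked example's threshold coordinates", {
  det <- detect_frt(example_series())
  expect_equal(round(det$frt1$fr, 1), 22.3)
  expect_equal(round(det$frt2$fr, 1), 29.3)
  # full-precision heart rates from solving the two fitted line pairs
  l <- det$lines
  hr1 <- (l$RL1$intercept - l$RL2$intercept) / (l$RL2$slope - l$RL1$slope)
  expect_equal(det$frt1$hr, hr1, tolerance = 1e-10)
  expect_equal(round(det$frt1$hr, 1), 145.4)
  expect_equal(round(det$frt2$hr, 1), 166.5)
  a <- fit_line(c(1, 2), c(1, 2))
  expect_error(intersect_lines(a, a), "parallel")
})

test_that("both thresholds are determined on the worked example and ordered in heart rate", {
  det <- detect_frt(example_series())
  expect_equal(det$frt1$status, "determined")
  expect_equal(det$frt2$status, "determined")
  expect_lt(det$frt1$hr, det$frt2$hr)
  expect_equal(det$scan$po_watts[det$pt1], 100)
})

test_that("provisional stages are invariant to stages added beyond the second trigger", {
  s <- example_series()
  sc <- scan_provisional(s)
  s_trim <- stage_series(po = s$po_watts[1:10], hr = s$hr_bpm[1:10],
                         fr = s$fr_brpm[1:10])
  sc_trim <- scan_provisional(s_trim)
  expect_equal(sc_trim$pt1, sc$pt1)
  expect_equal(sc_trim$pt2, sc$pt2)
})

test_that("trigger decisions are invariant to shifting and scaling breathing frequency", {
  s <- example_series()
  sc <- scan_provisional(s)
  shifted <- stage_series(po = s$po_watts, hr = s$hr_bpm, fr = s$fr_brpm + 7)
  sc_shift <- scan_provisional(shifted)
  expect_equal(sc_shift$scan$triggered, sc$scan$triggered)
  expect_equal(sc_shift$scan$sd_prev, sc$scan$sd_prev)
  expect_equal(sc_shift$scan$avg_prev, sc$scan$avg_prev + 7)
  scaled <- stage_series(po = s$po_watts, hr = s$hr_bpm, fr = s$fr_brpm * 2.5)
  sc_scale <- scan_provisional(scaled)
  expect_equal(sc_scale$scan$triggered, sc$scan$triggered)
  expect_equal(sc_scale$scan$excess, sc$scan$excess * 2.5)
  expect_equal(sc_scale$scan$gate, sc$scan$gate * 2.5)
})

test_that("threshold mapping inverts exact linear oxygen-uptake relations", {
  s <- linear_series()  # vo2 = 0.5 + 0.01*po, hr = 60 + 0.5*po
  m <- map_threshold(s, hr_t = 140)
  expect_equal(m$vo2, 2.1, tolerance = 1e-10)
  expect_equal(m$po, 160, tolerance = 1e-8)
})

test_that("threshold mapping equals the composition of the two closed-form fits", {
  for (seed in 1:5) {
    s <- random_series(seed)
    hr_t <- runif(1, 100, 170)
    m <- map_threshold(s, hr_t)
    f1 <- fit_line(s$hr_bpm, s$vo2_lmin)
    f2 <- fit_line(s$po_watts, s$vo2_lmin)
    vo2_t <- f1$slope * hr_t + f1$intercept
    expect_equal(m$vo2, vo2_t, tolerance = 1e-10)
    expect_equal(m$po, (vo2_t - f2$intercept) / f2$slope, tolerance = 1e-10)
  }
})

test_that("noisy linear mapping recovers the true power output within sampling error", {
  set.seed(60)
  errs <- replicate(30, {
    po <- seq(0, 260, 20)
    s <- stage_series(po = po, hr = 60 + 0.5 * po, fr = 14 + 0.05 * po,
                      vo2 = 0.5 + 0.01 * po + rnorm(14, 0, 0.05))
    map_threshold(s, hr_t = 140)$po - 160
  })
  expect_lt(abs(median(errs)), 10)
  expect_lt(stats::quantile(abs(errs), 0.9), 25)
})

test_that("mapping is skipped gracefully when oxygen uptake is absent", {
  s <- example_series()  # no vo2 column
  expect_error(map_threshold(s, 140), "mapping skipped")
  det <- detect_frt(s)
  expect_equal(det$frt1$status, "determined")
  expect_true(is.na(det$frt1$vo2))
  expect_true(is.na(det$frt1$po))
})
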