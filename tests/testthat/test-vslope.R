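# hand-built gas series: vo2 linear in po; vco2 piecewise-linear in vo2 with
# a break at stage `b1`; ve piecewise-linear in vco2 with a break at stage
# `b2`; noise added per channel where requested
gas_series <- function(n = 14, vco2_slopes = c(0.95, 1.25), b1 = 6,
                       ve_slopes = c(25, 35), b2 = 10,
                       ve_noise = 0, vco2_noise = 0, seed = NULL,
                       vo2 = NULL) {
  if (!is.null(seed)) set.seed(seed)
  po <- seq(0, by = 20, length.out = n)
  if (is.null(vo2)) vo2 <- 0.5 + 0.011 * po
  ramp <- function(x, xb, s1, s2, y0)
    y0 + s1 * pmin(x - x[1], xb - x[1]) + s2 * pmax(x - xb, 0)
  vco2 <- ramp(vo2, vo2[b1], vco2_slopes[1], vco2_slopes[2], 0.85 * vo2[1])
  ve <- ramp(vco2, vco2[b2], ve_slopes[1], ve_slopes[2], 11)
  stage_series(po = po, hr = 90 + 0.4 * po, fr = 14 + 0.06 * po,
               vo2 = vo2, vco2 = vco2 + rnorm(n, 0, vco2_noise),
               ve = ve + rnorm(n, 0, ve_noise))
}

test_that("the tail filter removes sub-increment stages and the first two stages", {
  vo2 <- 0.5 + 0.011 * seq(0, 260, 20)
  vo2[13] <- vo2[12] + 0.05
  vo2[14] <- vo2[13] + 0.08
  s <- gas_series(vo2 = vo2)
  flt <- filter_for_get2(s)
  expect_equal(length(flt$idx), 10L)
  expect_equal(flt$idx, 3:12)
})

test_that("the tail filter is a no-op on compliant increments", {
  s <- gas_series()
  flt <- filter_for_get2(s)
  expect_equal(flt$idx, 3:14)
})

test_that("tail removal stops at the first compliant increment", {
  # a flat stage in the middle of the tail shields the stages above it only
  # if the last increment itself is compliant
  vo2 <- 0.5 + 0.011 * seq(0, 260, 20)
  vo2[13] <- vo2[12] + 0.05   # non-compliant
  vo2[14] <- vo2[13] + 0.20   # compliant: nothing is removed
  s <- gas_series(vo2 = vo2)
  expect_equal(filter_for_get2(s)$idx, 3:14)
})

test_that("too few surviving points make the second gas threshold undetermined", {
  s <- gas_series(n = 7)  # 5 points after removing the first two stages
  res <- detect_get2(s)
  expect_equal(res$status, "undetermined")
  expect_equal(res$reason, "insufficient-points")
})

test_that("the two-segment fit recovers a noise-free breakpoint exactly", {
  x <- 5:15
  y <- ifelse(x <= 10, x, 10 + 2 * (x - 10))
  fit <- two_segment_best_fit(x, y, min_segment = 3)
  expect_equal(fit$break_x, 10, tolerance = 1e-8)
  expect_equal(fit$lower$slope, 1, tolerance = 1e-10)
  expect_equal(fit$upper$slope, 2, tolerance = 1e-10)
  expect_equal(fit$breakpoint_index, which(x == 10))
})

test_that("collinear points give zero slope change and a null criterion", {
  x <- 1:8
  fit <- two_segment_best_fit(x, 3 + 2 * x, min_segment = 3)
  expect_equal(fit$slope_change, 0, tolerance = 1e-10)
  expect_equal(fit$criterion, 0)
})

test_that("the split search agrees with the exhaustive brute-force oracle", {
  set.seed(505)
  for (i in 1:20) {
    n <- sample(8:30, 1)
    x <- sort(runif(n, 0, 10))
    jb <- sample(seq(3, n - 2), 1)
    y <- ifelse(x <= x[jb], x, x[jb] + runif(1, 1.3, 3) * (x - x[jb])) +
      rnorm(n, 0, 0.3)
    fit <- two_segment_best_fit(x, y, min_segment = 3)
    oracle <- brute_force_split(x, y, min_segment = 3)
    expect_equal(fit$breakpoint_index, oracle$j)
    expect_equal(fit$criterion, oracle$crit, tolerance = 1e-6)
  }
})

test_that("a 40% ventilation slope increase is detected within one stage under noise", {
  truth_b2 <- 10
  hits <- 0; errs <- c()
  for (seed in 1:20) {
    s <- gas_series(ve_noise = 1, seed = seed)
    truth_vco2 <- gas_series()$vco2_lmin[truth_b2]
    dstage <- diff(gas_series()$vco2_lmin[c(truth_b2 - 1, truth_b2 + 1)]) / 2
    res <- detect_get2(s)
    if (res$status == "determined") {
      hits <- hits + 1
      errs <- c(errs, abs(res$provenance$break_vco2 - truth_vco2) / dstage)
    }
  }
  expect_gte(hits, 18)
  expect_lte(median(errs), 1)
})

test_that("a single-slope ventilation relation leaves the second threshold undetermined", {
  s <- gas_series(ve_slopes = c(28, 28))
  res <- detect_get2(s)
  expect_equal(res$status, "undetermined")
  expect_true(res$reason %in% c("slope-change", "no-breakpoint"))
})

test_that("the slope-change rule is strictly greater-than", {
  s <- gas_series(ve_slopes = c(20, 23.5))  # 17.5% increase: accepted
  expect_equal(detect_get2(s)$status, "determined")
  s <- gas_series(ve_slopes = c(20, 22.9))  # 14.5%: rejected
  expect_equal(detect_get2(s)$status, "undetermined")
  # equality is rejected: feed the fitted change back as the rule threshold
  s <- gas_series(ve_slopes = c(20, 24))
  fit <- two_segment_best_fit(filter_for_get2(s)$x, filter_for_get2(s)$y, 3)
  res <- detect_get2(s, min_pct_change = fit$slope_change_pct)
  expect_equal(res$status, "undetermined")
  expect_equal(res$reason, "slope-change")
})

test_that("the first gas threshold is detected from the CO2-vs-O2 slope break", {
  s <- gas_series()
  gets <- detect_gets(s)
  expect_equal(gets$get2$status, "determined")
  expect_equal(gets$get1$status, "determined")
  truth_vo2 <- s$vo2_lmin[6]
  expect_lt(abs(gets$get1$vo2 - truth_vo2), 0.22)
  expect_gt(gets$get1$provenance$fit$slope_change, 0.1)
  expect_lte(gets$get1$vo2, gets$get2$vo2)
})

test_that("a 0.05 slope change leaves the first threshold undetermined", {
  s <- gas_series(vco2_slopes = c(0.95, 1.00))
  res <- detect_get1(s, get2 = detect_get2(s))
  expect_equal(res$status, "undetermined")
  expect_true(res$reason %in% c("slope-change", "no-breakpoint"))
})

test_that("leading stages with a sub-0.6 slope are excluded before fitting", {
  po <- seq(0, 300, 20)
  vo2 <- 0.5 + 0.011 * po
  # CO2 output nearly flat (local slope 0.2) over the first five stages,
  # then 0.95 up to the stage-10 break and 1.25 beyond
  vco2 <- numeric(16)
  vco2[1] <- 0.85 * vo2[1]
  for (i in 2:16) {
    sl <- if (i <= 5) 0.2 else if (i <= 10) 0.95 else 1.25
    vco2[i] <- vco2[i - 1] + sl * (vo2[i] - vo2[i - 1])
  }
  s <- stage_series(po = po, hr = 90 + 0.35 * po, fr = 14 + 0.06 * po,
                    vo2 = vo2, vco2 = vco2,
                    ve = 11 + 26 * (vco2 - vco2[1]))
  res <- detect_get1(s, get2 = NULL)
  expect_equal(res$status, "determined")
  expect_equal(min(res$provenance$idx), 5L)
  expect_true(res$provenance$no_get2_cap)
  expect_lt(abs(res$vo2 - vo2[10]), 0.23)
})

test_that("first-threshold search proceeds uncapped when the second is undetermined", {
  s <- gas_series(ve_slopes = c(28, 28))
  gets <- detect_gets(s)
  expect_equal(gets$get2$status, "undetermined")
  expect_equal(gets$get1$status, "determined")
  expect_true(gets$get1$provenance$no_get2_cap)
})

test_that("first and second gas thresholds stay ordered on simulated subjects", {
  for (seed in 1:15) {
    sim <- generate_series(subject_params(seed = 400 + seed))
    g <- detect_gets(sim$series)
    if (g$get1$status == "determined" && g$get2$status == "determined")
      expect_lte(g$get1$vo2, g$get2$vo2 + 1e-9)
  }
})
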