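#' Exclusion filter for second gas-exchange threshold detection
#'
#' Prepares the ventilation vs CO2-output point cloud for the two-segment
#' search: the first two stages (0 and 20 W, onset hyperventilation) are
#' removed, and trailing stages are removed while the stage-to-stage rise in
#' oxygen uptake stays below 0.120 L/min (the near-plateau at exhaustion,
#' where ventilation decouples from metabolic rate); removal stops at the
#' first compliant increment.
#'
#' @param series a [stage_series] carrying \code{vo2_lmin},
#'   \code{vco2_lmin} and \code{ve_lmin}.
#' @param min_dvo2 minimal stage-to-stage oxygen-uptake increment in L/min
#'   (default 0.120) for a trailing stage to be kept.
#' @return list with \code{idx} (kept row indices into the series),
#'   \code{x} (CO2 output) and \code{y} (ventilation).
#' @export
filter_for_get2 <- function(series, min_dvo2 = 0.120) {
  for (col in c("vo2_lmin", "vco2_lmin", "ve_lmin"))
    if (is.null(series[[col]]))
      stop("missing column: ", col, " is required for GET2 detection")
  n <- nrow(series)
  keep <- seq_len(n)[-(1:2)]
  vo2 <- series$vo2_lmin
  while (length(keep) >= 2L) {
    last <- keep[length(keep)]
    if (vo2[last] - vo2[last - 1L] < min_dvo2)
      keep <- keep[-length(keep)]
    else break
  }
  list(idx = keep, x = series$vco2_lmin[keep], y = series$ve_lmin[keep])
}

#' Two-segment piecewise-linear best fit
#'
#' The breakpoint search at the heart of the V-slope procedure: every
#' admissible split of the points into a lower and an upper limb (the
#' candidate point belongs to both limbs) is fitted by ordinary least
#' squares, and the split retained is the one maximizing the ratio of the
#' perpendicular distance between the two-line intersection and the single
#' regression line through all points, to the mean square error of that
#' single regression. Ties go to the earliest split; near-parallel limbs
#' score zero (their intersection is unusable).
#'
#' @param x,y point coordinates, in scan order along the test.
#' @param min_segment minimum points per limb (default 3; the shared
#'   boundary point counts for both).
#' @return An object of class \code{two_segment_fit}: list with
#'   \code{breakpoint_index} (ordinal of the shared point), \code{break_x},
#'   \code{break_y} (intersection coordinates), \code{lower}, \code{upper},
#'   \code{single} (\code{regression_line}s), \code{criterion},
#'   \code{slope_change} and \code{slope_change_pct}.
#' @export
two_segment_best_fit <- function(x, y, min_segment = 3) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 2L * min_segment)
    stop("insufficient points: need at least ", 2L * min_segment,
         ", got ", n)
  single <- tryCatch(fit_line(x, y, "single"), error = function(e) NULL)
  if (is.null(single)) stop("degenerate fit: x values are all identical")
  mse <- single$sse / (n - 2L)

  best <- NULL
  for (j in min_segment:(n - min_segment + 1L)) {
    lower <- tryCatch(fit_line(x[1:j], y[1:j], "lower"),
                      error = function(e) NULL)
    upper <- tryCatch(fit_line(x[j:n], y[j:n], "upper"),
                      error = function(e) NULL)
    if (is.null(lower) || is.null(upper)) next
    crit <- split_criterion(lower, upper, single, mse, range(x))
    if (is.null(best) || crit$criterion > best$criterion)
      best <- c(list(breakpoint_index = j, lower = lower, upper = upper),
                crit)
  }
  if (is.null(best)) stop("degenerate fit: no admissible split could be fitted")
  sc <- best$upper$slope - best$lower$slope
  structure(list(breakpoint_index = best$breakpoint_index,
                 break_x = best$break_x, break_y = best$break_y,
                 lower = best$lower, upper = best$upper, single = single,
                 criterion = best$criterion, slope_change = sc,
                 slope_change_pct = if (best$lower$slope > 0)
                   100 * sc / best$lower$slope else NA_real_),
            class = "two_segment_fit")
}

# distance-to-MSE criterion for one candidate split; parallel limbs have no
# usable intersection and score 0, as do splits whose fitted intersection
# falls outside the range of the data (a remote crossing of two
# near-parallel limbs is not a physiological breakpoint)
split_criterion <- function(lower, upper, single, mse, xrange, tol = 1e-9) {
  if (abs(upper$slope - lower$slope) < tol)
    return(list(criterion = 0, break_x = NA_real_, break_y = NA_real_))
  bx <- (lower$intercept - upper$intercept) / (upper$slope - lower$slope)
  by <- lower$slope * bx + lower$intercept
  if (bx < xrange[1] || bx > xrange[2])
    return(list(criterion = 0, break_x = bx, break_y = by))
  dist <- abs(single$slope * bx - by + single$intercept) /
    sqrt(1 + single$slope^2)
  crit <- if (mse > 0) dist / mse else if (dist > 0) Inf else 0
  list(criterion = crit, break_x = bx, break_y = by)
}

#' @export
print.two_segment_fit <- function(x, ...) {
  cat(sprintf(
    "Two-segment fit: break at point %d (x = %.4g), slopes %.4f -> %.4f\n",
    x$breakpoint_index, x$break_x, x$lower$slope, x$upper$slope))
  cat(sprintf("  slope change %.4f (%.1f%%), criterion %.4g\n",
              x$slope_change, x$slope_change_pct, x$criterion))
  invisible(x)
}

# linear interpolation of series channels at a break value of `xcol`,
# restricted to the kept rows; clamped at the ends
interp_series_at <- function(series, idx, xcol, x0) {
  xs <- series[[xcol]][idx]
  grab <- function(col) {
    v <- series[[col]]
    if (is.null(v)) return(NA_real_)
    stats::approx(xs, v[idx], xout = x0, rule = 2, ties = mean)$y
  }
  list(fr = grab("fr_brpm"), hr = grab("hr_bpm"),
       vo2 = grab("vo2_lmin"), po = grab("po_watts"))
}

#' Detect the second gas-exchange threshold (V-slope on VE vs VCO2)
#'
#' Applies [filter_for_get2()], runs the two-segment breakpoint search on
#' the ventilation vs CO2-output relation, and accepts the break only when
#' the slope increases by strictly more than \code{min_pct_change} percent
#' from the lower to the upper limb; otherwise the threshold is reported
#' undetermined. The accepted break's CO2-output coordinate is mapped back
#' onto the stage axis: respiratory frequency, heart rate, oxygen uptake and
#' power output at the threshold are linearly interpolated between the two
#' stages bracketing the break.
#'
#' @param series a [stage_series] with \code{vo2_lmin}, \code{vco2_lmin}
#'   and \code{ve_lmin}.
#' @param min_segment minimum points per limb in the breakpoint search.
#' @param min_pct_change acceptance rule: percent slope increase that must
#'   be strictly exceeded (default 15).
#' @return A \code{threshold_result} named "GET2"; its \code{provenance}
#'   carries the accepted \code{two_segment_fit} and the kept row indices.
#' @export
detect_get2 <- function(series, min_segment = 3, min_pct_change = 15) {
  undet <- function(reason)
    threshold_result("GET2", status = "undetermined", reason = reason)
  flt <- tryCatch(filter_for_get2(series), error = function(e) e)
  if (inherits(flt, "error")) return(undet(conditionMessage(flt)))
  if (length(flt$idx) < 2L * min_segment)
    return(undet("insufficient-points"))
  fit <- tryCatch(two_segment_best_fit(flt$x, flt$y, min_segment),
                  error = function(e) NULL)
  if (is.null(fit)) return(undet("degenerate-fit"))
  if (!is.finite(fit$break_x) || fit$criterion <= 0)
    return(undet("no-breakpoint"))
  if (is.na(fit$slope_change_pct) || fit$slope_change_pct <= min_pct_change)
    return(undet("slope-change"))
  at <- interp_series_at(series, flt$idx, "vco2_lmin", fit$break_x)
  summ <- summary(series)
  threshold_result("GET2", fr = at$fr, hr = at$hr, vo2 = at$vo2, po = at$po,
                   hr_pct_max = percent_of_peak(at$hr, summ$hr_max),
                   vo2_pct_peak = if (!is.null(summ$vo2_peak))
                     percent_of_peak(at$vo2, summ$vo2_peak) else NA_real_,
                   lines = list(fit$lower, fit$upper),
                   provenance = list(fit = fit, idx = flt$idx,
                                     break_vco2 = fit$break_x))
}

#' Detect the first gas-exchange threshold (classic V-slope on VCO2 vs VO2)
#'
#' Runs the two-segment breakpoint search on the CO2-output vs oxygen-uptake
#' relation after three exclusions: the first two stages; leading points
#' while the slope of the first \code{min_segment}-point window is below
#' 0.6 (re-checked after each removal); and all points whose oxygen uptake
#' exceeds the second gas-exchange threshold. The break is accepted only
#' when the slope increases by strictly more than \code{min_slope_change}
#' (absolute slope units) from the lower to the upper limb; the accepted
#' break's oxygen-uptake coordinate is the threshold value.
#'
#' When \code{get2} is undetermined the search proceeds without the upper
#' cap and the result is flagged in its provenance (\code{no_get2_cap}).
#'
#' @param series a [stage_series] with \code{vo2_lmin} and
#'   \code{vco2_lmin}.
#' @param get2 the GET2 \code{threshold_result} (from [detect_get2()]) used
#'   to cap the search domain, or NULL.
#' @param min_segment minimum points per limb.
#' @param min_slope_change acceptance rule: absolute slope increase that
#'   must be strictly exceeded (default 0.1).
#' @param min_lead_slope leading points are dropped while the slope of the
#'   first \code{min_segment}-point window is below this (default 0.6).
#' @return A \code{threshold_result} named "GET1".
#' @export
detect_get1 <- function(series, get2 = NULL, min_segment = 3,
                        min_slope_change = 0.1, min_lead_slope = 0.6) {
  undet <- function(reason)
    threshold_result("GET1", status = "undetermined", reason = reason)
  for (col in c("vo2_lmin", "vco2_lmin"))
    if (is.null(series[[col]]))
      return(undet(paste0("missing column: ", col)))
  idx <- seq_len(nrow(series))[-(1:2)]
  no_cap <- is.null(get2) || get2$status != "determined"
  if (!no_cap) idx <- idx[series$vo2_lmin[idx] <= get2$vo2]
  # drop leading points while the local entry slope is sub-metabolic
  while (length(idx) >= min_segment) {
    w <- idx[seq_len(min_segment)]
    sl <- tryCatch(fit_line(series$vo2_lmin[w], series$vco2_lmin[w])$slope,
                   error = function(e) NA_real_)
    if (!is.na(sl) && sl >= min_lead_slope) break
    idx <- idx[-1L]
  }
  if (length(idx) < 2L * min_segment) return(undet("insufficient-points"))
  fit <- tryCatch(two_segment_best_fit(series$vo2_lmin[idx],
                                       series$vco2_lmin[idx], min_segment),
                  error = function(e) NULL)
  if (is.null(fit)) return(undet("degenerate-fit"))
  if (!is.finite(fit$break_x) || fit$criterion <= 0)
    return(undet("no-breakpoint"))
  if (fit$slope_change <= min_slope_change) return(undet("slope-change"))
  at <- interp_series_at(series, idx, "vo2_lmin", fit$break_x)
  summ <- summary(series)
  threshold_result("GET1", fr = at$fr, hr = at$hr, vo2 = fit$break_x,
                   po = at$po,
                   hr_pct_max = percent_of_peak(at$hr, summ$hr_max),
                   vo2_pct_peak = if (!is.null(summ$vo2_peak))
                     percent_of_peak(fit$break_x, summ$vo2_peak) else NA_real_,
                   lines = list(fit$lower, fit$upper),
                   provenance = list(fit = fit, idx = idx,
                                     no_get2_cap = no_cap))
}

#' Detect both gas-exchange thresholds
#'
#' Convenience wrapper running [detect_get2()] first (as the procedure
#' requires, since its result caps the GET1 search domain) and then
#' [detect_get1()].
#'
#' @inheritParams detect_get2
#' @return list with elements \code{get1} and \code{get2}
#'   (\code{threshold_result}s).
#' @export
detect_gets <- function(series, min_segment = 3) {
  get2 <- detect_get2(series, min_segment = min_segment)
  get1 <- detect_get1(series, get2 = get2, min_segment = min_segment)
  list(get1 = get1, get2 = get2)
}
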