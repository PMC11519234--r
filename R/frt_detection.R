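#' Running baseline of respiratory frequency
#'
#' Mean and sample standard deviation (n - 1 denominator) of the respiratory
#' frequencies of all stages preceding the current one, the baseline against
#' which a disproportionate rise in breathing frequency is judged.
#'
#' @param fr_prev respiratory frequencies of stages 0..i-1, in stage order.
#' @return list with \code{mean} and \code{sd}.
#' @export
running_baseline <- function(fr_prev) {
  if (length(fr_prev) < 2L)
    stop("insufficient baseline: at least 2 prior stages are needed for an SD")
  list(mean = mean(fr_prev), sd = stats::sd(fr_prev))
}

#' Scan for provisional respiratory-frequency thresholds
#'
#' Walks the stages in order and, for each stage i >= 1, compares the excess
#' of the stage's respiratory frequency over the running baseline mean
#' (all prior stages, including the unloaded and low-load ones) against a
#' gate of twice the running baseline SD. A stage triggers when the excess
#' strictly exceeds the gate \emph{and} its power output strictly exceeds
#' \code{min_po}: low-load stages feed the baseline but cannot themselves be
#' thresholds, which shields the rule from the spontaneous hyperventilation
#' common at exercise onset. The first trigger is the provisional first
#' threshold, the next trigger after it the provisional second threshold;
#' the baseline definition is unchanged throughout (no reset after the first
#' trigger). All comparisons use full-precision values.
#'
#' @param series a [stage_series] with at least 6 stages.
#' @param min_po eligibility cut in watts (default 60): stages must have
#'   \code{po > min_po} to trigger. For protocols with other increments set
#'   it to the power output of the 4th stage.
#' @return list with \code{scan} (a per-stage data frame with columns
#'   \code{stage}, \code{po_watts}, \code{hr_bpm}, \code{fr_brpm},
#'   \code{avg_prev}, \code{sd_prev}, \code{excess}, \code{gate},
#'   \code{eligible}, \code{triggered}), and \code{pt1}, \code{pt2}: 1-based
#'   row indices into the series of the provisional thresholds (NA when not
#'   found).
#' @export
scan_provisional <- function(series, min_po = 60) {
  n <- nrow(series)
  if (n < 6L)
    stop("insufficient data: the provisional scan needs at least 6 stages")
  fr <- series$fr_brpm
  avg_prev <- sd_prev <- rep(NA_real_, n)
  for (i in 2:n) {
    avg_prev[i] <- mean(fr[1:(i - 1)])
    if (i >= 3L) sd_prev[i] <- stats::sd(fr[1:(i - 1)])
  }
  excess <- fr - avg_prev
  gate <- 2 * sd_prev
  eligible <- series$po_watts > min_po
  triggered <- !is.na(gate) & excess > gate & eligible
  scan <- data.frame(stage = series$stage, po_watts = series$po_watts,
                     hr_bpm = series$hr_bpm, fr_brpm = fr,
                     avg_prev = avg_prev, sd_prev = sd_prev,
                     excess = excess, gate = gate,
                     eligible = eligible, triggered = triggered)
  hits <- which(triggered)
  pt1 <- if (length(hits) >= 1L) hits[1L] else NA_integer_
  pt2 <- if (length(hits) >= 2L) hits[hits > pt1][1L] else NA_integer_
  if (length(hits) >= 2L && is.na(pt2)) pt2 <- NA_integer_
  list(scan = scan, pt1 = pt1, pt2 = pt2)
}

#' Ordinary least-squares line for a threshold segment
#'
#' Fits respiratory frequency (response) on heart rate (predictor) by
#' ordinary least squares. Coefficients are kept at full precision; rounding
#' happens only at display.
#'
#' @param hr predictor values (heart rate, beats/min).
#' @param fr response values (respiratory frequency, breaths/min).
#' @param segment label carried along (e.g. "RL1").
#' @return An object of class \code{regression_line}: list with
#'   \code{slope}, \code{intercept}, \code{n}, \code{sse}, \code{segment}.
#' @export
fit_line <- function(hr, fr, segment = "") {
  if (length(hr) != length(fr)) stop("hr and fr must have equal length")
  if (length(hr) < 2L) stop("degenerate fit: need at least 2 points")
  if (diff(range(hr)) == 0)
    stop("degenerate fit: predictor values are all identical")
  fit <- stats::lm.fit(cbind(1, hr), fr)
  structure(list(slope = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]),
                 n = length(hr), sse = sum(fit$residuals^2),
                 segment = segment),
            class = "regression_line")
}

#' @export
print.regression_line <- function(x, ...) {
  cat(sprintf("%s: y = %.4f * x + %.4f  (n = %d, SSE = %.4g)\n",
              if (nzchar(x$segment)) x$segment else "line",
              x$slope, x$intercept, x$n, x$sse))
  invisible(x)
}

#' Intersection of two fitted lines
#'
#' @param a,b \code{regression_line} objects in the same axes.
#' @param tol slopes closer than this are treated as parallel
#'   (no intersection).
#' @return named numeric vector \code{c(hr, fr)}: the predictor and response
#'   coordinates of the intersection.
#' @export
intersect_lines <- function(a, b, tol = 1e-6) {
  dslope <- b$slope - a$slope
  if (abs(dslope) < tol)
    stop("no intersection: lines are (near-)parallel")
  hr <- (a$intercept - b$intercept) / dslope
  c(hr = hr, fr = a$slope * hr + a$intercept)
}

threshold_result <- function(name, status = "determined", reason = NULL,
                             fr = NA_real_, hr = NA_real_, vo2 = NA_real_,
                             po = NA_real_, hr_pct_max = NA_real_,
                             vo2_pct_peak = NA_real_, lines = NULL,
                             provenance = NULL) {
  structure(list(name = name, status = status, reason = reason,
                 fr = unname(fr), hr = unname(hr), vo2 = unname(vo2),
                 po = unname(po), hr_pct_max = unname(hr_pct_max),
                 vo2_pct_peak = unname(vo2_pct_peak),
                 lines = lines, provenance = provenance),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$status == "determined") {
    cat(sprintf("%s [determined]: fR = %.1f breaths/min, HR = %.0f beats/min",
                x$name, x$fr, x$hr))
    if (!is.na(x$vo2)) cat(sprintf(", VO2 = %.3f L/min", x$vo2))
    if (!is.na(x$po)) cat(sprintf(", PO = %.0f W", x$po))
    cat("\n")
  } else {
    cat(sprintf("%s [undetermined]: %s\n", x$name,
                if (is.null(x$reason)) "unknown reason" else x$reason))
  }
  invisible(x)
}

#' Map a heart-rate threshold to oxygen uptake and power output
#'
#' Oxygen uptake and power output corresponding to a threshold heart rate,
#' obtained from the linear regressions of VO2 on HR and of VO2 on PO over
#' all completed stages: the first regression converts the threshold HR to a
#' VO2, the second is inverted to convert that VO2 to a PO.
#'
#' @param series a [stage_series] with a \code{vo2_lmin} column (>= 3
#'   stages with values).
#' @param hr_t threshold heart rate in beats/min.
#' @return list with \code{vo2} (L/min) and \code{po} (watts).
#' @export
map_threshold <- function(series, hr_t) {
  vo2 <- series$vo2_lmin
  if (is.null(vo2) || sum(!is.na(vo2)) < 3L)
    stop("mapping skipped: vo2_lmin needed for >= 3 stages")
  ok <- !is.na(vo2)
  f_hr <- fit_line(series$hr_bpm[ok], vo2[ok], "VO2~HR")
  f_po <- fit_line(series$po_watts[ok], vo2[ok], "VO2~PO")
  if (f_po$slope <= 0)
    stop("degenerate mapping: VO2 does not increase with power output")
  vo2_t <- f_hr$slope * hr_t + f_hr$intercept
  po_t <- (vo2_t - f_po$intercept) / f_po$slope
  list(vo2 = unname(vo2_t), po = unname(po_t))
}

#' Detect the two respiratory-frequency thresholds
#'
#' Full detection pipeline on the respiratory-frequency vs heart-rate
#' relation of an incremental test: (1) the provisional scan
#' ([scan_provisional()]) marks the two stages at which breathing frequency
#' first rises more than twice the running baseline SD above the baseline
#' mean; (2) three ordinary least-squares segments are fitted, sharing the
#' provisional stages as boundary points — RL1 from the first stage through
#' the first provisional stage, RL2 between the two provisional stages, RL3
#' from the second provisional stage through the last completed stage;
#' (3) the first threshold is the intersection of RL1 and RL2, the second
#' the intersection of RL2 and RL3. When the series carries oxygen-uptake
#' values the threshold heart rates are mapped to VO2 and power output via
#' [map_threshold()].
#'
#' Failures (no provisional trigger, degenerate segment fits, near-parallel
#' lines) are reported as \code{undetermined} statuses with reason codes,
#' never as errors, so cohorts can be processed in batch.
#'
#' @param series a [stage_series].
#' @param min_po eligibility cut in watts for the provisional scan.
#' @param parallel_tol slope-difference tolerance below which two segments
#'   are declared parallel and the intersection undetermined.
#' @return An object of class \code{frt_detection}: list with
#'   \code{frt1}, \code{frt2} (threshold results), \code{scan} (the
#'   provisional-scan table), \code{pt1}, \code{pt2} (provisional row
#'   indices), and \code{lines} (RL1, RL2, RL3 where fitted).
#' @examples
#' s <- stage_series(po = seq(0, 200, 20),
#'                   hr = c(90, 95, 101, 108, 116, 124, 132, 141, 150, 159, 168),
#'                   fr = c(14, 14.5, 15.2, 15.8, 16.5, 17.1, 19.9, 22.8,
#'                          28.5, 36.5, 44.4))
#' detect_frt(s)
#' @export
detect_frt <- function(series, min_po = 60, parallel_tol = 1e-6) {
  undet <- function(name, reason)
    threshold_result(name, status = "undetermined", reason = reason)
  fail_both <- function(reason, scan = NULL, pt1 = NA, pt2 = NA)
    structure(list(frt1 = undet("fRT1", reason), frt2 = undet("fRT2", reason),
                   scan = scan, pt1 = pt1, pt2 = pt2, lines = list()),
              class = "frt_detection")

  sc <- tryCatch(scan_provisional(series, min_po = min_po),
                 error = function(e) e)
  if (inherits(sc, "error")) return(fail_both("insufficient-stages"))
  if (is.na(sc$pt1)) return(fail_both("no-provisional-T1", sc$scan))
  if (is.na(sc$pt2))
    return(structure(list(frt1 = undet("fRT1", "no-provisional-T2"),
                          frt2 = undet("fRT2", "no-provisional-T2"),
                          scan = sc$scan, pt1 = sc$pt1, pt2 = NA_integer_,
                          lines = list()),
                     class = "frt_detection"))

  n <- nrow(series)
  seg <- function(rows, label)
    tryCatch(fit_line(series$hr_bpm[rows], series$fr_brpm[rows], label),
             error = function(e) NULL)
  rl1 <- seg(1:sc$pt1, "RL1")
  rl2 <- seg(sc$pt1:sc$pt2, "RL2")
  rl3 <- seg(sc$pt2:n, "RL3")
  lines <- Filter(Negate(is.null), list(RL1 = rl1, RL2 = rl2, RL3 = rl3))

  summ <- summary(series)
  make_t <- function(name, a, b, prov) {
    if (is.null(a) || is.null(b)) return(undet(name, "degenerate-fit"))
    pt <- tryCatch(intersect_lines(a, b, tol = parallel_tol),
                   error = function(e) NULL)
    if (is.null(pt)) return(undet(name, "parallel-lines"))
    map <- tryCatch(map_threshold(series, pt[["hr"]]),
                    error = function(e) list(vo2 = NA_real_, po = NA_real_))
    vo2_pct <- if (!is.na(map$vo2) && !is.null(summ$vo2_peak))
      percent_of_peak(map$vo2, summ$vo2_peak) else NA_real_
    threshold_result(name, fr = pt[["fr"]], hr = pt[["hr"]],
                     vo2 = map$vo2, po = map$po,
                     hr_pct_max = percent_of_peak(pt[["hr"]], summ$hr_max),
                     vo2_pct_peak = vo2_pct,
                     lines = list(a, b), provenance = prov)
  }
  prov <- list(pt1_stage = series$stage[sc$pt1], pt2_stage = series$stage[sc$pt2])
  structure(list(frt1 = make_t("fRT1", rl1, rl2, prov),
                 frt2 = make_t("fRT2", rl2, rl3, prov),
                 scan = sc$scan, pt1 = sc$pt1, pt2 = sc$pt2, lines = lines),
            class = "frt_detection")
}

#' @export
print.frt_detection <- function(x, ...) {
  cat("Respiratory-frequency threshold detection\n")
  if (!is.na(x$pt1))
    cat("  provisional stages:", x$scan$po_watts[x$pt1], "W",
        if (!is.na(x$pt2)) paste("and", x$scan$po_watts[x$pt2], "W"), "\n")
  for (l in x$lines) print(l)
  print(x$frt1); print(x$frt2)
  invisible(x)
}
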