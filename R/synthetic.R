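#' Parameters of a simulated incremental-test subject
#'
#' Describes one simulated subject of a 1-min, +20 W incremental cycling
#' protocol with known ground-truth thresholds. Heart rate rises linearly
#' with power output; respiratory frequency is piecewise-linear in heart
#' rate with two breakpoints (the embedded first and second
#' respiratory-frequency thresholds); oxygen uptake rises linearly with
#' power output; CO2 output is piecewise-linear in oxygen uptake with its
#' slope increasing at the first threshold (so the respiratory exchange
#' ratio ramps from about 0.85 at rest past 1.1 near exhaustion); and
#' ventilation is piecewise-linear in CO2 output with its slope increasing
#' at the second threshold. The gas-exchange breakpoints are thereby
#' co-located with the respiratory-frequency breakpoints, as both detection
#' families target the same underlying intensity boundaries.
#'
#' Default values portray a middle-aged male of average fitness
#' (W_max 240 W, HR from 90 to about 186 beats/min, thresholds at 71.5%
#' and 83% of peak HR, peak oxygen uptake about 3.1 L/min, peak
#' respiratory frequency about 80 breaths/min).
#'
#' @param w_max maximal workload in watts (multiple of the 20 W increment).
#' @param hr0 heart rate at 0 W, beats/min.
#' @param hr_slope heart-rate rise per watt.
#' @param fr0 respiratory frequency at 0 W, breaths/min.
#' @param fr_slopes three segment slopes of respiratory frequency on heart
#'   rate (breaths/min per beat/min), strictly increasing.
#' @param break_hr the two heart-rate breakpoints, strictly increasing and
#'   inside the test's heart-rate range.
#' @param vo2_0 oxygen uptake at 0 W, L/min.
#' @param vo2_slope oxygen-uptake rise per watt (about 0.010-0.012).
#' @param vco2_slopes two segment slopes of CO2 output on oxygen uptake,
#'   breaking at the first threshold.
#' @param ve_slopes two segment slopes of ventilation on CO2 output
#'   (L/min per L/min), breaking at the second threshold.
#' @param noise_sd named list of per-channel i.i.d. Gaussian noise SDs:
#'   \code{hr}, \code{fr}, \code{vo2}, \code{vco2}, \code{ve}.
#' @param seed optional integer seed fixing this subject's noise draws.
#' @param subject_id label.
#' @return list of class \code{subject_params}.
#' @export
subject_params <- function(w_max = 240, hr0 = 90, hr_slope = 0.4,
                           fr0 = 14, fr_slopes = c(0.06, 0.35, 1.8),
                           break_hr = c(133, 155),
                           vo2_0 = 0.45, vo2_slope = 0.011,
                           vco2_slopes = c(0.92, 1.30),
                           ve_slopes = c(23, 33),
                           noise_sd = list(hr = 2, fr = 0.8, vo2 = 0.035,
                                           vco2 = 0.035, ve = 1.0),
                           seed = NULL, subject_id = "sim") {
  p <- list(w_max = w_max, hr0 = hr0, hr_slope = hr_slope, fr0 = fr0,
            fr_slopes = fr_slopes, break_hr = break_hr, vo2_0 = vo2_0,
            vo2_slope = vo2_slope, vco2_slopes = vco2_slopes,
            ve_slopes = ve_slopes, noise_sd = noise_sd, seed = seed,
            subject_id = subject_id)
  if (length(fr_slopes) != 3L || any(diff(fr_slopes) <= 0))
    stop("parameter error: fr_slopes must be three strictly increasing slopes")
  if (length(break_hr) != 2L || diff(break_hr) <= 0)
    stop("parameter error: break_hr must be two increasing heart rates")
  hr_max <- hr0 + hr_slope * w_max
  if (break_hr[1] <= hr0 || break_hr[2] >= hr_max)
    stop("parameter error: break_hr must lie strictly inside (",
         hr0, ", ", hr_max, ")")
  if (hr_slope <= 0 || vo2_slope <= 0 || w_max < 120)
    stop("parameter error: hr_slope, vo2_slope must be > 0 and w_max >= 120")
  class(p) <- "subject_params"
  p
}

# continuous piecewise-linear ramp in `x` with breakpoints `bx` and one
# slope per piece; anchored at (x0, y0)
piecewise_ramp <- function(x, x0, y0, bx, slopes) {
  knots <- c(x0, bx)
  y <- rep(y0, length(x))
  for (k in seq_along(slopes)) {
    lo <- knots[k]
    hi <- if (k < length(knots)) knots[k + 1L] else Inf
    y <- y + slopes[k] * pmax(0, pmin(x, hi) - lo)
  }
  y
}

#' Simulate one incremental test with known thresholds
#'
#' Builds the stage table of a simulated subject (stages 0 W to W_max in
#' 20 W steps) and returns it together with the embedded ground truth, so
#' detector accuracy can be measured without any real data. Noise is
#' i.i.d. Gaussian per channel per stage; the piecewise structures are built
#' on the noiseless heart rate and oxygen uptake, so the truth is exact.
#'
#' @param params a [subject_params].
#' @return list with \code{series} (a [stage_series]) and \code{truth}:
#'   heart rate, respiratory frequency, oxygen uptake, CO2 output and power
#'   output at the two embedded thresholds, plus \code{hr_increment}, the
#'   heart-rate rise per 20 W stage.
#' @examples
#' sim <- generate_series(subject_params(seed = 1))
#' det <- detect_frt(sim$series)
#' c(detected = det$frt1$hr, truth = sim$truth$frt1_hr)
#' @export
generate_series <- function(params) {
  stopifnot(inherits(params, "subject_params"))
  p <- params
  if (!is.null(p$seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(p$seed)
  }
  po <- seq(0, p$w_max, by = 20)
  n <- length(po)
  ns <- p$noise_sd
  hr_true <- p$hr0 + p$hr_slope * po
  fr_true <- piecewise_ramp(hr_true, p$hr0, p$fr0, p$break_hr, p$fr_slopes)
  vo2_true <- p$vo2_0 + p$vo2_slope * po

  po_b <- (p$break_hr - p$hr0) / p$hr_slope
  vo2_b <- p$vo2_0 + p$vo2_slope * po_b
  # CO2 output vs oxygen uptake: slope break at the first threshold,
  # starting from a resting exchange ratio of 0.85
  vco2_true <- piecewise_ramp(vo2_true, p$vo2_0, 0.85 * p$vo2_0,
                              vo2_b[1], p$vco2_slopes)
  vco2_b2 <- piecewise_ramp(vo2_b[2], p$vo2_0, 0.85 * p$vo2_0,
                            vo2_b[1], p$vco2_slopes)
  # ventilation vs CO2 output: slope break at the second threshold,
  # anchored at a resting ventilation of 12 L/min
  vco2_0 <- 0.85 * p$vo2_0
  ve_true <- piecewise_ramp(vco2_true, vco2_0, 12, vco2_b2, p$ve_slopes)

  series <- stage_series(
    po = po,
    hr = hr_true + stats::rnorm(n, 0, ns$hr),
    fr = pmax(fr_true + stats::rnorm(n, 0, ns$fr), 1),
    vo2 = pmax(vo2_true + stats::rnorm(n, 0, ns$vo2), 0.05),
    vco2 = pmax(vco2_true + stats::rnorm(n, 0, ns$vco2), 0.05),
    ve = pmax(ve_true + stats::rnorm(n, 0, ns$ve), 1),
    subject_id = p$subject_id)
  truth <- list(
    frt1_hr = p$break_hr[1], frt2_hr = p$break_hr[2],
    frt1_fr = piecewise_ramp(p$break_hr[1], p$hr0, p$fr0, p$break_hr,
                             p$fr_slopes),
    frt2_fr = piecewise_ramp(p$break_hr[2], p$hr0, p$fr0, p$break_hr,
                             p$fr_slopes),
    get1_vo2 = vo2_b[1], get2_vo2 = vo2_b[2], get2_vco2 = vco2_b2,
    frt1_po = po_b[1], frt2_po = po_b[2],
    hr_increment = p$hr_slope * 20)
  list(series = series, truth = truth, params = p)
}

#' Simulate a cohort of incremental tests
#'
#' Draws per-subject parameters from population ranges portraying a
#' middle-aged cohort of mixed fitness: W_max roughly 240 +/- 40 W, peak
#' heart rate around 185 beats/min, first threshold near 70-76% and second
#' threshold near 82-87% of peak heart rate. The middle-segment slope of
#' respiratory frequency is drawn so that its rise per stage is 3 to 4.5
#' noise SDs — the sharp-breakpoint regime the 2-SD trigger rule is
#' designed for — and the adjacent-segment slope ratios stay above 3.
#' Fully reproducible from the seed.
#'
#' @param n number of subjects.
#' @param seed integer seed.
#' @param noise_sd per-channel noise SDs passed to every subject.
#' @return list of length \code{n}; each element as returned by
#'   [generate_series()].
#' @export
generate_cohort <- function(n, seed = 1,
                            noise_sd = list(hr = 2, fr = 0.8, vo2 = 0.035,
                                            vco2 = 0.035, ve = 1.0)) {
  if (n < 1L) stop("n must be >= 1")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    w_max <- 20 * round(stats::rnorm(1, 242, 38) / 20)
    w_max <- min(max(w_max, 160), 340)
    hr0 <- stats::rnorm(1, 90, 6)
    hr_slope <- max(stats::rnorm(1, 0.39, 0.04), 0.30)
    hr_range <- hr_slope * w_max
    f1 <- stats::runif(1, 0.42, 0.52)
    f2 <- stats::runif(1, f1 + 0.17, 0.75)
    # middle-segment rise per stage between 3 and 4.5 noise SDs
    s2 <- stats::runif(1, 3, 4.5) * noise_sd$fr / (hr_slope * 20)
    s1 <- s2 / stats::runif(1, 5, 6.5)
    s3 <- s2 * stats::runif(1, 4, 6)
    v1 <- stats::runif(1, 21, 25)
    p <- subject_params(
      w_max = w_max, hr0 = hr0, hr_slope = hr_slope,
      fr0 = stats::rnorm(1, 14, 1.5),
      fr_slopes = c(s1, s2, s3),
      break_hr = hr0 + hr_range * c(f1, f2),
      vo2_0 = stats::runif(1, 0.40, 0.55),
      vo2_slope = stats::runif(1, 0.010, 0.012),
      vco2_slopes = c(stats::runif(1, 0.88, 0.96),
                      stats::runif(1, 1.25, 1.38)),
      ve_slopes = c(v1, v1 * stats::runif(1, 1.35, 1.60)),
      noise_sd = noise_sd, subject_id = sprintf("sim%03d", i))
    generate_series(p)
  })
}
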