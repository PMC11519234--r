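#' Gas sample from open-circuit spirometry
#'
#' Inspired ventilation together with mixed-expired gas fractions, the raw
#' quantities from which oxygen uptake and carbon-dioxide output are derived
#' by the Haldane transformation (nitrogen balance between inspired and
#' expired air). Inspired fractions default to ambient air.
#'
#' @param vi inspired ventilation in L/min (STPD assumed).
#' @param feo2 mixed-expired O2 fraction (0-1).
#' @param feco2 mixed-expired CO2 fraction (0-1).
#' @param fio2 inspired O2 fraction; ambient-air default 0.2093.
#' @param fico2 inspired CO2 fraction; ambient-air default 0.0003.
#' @return A list of class \code{gas_sample}.
#' @examples
#' g <- gas_sample(vi = 100, feo2 = 0.16, feco2 = 0.04)
#' compute_vo2(g)   # 5.122 L/min
#' compute_vco2(g)  # 3.922 L/min
#' @export
gas_sample <- function(vi, feo2, feco2, fio2 = 0.2093, fico2 = 0.0003) {
  if (any(vi <= 0)) stop("vi must be > 0")
  if (any(feo2 < 0) || any(feco2 < 0) || any(feo2 + feco2 >= 1))
    stop("domain error: expired fractions must satisfy 0 <= feo2 + feco2 < 1")
  if (any(fio2 <= 0) || any(fico2 < 0) || any(fio2 + fico2 >= 1))
    stop("domain error: inspired fractions must satisfy 0 < fio2 + fico2 < 1")
  structure(list(vi = vi, feo2 = feo2, feco2 = feco2,
                 fio2 = fio2, fico2 = fico2), class = "gas_sample")
}

# expired/inspired nitrogen ratio used by the Haldane transformation;
# with ambient air the numerator (1 - fio2 - fico2) is exactly 0.7904
haldane_factor <- function(s) (1 - s$fio2 - s$fico2) / (1 - s$feo2 - s$feco2)

#' Oxygen uptake by the Haldane transformation
#'
#' \deqn{\dot{V}O_2 = \dot{V}_I (F_{IO_2} - \frac{1 - F_{IO_2} - F_{ICO_2}}
#'   {1 - F_{EO_2} - F_{ECO_2}} F_{EO_2})}
#' Expired ventilation is reconstructed from inspired ventilation through
#' the nitrogen balance, so only inspired flow and expired fractions are
#' needed. A tiny negative result (measurement noise around zero uptake) is
#' clamped to 0 with a warning; larger negatives raise an error.
#'
#' @param sample a [gas_sample].
#' @param tol negatives above \code{-tol * vi} are clamped to zero.
#' @return Oxygen uptake in L/min.
#' @export
compute_vo2 <- function(sample, tol = 1e-3) {
  vo2 <- sample$vi * (sample$fio2 - haldane_factor(sample) * sample$feo2)
  clamp_small_negative(vo2, sample$vi, tol, "vo2")
}

#' Carbon-dioxide output by the Haldane transformation
#'
#' \deqn{\dot{V}CO_2 = \dot{V}_I (\frac{1 - F_{IO_2} - F_{ICO_2}}
#'   {1 - F_{EO_2} - F_{ECO_2}} F_{ECO_2} - F_{ICO_2})}
#' With inspired CO2 at its ambient trace level the subtracted term is
#' negligible but it is retained for non-ambient inspirates.
#'
#' @inheritParams compute_vo2
#' @return CO2 output in L/min.
#' @export
compute_vco2 <- function(sample, tol = 1e-3) {
  vco2 <- sample$vi * (haldane_factor(sample) * sample$feco2 - sample$fico2)
  clamp_small_negative(vco2, sample$vi, tol, "vco2")
}

clamp_small_negative <- function(x, vi, tol, what) {
  bad <- x < -tol * vi
  if (any(bad))
    stop("domain error: ", what, " is negative beyond tolerance")
  neg <- x < 0
  if (any(neg)) {
    warning(what, " slightly negative; clamped to 0")
    x[neg] <- 0
  }
  x
}

#' Derived gas-exchange quantities
#'
#' Bundles oxygen uptake, CO2 output, the respiratory exchange ratio
#' (RER = VCO2/VO2) and the ventilatory equivalents for O2 and CO2. Ratios
#' whose denominator is zero are returned as \code{NA} (flagged undefined),
#' never as infinities.
#'
#' @param sample a [gas_sample].
#' @param ve expired minute ventilation in L/min, as reported by the
#'   measurement system.
#' @return A list of class \code{gas_derived} with elements \code{vo2},
#'   \code{vco2}, \code{rer}, \code{ve_vo2}, \code{ve_vco2}.
#' @export
derive_gas <- function(sample, ve) {
  if (any(ve <= 0)) stop("ve must be > 0")
  vo2 <- compute_vo2(sample)
  vco2 <- compute_vco2(sample)
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  structure(list(vo2 = vo2, vco2 = vco2,
                 rer = ratio(vco2, vo2),
                 ve_vo2 = ratio(ve, vo2),
                 ve_vco2 = ratio(ve, vco2)),
            class = "gas_derived")
}
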