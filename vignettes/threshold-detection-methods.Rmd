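---
title: "Detecting ventilatory thresholds from respiratory frequency: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ventilatory thresholds from respiratory frequency: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frthresh)
```

## The problem

During an incremental (graded) exercise test, two submaximal intensity
boundaries separate the moderate, heavy and severe exercise domains. They
are conventionally located from gas-exchange measurements: the first
gas-exchange threshold (GET1) is the onset of a disproportionate rise of
CO2 output relative to O2 uptake, and the second (GET2) the onset of a
disproportionate rise of ventilation relative to CO2 output. Measuring them
requires a metabolic cart. `frthresh` implements, alongside the classic
V-slope reference procedure, an alternative that needs only a chest strap
and a breathing-rate sensor: two respiratory-frequency thresholds (fRT1,
fRT2) located on the relation of breathing frequency (f_R, breaths/min) to
heart rate (HR, beats/min).

## The respiratory-frequency method

The input is a stage table: one row per completed stage of a 1-min, +20 W
cycling protocol, from the unloaded stage to exhaustion, with the stage's
power output, heart rate and respiratory frequency.

**Provisional scan.** For each stage $i \ge 1$ the running baseline is the
mean and sample SD (denominator $n-1$) of the f_R values of *all* previous
stages, including the unloaded and low-load ones. A stage *triggers* when

$$f_{R,i} - \overline{f_R}_{\,0..i-1} > 2\,\mathrm{SD}_{0..i-1}$$

and its power output strictly exceeds 60 W. The 2-SD gate marks a rise in
breathing frequency outside the plausible range of the preceding trend (a
95%-style criterion); the strict 60 W eligibility cut keeps the spontaneous
hyperventilation common in the first minutes of exercise from triggering,
while those early stages still feed the baseline. The first triggering
stage is the provisional first threshold, the next triggering stage after
it the provisional second threshold; the baseline definition never resets.
All comparisons use full-precision values — rounding happens only in
displays.

**Segment fits and intersections.** Three ordinary least-squares lines of
f_R on HR are fitted: RL1 from the first stage through the first
provisional stage, RL2 between the two provisional stages, RL3 from the
second provisional stage through the last completed stage. The provisional
stages belong to both adjacent segments. The final thresholds are the
intersections RL1×RL2 (fRT1) and RL2×RL3 (fRT2), reported as (HR, f_R)
coordinates. When the series carries oxygen-uptake values, the threshold
heart rates are mapped to V̇O2 and power output through the linear
regressions of V̇O2 on HR and of V̇O2 on PO; both mapping regressions use
all completed stages, the widest and therefore most stable window, since no
narrower window is canonical.

Failures are statuses, not errors: a series with no trigger, only one
trigger, a degenerate segment (fewer than two points or constant HR), or
near-parallel segments (slope difference below $10^{-6}$) yields
`undetermined` with a reason code, so cohorts can be processed in batch.

The worked example shipped with the package reproduces every displayed
number of its source: provisional stages at 100 W and 160 W, running
baselines 16.1/2.42 and 17.9/3.23, segment coefficients 0.1399/1.9233,
0.3333/−26.179, 2.3453/−361.17, and intersection f_R values 22.3 and
29.3 breaths/min:

```{r example}
series <- read_stage_csv(system.file("extdata",
  "incremental_test_example.csv", package = "frthresh"))
detect_frt(series)
```

The intersection heart rates at full precision are 145.4 and 166.5
beats/min; displays round HR to the nearest integer and f_R to one
decimal.

## The V-slope reference method

GET2 is located on the ventilation vs CO2-output relation, GET1 on the
CO2-output vs O2-uptake relation, by a two-segment best fit: every
admissible split of the filtered points into a lower and an upper limb
(minimum three points each, the candidate point shared) is fitted by
ordinary least squares, and the retained split maximizes the ratio of the
perpendicular distance between the two-limb intersection and the single
all-points regression line to that single regression's mean square error.
Ties go to the earliest split.

Exclusion filters precede the search. For GET2: the first two stages, and
trailing stages whose stage-to-stage V̇O2 increment is below 0.120 L/min
(removal stops at the first compliant increment). For GET1: the first two
stages, leading points while the slope of the first three-point window of
the CO2-vs-O2 relation is below 0.6 (re-checked after each removal), and
all points whose V̇O2 exceeds the detected GET2. Acceptance rules are
strict inequalities: GET2 requires the slope to increase by more than 15%
from the lower to the upper limb, GET1 by more than 0.1 in absolute slope
units; otherwise the threshold is undetermined. When GET2 is undetermined
the GET1 search proceeds without the upper cap and the result carries a
`no_get2_cap` flag.

Numerical choices worth knowing:

* the distance in the criterion is measured in raw axis units (both axes
  in L/min); no axis normalization precedes it;
* a candidate split whose fitted intersection falls outside the x-range of
  the data scores zero. On steep relations (ventilation rises ~25-35 L/min
  per L/min of CO2) two near-parallel limbs can intersect far outside the
  data, at a large distance from the single line; such a crossing is not a
  physiological breakpoint, and without this guard it can dominate the
  criterion;
* parallel limbs (slope difference below $10^{-9}$) likewise score zero, so
  perfectly collinear data return a zero criterion and no accepted break;
* a minimum of three points per limb keeps zero-residual two-point limbs
  from destabilizing the criterion;
* threshold coordinates off the fitted axis (HR, PO, f_R and — for GET2 —
  V̇O2) are linearly interpolated between the two stages bracketing the
  break on the fitted predictor.

## Gas-exchange computations

For setups recording inspired ventilation and mixed-expired fractions, the
package computes V̇O2 and V̇CO2 by the Haldane transformation (nitrogen
balance), with ambient-air inspired fractions F_IO2 = 0.2093 and
F_ICO2 = 0.0003, giving a nitrogen factor of exactly
1 − 0.2093 − 0.0003 = 0.7904:

$$\dot{V}O_2 = \dot{V}_I\left(F_{IO_2} -
  \frac{0.7904}{1 - F_{EO_2} - F_{ECO_2}}\,F_{EO_2}\right), \qquad
\dot{V}CO_2 = \dot{V}_I\left(\frac{0.7904}{1 - F_{EO_2} - F_{ECO_2}}
  \,F_{ECO_2} - F_{ICO_2}\right)$$

The $-F_{ICO_2}$ term in the CO2 equation is retained for non-ambient
inspirates (it is negligible for room air). The ratio quantities (RER,
ventilatory equivalents) are flagged `NA` rather than infinite when their
denominator is zero, and small negative volumes around zero uptake are
clamped to zero with a warning. Volumes are assumed already standardized
(STPD); no drift or response-time correction is attempted, as those are
hardware-level procedures.

## Method-comparison statistics

Agreement between a candidate and a reference threshold estimate uses the
conventional toolkit: Bland–Altman mean bias with 1.96-SD limits of
agreement (sample SD of the paired differences; proportional bias assessed
by regressing differences on pair means), Pearson correlation, the standard
error of estimate of the reference-on-candidate regression
($\sqrt{SSE/(n-2)}$, also as % of the response mean), Hedges' g (pooled-SD
standardized mean difference with the small-sample correction
$J = 1 - 3/(4\,df - 1)$) and the two-sided paired t-test. Magnitude
classes use lower-edge-inclusive half-open bands: correlation small /
moderate / large / very large / extremely large at 0.3 / 0.5 / 0.7 / 0.9;
relative SEE excellent < 2%, good < 5%, acceptable < 10%, moderate < 15%,
poor < 20%, very poor ≥ 20%; effect size small / moderate / large / very
large at 0.6 / 1.2 / 2.0. Every value maps to exactly one class.

## The simulator and what it does (not) show

`generate_series()` builds tests with known ground truth: HR linear in
power output; f_R continuous piecewise-linear in the noiseless HR with two
breakpoints; V̇O2 linear in power output; V̇CO2 piecewise-linear in V̇O2
with its slope increasing at the first threshold; ventilation
piecewise-linear in V̇CO2 with its slope increasing at the second
threshold. The gas-exchange and respiratory-frequency breakpoints are thus
co-located by construction, and i.i.d. Gaussian noise is added per channel
per stage.

Default single-subject parameters portray a middle-aged male of average
fitness: W_max 240 W, HR 90→186 beats/min (slope 0.4 per W), breakpoints
at 133 and 155 beats/min (71.5% and 83% of peak HR), V̇O2 from 0.45 L/min
at rest with 0.011 L/min/W, CO2-output slopes 0.92→1.30 (resting exchange
ratio 0.85 ramping past 1.05 near exhaustion), ventilation slopes 23→33.
Channel noise SDs are 2 beats/min (HR), 0.8 breaths/min (f_R), 0.035 L/min
(V̇O2, V̇CO2) and 1.0 L/min (ventilation). With these values the
middle-segment f_R rise per stage is 2.8 breaths/min — 3.5 noise SDs —
and the final-segment rise 14.4; the 2-SD trigger rule is designed for
exactly this sharp-breakpoint regime, and the cohort generator draws the
middle-segment rise as 3–4.5 noise SDs with adjacent-slope ratios above 3
to stay in it. A V̇CO2 generated as a smoothly ramping exchange-ratio
multiple of V̇O2 was considered and rejected: a smooth ramp has no
breakpoint, hence no GET1 ground truth to score against.

Two behaviors of the published rule are visible in simulation and worth
knowing when interpreting results:

* when early-stage f_R scatter is small, the gate is small, and the
  middle segment re-triggers immediately after the first provisional
  stage; the second provisional stage then precedes the true second
  breakpoint and RL3 spans it. Real tests (including the shipped worked
  example, whose early-stage scatter is ~2.4 breaths/min) have larger
  baselines, which quiet the middle segment;
* detection accuracy is bounded by stage discretization: a median
  absolute HR error of roughly one stage's HR rise (~8 beats/min here) is
  the expected operating accuracy, matching the precision the method
  reports against gas-exchange references on real cohorts.

The simulator emulates stage-averaged data with independent Gaussian
noise. It does not model breath-by-breath dynamics, V̇O2 kinetics (mean
response time), cardiovascular drift, autocorrelated noise, or the
irregular breathing patterns of real participants — so passing recovery
tests demonstrate correctness of the algorithms under the stated
conditions, not field performance.

Problem sizes used by the test suite: 200 simulated series for parameter
recovery, 100 random instances for the breakpoint-search oracle check,
2000 replicates of n = 20 pairs for t-test calibration, cohorts of 4–12
subjects for the batch pipeline.

## Known limitations

* The provisional-scan eligibility cut (default 60 W) assumes a 20 W/min
  protocol; other protocols should set `min_po` to the power output of
  their fourth stage.
* GET1 determinacy is intrinsically limited on short tests: after the
  two-stage, leading-slope and GET2-cap exclusions, fewer than six points
  often remain, and the fitted slope change on so few points is noisy.
  Mid-80s percent determinacy on simulated cohorts mirrors the mid-80s
  rates reported for real middle-aged cohorts; this is a property of the
  procedure, not an implementation artifact.
* Threshold coordinates are only as good as the stage-level averaging of
  the inputs; the package takes stage values as given.
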