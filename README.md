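# frthresh

Detection of ventilatory exercise-intensity thresholds from stage-wise
incremental cycling tests.

During a graded exercise test two submaximal thresholds separate the
moderate, heavy and severe intensity domains. The conventional way to
locate them — the Beaver–Wasserman–Whipp "V-slope" analysis of gas-exchange
data — needs a metabolic cart. `frthresh` implements, side by side:

* **Respiratory-frequency thresholds (fRT1, fRT2).** An objective
  breakpoint method needing only heart rate (HR) and breathing frequency
  (f_R): a running-baseline scan flags the first stage (above a 60 W
  eligibility cut) where f_R exceeds the mean of all prior stages by more
  than twice their SD, and the first later stage where that happens again;
  three least-squares segments of f_R on HR are fitted around these two
  provisional stages (which belong to both neighbouring segments), and the
  segment intersections are the thresholds.
* **Gas-exchange thresholds (GET1, GET2) by the V-slope procedure.**
  Two-segment best fit on V̇E vs V̇CO2 (GET2) and V̇CO2 vs V̇O2 (GET1),
  maximizing the ratio of the intersection's distance from the single
  regression line to its mean square error, with the classic exclusion
  filters (first two stages; sub-0.120 L/min V̇O2 tail increments; leading
  slope < 0.6; data beyond GET2) and strict slope-change acceptance rules
  (> 15% for GET2, > 0.1 for GET1).
* **Gas-exchange computation** from inspired ventilation and expired
  fractions via the Haldane transformation (nitrogen factor 0.7904).
* **Method-comparison statistics**: Bland–Altman bias and limits of
  agreement, Pearson r, standard error of estimate and Hedges' g, each
  with the standard magnitude-classification bands, plus paired t-tests.
* **A seedable simulator** of single tests and cohorts with embedded
  ground-truth breakpoints, so every detector is testable end to end.

## Worked example

The package ships a fully worked 14-stage test (0–260 W, 1-min +20 W
stages) under `inst/extdata/`:

```r
library(frthresh)
series <- read_stage_csv(system.file("extdata",
  "incremental_test_example.csv", package = "frthresh"))
summary(series)
#> Test summary (incremental_test_example)
#>   W_max   : 260 W
#>   HR_max  : 184 beats/min
#>   fR_max  : 92.3 breaths/min

detect_frt(series)
#> Respiratory-frequency threshold detection
#>   provisional stages: 100 W and 160 W
#> RL1: y = 0.1399 * x + 1.9233  (n = 6, SSE = 19.67)
#> RL2: y = 0.3333 * x + -26.1794  (n = 4, SSE = 34.76)
#> RL3: y = 2.3453 * x + -361.1735  (n = 6, SSE = 975.5)
#> fRT1 [determined]: fR = 22.3 breaths/min, HR = 145 beats/min
#> fRT2 [determined]: fR = 29.3 breaths/min, HR = 166 beats/min
```

Reading: the 2-SD scan flags the 100 W and 160 W stages as provisional
thresholds; the three fitted segments (slope in breaths/min per beat/min)
intersect at the two final thresholds — the first at a breathing frequency
of 22.3 breaths/min and heart rate ≈ 145 beats/min, the second at
29.3 breaths/min and ≈ 166 beats/min. When V̇O2 data are present the
thresholds are also expressed in V̇O2 and power output, and
`detect_gets()` adds the V-slope gas-exchange thresholds:

```r
sim <- generate_series(subject_params(seed = 1))
detect_all(sim$series)       # fRT1/fRT2 + GET1/GET2 + test summary
sim$truth                    # embedded ground-truth breakpoints
```

Batch processing over a directory of stage CSVs, with per-subject JSON
output and cohort agreement statistics (candidate fRT vs reference GET for
V̇O2, HR and power output), is available as `run_batch()` or from the
shell via the thin CLI at `inst/cli/frthresh.R` (subcommands `detect`,
`vslope`, `batch`, `simulate`).

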