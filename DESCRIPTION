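Package: frthresh
Title: Respiratory-Frequency and Gas-Exchange Threshold Detection for
    Incremental Exercise Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects the two ventilatory exercise-intensity thresholds from
    stage-wise incremental cycling tests. Implements an objective
    respiratory-frequency method (a 2-SD running-baseline scan of breathing
    frequency against heart rate followed by three-segment linear regression
    and line intersection), the classic Beaver-Wasserman-Whipp V-slope
    procedure for the gas-exchange thresholds with its exclusion filters and
    slope-change acceptance rules, Haldane-transform gas-exchange
    computations from expired fractions, and the method-comparison
    statistics (Bland-Altman agreement, correlation and standard-error
    magnitude classes, Hedges' g) used to validate threshold estimates.
    A seedable simulator generates incremental-test series and cohorts with
    known ground-truth breakpoints for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
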