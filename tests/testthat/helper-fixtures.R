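# the worked-example incremental test shipped with the package: a
# representative middle-aged participant, 1-min +20 W stages to 260 W
example_series <- function() {
  read_stage_csv(system.file("extdata", "incremental_test_example.csv",
                             package = "frthresh"))
}

# exactly linear test: vo2 = 0.5 + 0.01*po, hr = 60 + 0.5*po, fr mildly rising
linear_series <- function(n_stages = 14) {
  po <- seq(0, by = 20, length.out = n_stages)
  stage_series(po = po, hr = 60 + 0.5 * po, fr = 14 + 0.02 * po,
               vo2 = 0.5 + 0.01 * po)
}

# random valid stage series for property-style checks
random_series <- function(seed, n_stages = 10) {
  set.seed(seed)
  po <- seq(0, by = 20, length.out = n_stages)
  stage_series(po = po,
               hr = sort(stats::runif(n_stages, 80, 190)),
               fr = stats::runif(n_stages, 10, 60),
               vo2 = sort(stats::runif(n_stages, 0.4, 3.5)))
}
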