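#' Detect all four thresholds for one test
#'
#' Runs the respiratory-frequency detector and, when the gas channels are
#' present, the V-slope gas-exchange detector on one stage series, and
#' bundles the four threshold results with the test summary.
#'
#' @param series a [stage_series].
#' @param min_po eligibility cut for the provisional scan, watts.
#' @param min_segment minimum points per V-slope limb.
#' @return list with \code{summary}, \code{thresholds} (fRT1, fRT2 and,
#'   when gas data allow, GET1 and GET2) and \code{frt} (the full
#'   \code{frt_detection} object).
#' @export
detect_all <- function(series, min_po = 60, min_segment = 3) {
  frt <- detect_frt(series, min_po = min_po)
  thresholds <- list(frt$frt1, frt$frt2)
  has_gas <- !is.null(series$vo2_lmin) && !is.null(series$vco2_lmin) &&
    !is.null(series$ve_lmin)
  if (has_gas) {
    gets <- detect_gets(series, min_segment = min_segment)
    thresholds <- c(thresholds, list(gets$get1, gets$get2))
  }
  names(thresholds) <- vapply(thresholds, `[[`, "", "name")
  list(summary = summary(series), thresholds = thresholds, frt = frt)
}

#' Batch threshold detection over a directory of stage CSVs
#'
#' Processes every \code{*.csv} stage table in a directory with
#' [detect_all()]. Per-file failures are logged to stderr and skipped; the
#' call fails only if no file could be processed. When at least
#' \code{min_pairs} subjects have a paired determined respiratory-frequency
#' and gas-exchange threshold, cohort agreement reports
#' ([agreement_report()]) are computed for oxygen uptake, heart rate and
#' power output at each threshold level, with the gas-exchange value as the
#' reference. Results are independent of file-processing order (files are
#' taken in sorted order).
#'
#' @param input_dir directory containing stage CSVs.
#' @param output_dir optional directory for per-subject results JSON files
#'   (created if needed).
#' @param min_po,min_segment detector settings.
#' @param min_pairs minimum paired subjects for cohort agreement (default 3).
#' @return list with \code{results} (per-subject [detect_all()] outputs,
#'   named by subject), \code{determinacy} (per-threshold determined
#'   counts), and \code{agreement} (list of agreement reports, possibly
#'   empty).
#' @export
run_batch <- function(input_dir, output_dir = NULL, min_po = 60,
                      min_segment = 3, min_pairs = 3) {
  files <- sort(list.files(input_dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0L)
    stop("no stage CSV files found in ", input_dir)
  if (!is.null(output_dir) && !dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)

  results <- list()
  for (f in files) {
    res <- tryCatch({
      series <- read_stage_csv(f)
      detect_all(series, min_po = min_po, min_segment = min_segment)
    }, error = function(e) {
      message("skipping ", basename(f), ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    id <- res$summary$subject_id
    results[[id]] <- res
    if (!is.null(output_dir))
      write_results_json(res, file.path(output_dir, paste0(id, ".json")))
    statuses <- vapply(res$thresholds, function(t)
      paste0(t$name, "=", t$status), "")
    message(id, ": ", paste(statuses, collapse = ", "))
  }
  if (length(results) == 0L) stop("all input files failed to process")

  all_names <- c("fRT1", "fRT2", "GET1", "GET2")
  determinacy <- vapply(all_names, function(nm)
    sum(vapply(results, function(r) {
      t <- r$thresholds[[nm]]
      !is.null(t) && t$status == "determined"
    }, NA)), 0L)

  agreement <- cohort_agreement(results, min_pairs = min_pairs)
  list(results = results, determinacy = determinacy, agreement = agreement)
}

# paired agreement reports (candidate = fRT, reference = GET) for each
# variable and threshold level with enough complete pairs
cohort_agreement <- function(results, min_pairs = 3) {
  pairs <- list(c("fRT1", "GET1"), c("fRT2", "GET2"))
  vars <- c("vo2", "hr", "po")
  out <- list()
  for (pr in pairs) {
    for (v in vars) {
      xy <- vapply(results, function(r) {
        a <- r$thresholds[[pr[1]]]; b <- r$thresholds[[pr[2]]]
        if (is.null(a) || is.null(b) ||
            a$status != "determined" || b$status != "determined")
          return(c(NA_real_, NA_real_))
        c(a[[v]], b[[v]])
      }, numeric(2))
      ok <- stats::complete.cases(t(xy))
      if (sum(ok) >= min_pairs) {
        lbl <- paste0(v, "@", pr[1], "-vs-", pr[2])
        out[[lbl]] <- agreement_report(xy[1, ok], xy[2, ok], variable = lbl)
      }
    }
  }
  out
}
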