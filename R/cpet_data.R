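#' Stage-wise incremental exercise test series
#'
#' Container for one incremental (graded) exercise test recorded at the stage
#' level: one row per completed stage, ordered from the unloaded (0 W) stage
#' to the last completed stage. Power output, heart rate and respiratory
#' frequency are mandatory; gas-exchange channels (oxygen uptake,
#' carbon-dioxide output, minute ventilation, tidal volume) are optional and
#' simply enable the detectors that need them.
#'
#' @param po numeric vector of stage power outputs in watts, non-decreasing,
#'   first stage usually 0 W (unloaded pedalling).
#' @param hr numeric vector of stage heart rates in beats per minute.
#' @param fr numeric vector of stage respiratory frequencies in breaths per
#'   minute.
#' @param vo2,vco2,ve,vt optional numeric vectors: oxygen uptake, CO2 output
#'   and minute ventilation in L/min, tidal volume in L.
#' @param subject_id character label for the subject.
#' @param increment stage power increment in watts (protocol metadata).
#' @param stage_min stage duration in minutes (protocol metadata).
#'
#' @return An object of class \code{stage_series}: a data frame with columns
#'   \code{stage} (0-based index), \code{po_watts}, \code{hr_bpm},
#'   \code{fr_brpm} and any optional gas columns, plus attributes
#'   \code{subject_id} and \code{protocol}.
#'
#' @examples
#' s <- stage_series(po = seq(0, 140, 20), hr = seq(90, 160, 10),
#'                   fr = c(14, 15, 15, 17, 18, 21, 26, 33))
#' summary(s)
#' @export
stage_series <- function(po, hr, fr, vo2 = NULL, vco2 = NULL, ve = NULL,
                         vt = NULL, subject_id = "subject",
                         increment = 20, stage_min = 1) {
  n <- length(po)
  if (length(hr) != n || length(fr) != n)
    stop("po, hr and fr must have the same length")
  df <- data.frame(stage = seq_len(n) - 1L, po_watts = as.numeric(po),
                   hr_bpm = as.numeric(hr), fr_brpm = as.numeric(fr))
  opt <- list(vo2_lmin = vo2, vco2_lmin = vco2, ve_lmin = ve, vt_l = vt)
  for (nm in names(opt)) {
    v <- opt[[nm]]
    if (!is.null(v)) {
      if (length(v) != n) stop(nm, " must have length ", n)
      df[[nm]] <- as.numeric(v)
    }
  }
  attr(df, "subject_id") <- subject_id
  attr(df, "protocol") <- list(increment_watts = increment,
                               stage_min = stage_min)
  class(df) <- c("stage_series", "data.frame")
  validate_stage_series(df)
}

validate_stage_series <- function(x) {
  if (nrow(x) < 4L)
    stop("insufficient data: at least 4 completed stages are required, got ",
         nrow(x))
  if (any(!is.finite(x$po_watts)) || any(x$po_watts < 0))
    stop("validation error: po_watts must be finite and >= 0")
  if (is.unsorted(x$po_watts))
    stop("validation error: po_watts must be non-decreasing across stages")
  if (any(!is.finite(x$hr_bpm)) || any(x$hr_bpm <= 0))
    stop("validation error: hr_bpm must be finite and > 0")
  if (any(!is.finite(x$fr_brpm)) || any(x$fr_brpm <= 0))
    stop("validation error: fr_brpm must be finite and > 0")
  for (nm in c("vo2_lmin", "vco2_lmin", "ve_lmin", "vt_l"))
    if (!is.null(x[[nm]]) && any(x[[nm]][!is.na(x[[nm]])] <= 0))
      stop("validation error: ", nm, " must be > 0 where present")
  x
}

#' @export
print.stage_series <- function(x, ...) {
  cat("Incremental test series: subject '", attr(x, "subject_id"), "', ",
      nrow(x), " stages, W_max = ", x$po_watts[nrow(x)], " W\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Read a stage-table CSV
#'
#' Reads a comma-separated stage table with a mandatory header row. Required
#' columns are \code{po_watts}, \code{hr_bpm} and \code{fr_brpm}; the
#' optional columns \code{stage}, \code{vo2_lmin}, \code{vco2_lmin},
#' \code{ve_lmin} and \code{vt_l} are captured when present and unknown
#' columns are ignored. Rows are ordered by \code{stage} when that column is
#' present, otherwise taken in file order.
#'
#' @param path path to the CSV file.
#' @param subject_id subject label; defaults to the file name without
#'   extension.
#' @return A validated [stage_series].
#' @seealso [write_stage_csv()]
#' @export
read_stage_csv <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = TRUE)
  for (col in c("po_watts", "hr_bpm", "fr_brpm"))
    if (!col %in% names(raw))
      stop("input format error: required column '", col, "' missing in ", path)
  if ("stage" %in% names(raw)) raw <- raw[order(raw$stage), , drop = FALSE]
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  opt <- function(col) if (col %in% names(raw)) as.numeric(raw[[col]]) else NULL
  stage_series(po = raw$po_watts, hr = raw$hr_bpm, fr = raw$fr_brpm,
               vo2 = opt("vo2_lmin"), vco2 = opt("vco2_lmin"),
               ve = opt("ve_lmin"), vt = opt("vt_l"),
               subject_id = subject_id)
}

#' Write a stage series to CSV
#'
#' Writes the canonical column layout read back by [read_stage_csv()];
#' write-then-read reproduces the series to numeric precision.
#'
#' @param series a [stage_series].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stage_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Summarize an incremental test
#'
#' Per-test maxima as conventionally reported: maximal workload
#' \eqn{W_{max}} (power output of the last completed stage), maximal heart
#' rate (highest heart rate achieved), peak oxygen uptake, maximal
#' respiratory frequency, and maximal respiratory exchange ratio when both
#' gas channels are available.
#'
#' @param object a [stage_series].
#' @param body_mass_kg optional body mass; when given, peak oxygen uptake is
#'   additionally expressed in mL/kg/min.
#' @param ... unused.
#' @return A list of class \code{series_summary} with elements
#'   \code{w_max}, \code{hr_max}, \code{fr_max} and, when computable,
#'   \code{vo2_peak}, \code{vo2_peak_rel}, \code{rer_max}.
#' @export
summary.stage_series <- function(object, body_mass_kg = NULL, ...) {
  out <- list(subject_id = attr(object, "subject_id"),
              w_max = object$po_watts[nrow(object)],
              hr_max = max(object$hr_bpm),
              fr_max = max(object$fr_brpm))
  if (!is.null(object$vo2_lmin)) {
    out$vo2_peak <- max(object$vo2_lmin)
    if (!is.null(body_mass_kg)) {
      if (body_mass_kg <= 0) stop("body_mass_kg must be > 0")
      out$vo2_peak_rel <- 1000 * out$vo2_peak / body_mass_kg
    }
  }
  if (!is.null(object$vo2_lmin) && !is.null(object$vco2_lmin))
    out$rer_max <- max(object$vco2_lmin / object$vo2_lmin)
  class(out) <- "series_summary"
  out
}

#' @export
print.series_summary <- function(x, ...) {
  cat("Test summary (", x$subject_id, ")\n", sep = "")
  cat("  W_max   :", x$w_max, "W\n")
  cat("  HR_max  :", x$hr_max, "beats/min\n")
  cat("  fR_max  :", x$fr_max, "breaths/min\n")
  if (!is.null(x$vo2_peak))
    cat("  VO2peak :", format(x$vo2_peak, digits = 4), "L/min\n")
  if (!is.null(x$vo2_peak_rel))
    cat("  VO2peak :", format(x$vo2_peak_rel, digits = 4), "mL/kg/min\n")
  if (!is.null(x$rer_max))
    cat("  RER_max :", format(x$rer_max, digits = 3), "\n")
  invisible(x)
}

#' Express a value as a percentage of its peak
#'
#' @param value measurement (same units as \code{peak}).
#' @param peak peak value, must be positive.
#' @return \code{100 * value / peak}.
#' @examples
#' percent_of_peak(1.726, 3.138) # 55.0 (% of peak)
#' @export
percent_of_peak <- function(value, peak) {
  if (any(peak <= 0)) stop("domain error: peak must be > 0")
  100 * value / peak
}

#' Write detection results to JSON
#'
#' Serialises a test summary plus a set of threshold results into a
#' schema-stable JSON document:
#' \code{\{subject_id, summary\{...\}, thresholds: [\{name, status, reason,
#' fr, hr, vo2, po, hr_pct_max, vo2_pct_peak, lines: [\{segment, slope,
#' intercept, n\}]\}]\}}. Numbers are written with enough digits that a
#' read-back via [read_results_json()] round-trips, and identical inputs
#' always produce byte-identical files.
#'
#' @param results list with elements \code{summary} (a
#'   \code{series_summary}) and \code{thresholds} (a list of
#'   \code{threshold_result} objects, possibly empty).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(results, path) {
  summ <- results$summary
  if (is.null(summ)) stop("results must contain a 'summary' element")
  thr <- lapply(results$thresholds, function(t) {
    out <- list(name = t$name, status = t$status)
    if (!is.null(t$reason)) out$reason <- t$reason
    for (f in c("fr", "hr", "vo2", "po", "hr_pct_max", "vo2_pct_peak"))
      if (!is.null(t[[f]]) && !is.na(t[[f]])) out[[f]] <- unname(t[[f]])
    if (!is.null(t$lines))
      out$lines <- lapply(t$lines, function(l)
        list(segment = l$segment, slope = unname(l$slope),
             intercept = unname(l$intercept), n = l$n))
    out
  })
  doc <- list(subject_id = summ$subject_id,
              summary = unclass(summ)[setdiff(names(summ), "subject_id")],
              thresholds = thr)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(10),
                           pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read back a results JSON document
#'
#' @param path path written by [write_results_json()].
#' @return The parsed list (\code{subject_id}, \code{summary},
#'   \code{thresholds}).
#' @export
read_results_json <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}
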