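#' Bland-Altman agreement analysis
#'
#' Mean bias and 95% limits of agreement between two methods measuring the
#' same quantity: differences \code{d = x - y}, bias = mean(d), limits =
#' bias +/- 1.96 * SD(d) (sample SD). Proportional bias is assessed by
#' regressing the differences on the pair means and reporting the slope's
#' p-value.
#'
#' @param x,y paired measurements (equal length, n >= 3).
#' @return list with \code{n}, \code{bias}, \code{loa_low}, \code{loa_high},
#'   \code{sd_diff}, \code{proportional_bias_p}.
#' @export
bland_altman <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("insufficient pairs: need at least 3")
  d <- x - y
  m <- (x + y) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  prop_p <- if (stats::sd(m) > 0 && s > 1e-10 * (abs(bias) + 1)) {
    fit <- stats::lm(d ~ m)
    stats::coef(summary(fit))[2L, "Pr(>|t|)"]
  } else NA_real_
  list(n = n, bias = bias, loa_low = bias - 1.96 * s,
       loa_high = bias + 1.96 * s, sd_diff = s,
       proportional_bias_p = unname(prop_p))
}

r_class_breaks <- c(0.3, 0.5, 0.7, 0.9)
r_class_labels <- c("small", "moderate", "large", "very large",
                    "extremely large")

#' Pearson correlation with magnitude class
#'
#' Product-moment correlation classified on the conventional magnitude
#' scale, lower edge inclusive on the absolute value: |r| < 0.3 small,
#' [0.3, 0.5) moderate, [0.5, 0.7) large, [0.7, 0.9) very large,
#' >= 0.9 extremely large.
#'
#' @param x,y paired values (equal length, n >= 3, nonzero variance each).
#' @return list with \code{r} and \code{r_class}.
#' @export
pearson_with_class <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: an input has zero variance")
  r <- stats::cor(x, y)
  list(r = r, r_class = classify(abs(r), r_class_breaks, r_class_labels))
}

see_class_breaks <- c(2, 5, 10, 15, 20)
see_class_labels <- c("excellent", "good", "acceptable", "moderate",
                      "poor", "very poor")

#' Standard error of estimate with precision class
#'
#' Ordinary least squares of \code{y} on \code{x}; the standard error of
#' estimate is \code{sqrt(SSE / (n - 2))} and its relative value (% of the
#' response mean) is classified: < 2% excellent, < 5% good, < 10%
#' acceptable, < 15% moderate, < 20% poor, >= 20% very poor (lower edge
#' inclusive: 20% is very poor).
#'
#' @param x predictor values.
#' @param y response values (equal length, n >= 3).
#' @return list with \code{see}, \code{see_pct}, \code{see_class}.
#' @export
see_with_class <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 pairs")
  line <- fit_line(x, y)
  see <- sqrt(line$sse / (n - 2L))
  see_pct <- 100 * see / mean(y)
  list(see = see, see_pct = see_pct,
       see_class = classify(see_pct, see_class_breaks, see_class_labels))
}

g_class_breaks <- c(0.6, 1.2, 2.0)
g_class_labels <- c("small", "moderate", "large", "very large")

#' Hedges' g effect size with magnitude class
#'
#' Standardized mean difference with the small-sample correction
#' \code{J = 1 - 3 / (4 df - 1)} applied to the pooled-SD Cohen's d:
#' \code{g = J * (mean(a) - mean(b)) / s_pooled}, df = n_a + n_b - 2.
#' Magnitude classes on |g|, lower edge inclusive: < 0.6 small,
#' [0.6, 1.2) moderate, [1.2, 2.0) large, >= 2.0 very large.
#'
#' @param a,b the two samples (n >= 2 each).
#' @return list with \code{g} and \code{g_class}.
#' @export
hedges_g <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("need at least 2 values per sample")
  df <- na + nb - 2L
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df)
  if (sp == 0) stop("undefined effect size: pooled SD is zero")
  g <- (mean(a) - mean(b)) / sp * (1 - 3 / (4 * df - 1))
  list(g = g, g_class = classify(abs(g), g_class_breaks, g_class_labels))
}

# half-open bands, lower edge inclusive for the labelled break values
classify <- function(value, breaks, labels) {
  labels[findInterval(value, breaks, left.open = FALSE) + 1L]
}

#' Paired Student's t-test p-value
#'
#' Two-sided p-value of the paired t statistic
#' \code{t = mean(d) / (SD(d) / sqrt(n))}, df = n - 1. When the differences
#' have zero SD the test is degenerate: p is reported as 0 (with a warning)
#' for a nonzero mean difference and 1 for identical vectors.
#'
#' @param a,b paired samples (equal length, n >= 3).
#' @return the two-sided p-value.
#' @export
paired_t <- function(a, b) {
  n <- length(a)
  if (length(b) != n) stop("a and b must have equal length")
  if (n < 3L) stop("need at least 3 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(1)
    warning("zero SD of differences with nonzero mean; p reported as 0")
    return(0)
  }
  stats::t.test(a, b, paired = TRUE)$p.value
}

#' Full method-comparison report for a pair of threshold estimates
#'
#' Bundles the statistics used to validate one threshold variable
#' (e.g. oxygen uptake at the first threshold) across two methods:
#' Bland-Altman bias and limits of agreement, Pearson correlation with
#' magnitude class, standard error of estimate with precision class,
#' Hedges' g with magnitude class, and the paired t-test p-value.
#'
#' @param x,y paired per-subject values from the two methods (\code{x}
#'   conventionally the candidate method, \code{y} the reference).
#' @param variable label carried into the report.
#' @return list of class \code{agreement_report}.
#' @export
agreement_report <- function(x, y, variable = "") {
  ba <- bland_altman(x, y)
  pc <- pearson_with_class(x, y)
  sc <- see_with_class(x, y)
  hg <- hedges_g(x, y)
  grand_mean <- mean(c(x, y))
  structure(list(variable = variable, n = ba$n,
                 bias = ba$bias,
                 bias_pct_mean = if (grand_mean != 0)
                   100 * ba$bias / grand_mean else NA_real_,
                 loa_low = ba$loa_low, loa_high = ba$loa_high,
                 proportional_bias_p = ba$proportional_bias_p,
                 r = pc$r, r_class = pc$r_class,
                 see = sc$see, see_pct = sc$see_pct,
                 see_class = sc$see_class,
                 g = hg$g, g_class = hg$g_class,
                 paired_p = paired_t(x, y)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement report", if (nzchar(x$variable)) paste0("(", x$variable, ")"),
      "- n =", x$n, "\n")
  cat(sprintf("  bias %.4g (%.1f%% of mean), LOA [%.4g, %.4g], prop-bias p = %.3f\n",
              x$bias, x$bias_pct_mean, x$loa_low, x$loa_high,
              x$proportional_bias_p))
  cat(sprintf("  r = %.3f (%s); SEE = %.4g (%.1f%%, %s)\n",
              x$r, x$r_class, x$see, x$see_pct, x$see_class))
  cat(sprintf("  Hedges' g = %.3f (%s); paired t p = %.3f\n",
              x$g, x$g_class, x$paired_p))
  invisible(x)
}
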