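# exhaustive-split search written independently with lm(); same criterion
# definition (perpendicular distance of the intersection from the single
# line over its mean square error, zero when the intersection leaves the
# x-range or the limbs are parallel)
brute_force_split <- function(x, y, min_segment = 3) {
  n <- length(x)
  single <- lm(y ~ x)
  mse <- sum(residuals(single)^2) / (n - 2)
  a0 <- unname(coef(single)[1]); b0 <- unname(coef(single)[2])
  best_j <- NA; best_crit <- -Inf
  for (j in min_segment:(n - min_segment + 1)) {
    lo <- lm(y[1:j] ~ x[1:j]); up <- lm(y[j:n] ~ x[j:n])
    sl <- unname(coef(lo)[2]); su <- unname(coef(up)[2])
    if (!is.finite(sl) || !is.finite(su)) next
    crit <- 0
    if (abs(su - sl) >= 1e-9) {
      bx <- unname(coef(lo)[1] - coef(up)[1]) / (su - sl)
      by <- sl * bx + unname(coef(lo)[1])
      if (bx >= min(x) && bx <= max(x)) {
        dist <- abs(b0 * bx - by + a0) / sqrt(1 + b0^2)
        crit <- if (mse > 0) dist / mse else if (dist > 0) Inf else 0
      }
    }
    if (crit > best_crit + 1e-12) { best_crit <- crit; best_j <- j }
  }
  list(j = best_j, crit = best_crit)
}
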