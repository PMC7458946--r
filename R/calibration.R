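#' Bin cross-validated predictions for calibration
#'
#' Divides the observed range of predicted probabilities into `n_bins`
#' equal-width bins (range-based, not quantile-based; half-open
#' `[lower, upper)`, last bin closed) and counts test predictions and
#' positive outcomes per bin. Empty bins are retained with `n = 0`.
#'
#' @param predictions Predicted probabilities from the cross-validation test
#'   sets.
#' @param outcomes Aligned 0/1 outcomes.
#' @param n_bins Number of bins (default 4).
#' @param ci_level Confidence level of the per-bin Wilson interval
#'   (default 0.75).
#' @return Data frame of class `"calibration_bins"`: `lower`, `upper`, `n`,
#'   `n_pos`, `observed`, `ci_lower`, `ci_upper` (NA for empty bins). If all
#'   predictions are identical the result is a single degenerate bin, with a
#'   warning.
#' @export
bin_predictions <- function(predictions, outcomes, n_bins = 4L,
                            ci_level = 0.75) {
  stopifnot(length(predictions) == length(outcomes),
            length(predictions) > 0, n_bins >= 1)
  outcomes <- as.numeric(outcomes)
  lo <- min(predictions)
  hi <- max(predictions)
  if (lo == hi) {
    warning("all predictions identical; single degenerate calibration bin")
    ci <- ci75(sum(outcomes), length(outcomes), ci_level)
    out <- data.frame(lower = lo, upper = hi, n = length(outcomes),
                      n_pos = sum(outcomes), observed = mean(outcomes),
                      ci_lower = ci[1], ci_upper = ci[2])
    class(out) <- c("calibration_bins", "data.frame")
    return(out)
  }
  edges <- seq(lo, hi, length.out = n_bins + 1)
  # half-open [lower, upper), last bin closed
  idx <- pmin(findInterval(predictions, edges), n_bins)
  out <- data.frame(lower = edges[-length(edges)], upper = edges[-1])
  out$n <- tabulate(idx, nbins = n_bins)
  out$n_pos <- vapply(seq_len(n_bins),
                      function(b) sum(outcomes[idx == b]), numeric(1))
  out$observed <- ifelse(out$n > 0, out$n_pos / out$n, NA_real_)
  ci <- t(vapply(seq_len(n_bins), function(b) {
    if (out$n[b] == 0) c(NA_real_, NA_real_)
    else ci75(out$n_pos[b], out$n[b], ci_level)
  }, numeric(2)))
  out$ci_lower <- ci[, 1]
  out$ci_upper <- ci[, 2]
  class(out) <- c("calibration_bins", "data.frame")
  out
}

#' Wilson score interval at 75% confidence
#'
#' Confidence interval for a binomial proportion used to decide whether a
#' calibration bin's observed event rate deviates from the base rate. The
#' Wilson score form stays inside \[0, 1\] and behaves sensibly at small n
#' and proportions near 0 or 1, where the Wald interval degenerates.
#'
#' @param n_pos Number of positive outcomes.
#' @param n Number of observations (>= 1).
#' @param level Confidence level (default 0.75, z ~ 1.1503).
#' @return Numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' ci75(0, 10)   # lower bound exactly 0
#' ci75(5, 10)
ci75 <- function(n_pos, n, level = 0.75) {
  stopifnot(n >= 1, n_pos >= 0, n_pos <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  phat <- n_pos / n
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Fit the step-function calibration curve
#'
#' Models the relationship between predicted and observed probabilities as a
#' step function over the binned prediction range. A bin whose CI75 overlaps
#' the base rate carries no evidence of deviation on its own, so it is
#' merged with an adjacent bin that also overlaps — the one whose observed
#' probability is closest to its own (counts and CI75 recomputed, ranges
#' unioned) — pooling weakly informative neighbors in the hope that the
#' combined counts resolve the deviation. When an overlapping bin has no
#' overlapping neighbor left, merging stops for it and its calibrated value
#' defaults to the base rate; bins whose CI75 excludes the base rate keep
#' their observed probability. Empty bins are merged into their nearest
#' non-empty neighbor first.
#'
#' @param bins Output of [bin_predictions()].
#' @param base_rate Marginal event rate of the CIF over the whole dataset.
#' @param ci_level Confidence level used when recomputing merged intervals.
#' @return Object of class `"calibration_curve"`: `steps` (data frame
#'   `lower`, `upper`, `value`, `n`, `n_pos`, `defaulted`), `base_rate`,
#'   `prediction_range` (min/max step value) and `delta` (their difference,
#'   the width of the calibrated prediction range). A curve whose every step
#'   equals the base rate is flagged `constant = TRUE` (no calibrated
#'   deviation from base rate).
#' @export
fit_step_calibration <- function(bins, base_rate, ci_level = 0.75) {
  stopifnot(base_rate > 0, base_rate < 1, any(bins$n > 0))
  b <- as.data.frame(bins)[c("lower", "upper", "n", "n_pos")]

  # (1) merge empty bins into the nearest non-empty neighbor; merges are
  # always with the adjacent bin, stepping toward that neighbor, so the
  # ranges stay a partition
  while (any(b$n == 0) && nrow(b) > 1) {
    i <- which(b$n == 0)[1]
    nonempty <- which(b$n > 0)
    target <- nonempty[which.min(abs(nonempty - i))]
    j <- i + sign(target - i)
    b <- merge_bins(b, i, j)
  }
  b <- recompute_bins(b, ci_level)

  overlaps <- function(b) b$ci_lower <= base_rate & b$ci_upper >= base_rate

  # (2) pool overlapping bins with adjacent overlapping bins, choosing the
  # neighbor with the closest observed probability (ties: larger n, then
  # left); a bin whose CI75 overlaps the base rate but has no overlapping
  # neighbor left carries no usable deviation and will default in step (3)
  repeat {
    ov <- overlaps(b)
    if (nrow(b) == 1) break
    i <- NULL
    for (k in which(ov)) {
      nb <- intersect(c(k - 1, k + 1), which(ov))
      if (length(nb)) { i <- k; break }
    }
    if (is.null(i)) break
    nb <- intersect(c(i - 1, i + 1), which(ov))
    if (length(nb) == 1) {
      j <- nb
    } else {
      d <- abs(b$observed[nb] - b$observed[i])
      best <- nb[d == min(d)]
      if (length(best) > 1) best <- best[order(-b$n[best], best)][1]
      j <- best[1]
    }
    b <- recompute_bins(merge_bins(b, i, j), ci_level)
  }

  # (3) surviving overlapping bins default to the base rate
  ov <- overlaps(b)
  b$value <- ifelse(ov, base_rate, b$observed)
  b$defaulted <- ov
  steps <- b[c("lower", "upper", "value", "n", "n_pos", "defaulted")]
  structure(list(
    steps = steps,
    base_rate = base_rate,
    prediction_range = range(steps$value),
    delta = diff(range(steps$value)),
    constant = all(steps$defaulted)
  ), class = "calibration_curve")
}

merge_bins <- function(b, i, j) {
  lo <- min(i, j); hi <- max(i, j)
  b$lower[lo] <- b$lower[lo]
  b$upper[lo] <- b$upper[hi]
  b$n[lo] <- b$n[i] + b$n[j]
  b$n_pos[lo] <- b$n_pos[i] + b$n_pos[j]
  b[-hi, , drop = FALSE]
}

recompute_bins <- function(b, ci_level) {
  b$observed <- ifelse(b$n > 0, b$n_pos / b$n, NA_real_)
  ci <- t(vapply(seq_len(nrow(b)), function(k) {
    if (b$n[k] == 0) c(NA_real_, NA_real_) else ci75(b$n_pos[k], b$n[k], ci_level)
  }, numeric(2)))
  b$ci_lower <- ci[, 1]
  b$ci_upper <- ci[, 2]
  rownames(b) <- NULL
  b
}

#' Constant base-rate calibration curve
#'
#' The degenerate curve used when a model carries no features: every
#' prediction maps to the base rate, and the calibrated prediction range has
#' zero width.
#'
#' @param base_rate Marginal event rate.
#' @param range Prediction range the single step spans (length 2).
#' @return A `"calibration_curve"` with a single defaulted step and
#'   `delta = 0`.
#' @export
constant_curve <- function(base_rate, range = c(base_rate, base_rate)) {
  steps <- data.frame(lower = range[1], upper = range[2], value = base_rate,
                      n = NA_integer_, n_pos = NA_real_, defaulted = TRUE)
  structure(list(steps = steps, base_rate = base_rate,
                 prediction_range = c(base_rate, base_rate), delta = 0,
                 constant = TRUE),
            class = "calibration_curve")
}

#' Apply a calibration curve to predicted probabilities
#'
#' Returns the step value of the range containing each prediction;
#' predictions below or above the fitted range clamp to the first or last
#' step (the curve defines the upper and lower boundaries of the model
#' output, so there is no extrapolation). A value landing exactly on an
#' interior edge belongs to the right-hand (higher) step, by the half-open
#' bin convention.
#'
#' @param curve A `"calibration_curve"`.
#' @param p Predicted probability (vector).
#' @return Calibrated probabilities, always within the curve's
#'   `prediction_range`.
#' @export
apply_calibration <- function(curve, p) {
  steps <- curve$steps
  edges <- c(steps$lower, steps$upper[nrow(steps)])
  idx <- findInterval(p, edges)          # 0 below range, nrow+1 above
  idx <- pmin(pmax(idx, 1), nrow(steps)) # clamp
  steps$value[idx]
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve: base rate %.3f, range [%.3f, %.3f], delta %.3f%s\n",
              x$base_rate, x$prediction_range[1], x$prediction_range[2],
              x$delta,
              if (x$constant) " (constant: no calibrated deviation from base rate)" else ""))
  print(x$steps, ...)
  invisible(x)
}
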