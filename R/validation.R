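#' Rolling-origin time-series cross-validation splits
#'
#' One split per calendar year from the second observed year onward: the
#' training set is every activity of strictly earlier years, and the test
#' set is that year's activities minus those belonging to a study already
#' audited or inspected in an earlier year (audit planning historically
#' avoided revisiting studies, and repeat-study activities in the test year
#' would leak study-level signal). Same-year repeat activities are not
#' excluded. Exclusion applies to test sets only; training keeps repeat
#' activities.
#'
#' @param activities Activity table with `activity_id`, `year`, `study_id`.
#' @return List of `"ts_split"` objects, each with `train_years`,
#'   `test_year`, `train_ids`, `test_ids` and `excluded_ids`. Splits whose
#'   test set is emptied entirely by the exclusion are dropped with a
#'   warning.
#' @export
time_series_splits <- function(activities) {
  years <- sort(unique(activities$year))
  if (length(years) < 2) stop("need at least 2 distinct years")
  out <- list()
  for (ty in years[-1]) {
    train <- activities[activities$year < ty, , drop = FALSE]
    test <- activities[activities$year == ty, , drop = FALSE]
    prior_studies <- unique(train$study_id)
    excluded <- test$activity_id[test$study_id %in% prior_studies]
    kept <- setdiff(test$activity_id, excluded)
    if (length(kept) == 0) {
      warning("test year ", ty,
              " emptied entirely by the prior-audit exclusion; split dropped")
      next
    }
    out[[length(out) + 1]] <- structure(list(
      train_years = years[years < ty],
      test_year = ty,
      train_ids = train$activity_id,
      test_ids = kept,
      excluded_ids = excluded
    ), class = "ts_split")
  }
  out
}

#' Area under the ROC curve (rank estimator)
#'
#' Mann-Whitney form: the probability that a randomly chosen positive
#' outranks a randomly chosen negative, with tied scores contributing 1/2
#' per tied positive-negative pair (average ranks).
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 outcomes; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 1))  # 2/3
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: only one class present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and binary outcome;
#' 0 is best, 1 worst.
#'
#' @param probabilities Predicted probabilities.
#' @param labels 0/1 outcomes.
#' @return Brier score in \[0, 1\].
#' @export
brier <- function(probabilities, labels) {
  stopifnot(length(probabilities) == length(labels),
            length(labels) > 0)
  mean((probabilities - as.numeric(labels))^2)
}

#' Backtest a fixed feature set by time-series cross-validation
#'
#' For each split, refits the logistic coefficients of a previously selected
#' feature set on the training years and scores the (exclusion-filtered)
#' test year; AUC and Brier score are computed per split and aggregated as
#' mean +/- standard error (sample SD over splits / sqrt(number of splits)).
#' Feature selection is never redone inside the backtest.
#'
#' @param activities Activity table.
#' @param X `"binary_feature_matrix"` over all activities.
#' @param outcomes 0/1 vector (or [make_binary_outcome()] data frame)
#'   aligned with `X`.
#' @param selected_features Character vector of feature names fixed before
#'   backtesting (may be empty: intercept-only backtest).
#' @param cif CIF label for reporting.
#' @return Object of class `"performance_summary"` with `per_split` (data
#'   frame: `test_year`, `n_test`, `auc`, `brier`), `mean_auc`, `se_auc`,
#'   `mean_brier`, `se_brier`, and `predictions` (pooled test-set
#'   predictions across splits, the input to calibration). Splits whose
#'   training outcome is single-class are skipped with a warning; a
#'   single-class test year yields `NA` AUC (Brier is still computed).
#'   A selected feature that is constant within one split's training window
#'   is dropped from that split's refit with a warning (its coefficient is
#'   unidentifiable there; test rows then receive the intercept-only
#'   contribution for it).
#' @export
backtest <- function(activities, X, outcomes, selected_features,
                     cif = "unspecified") {
  v <- if (inherits(X, "binary_feature_matrix")) X$values else X
  if (is.data.frame(outcomes)) outcomes <- outcomes$present
  stopifnot(nrow(v) == length(outcomes),
            nrow(v) == nrow(activities))
  ids <- activities$activity_id
  splits <- time_series_splits(activities)
  rows <- list()
  preds <- list()
  for (sp in splits) {
    tr <- match(sp$train_ids, ids)
    te <- match(sp$test_ids, ids)
    ytr <- outcomes[tr]
    if (length(unique(ytr)) < 2) {
      warning("split for test year ", sp$test_year,
              " skipped: single-class training outcome")
      next
    }
    feats <- selected_features
    if (length(feats)) {
      const <- vapply(feats, function(f) stats::sd(v[tr, f]) == 0, logical(1))
      if (any(const)) {
        warning("split for test year ", sp$test_year,
                ": feature(s) constant in the training window dropped: ",
                paste(feats[const], collapse = ", "))
        feats <- feats[!const]
      }
    }
    fit <- fit_logistic(v[tr, feats, drop = FALSE], ytr,
                        cif = cif, train_years = range(sp$train_years))
    p <- predict_probability(fit, v[te, , drop = FALSE])
    yte <- outcomes[te]
    a <- if (length(unique(yte)) < 2) NA_real_ else auc(p, yte)
    rows[[length(rows) + 1]] <- data.frame(
      test_year = sp$test_year, n_test = length(te),
      auc = a, brier = brier(p, yte))
    preds[[length(preds) + 1]] <- data.frame(
      activity_id = sp$test_ids, test_year = sp$test_year,
      predicted = p, observed = yte, stringsAsFactors = FALSE)
  }
  per_split <- do.call(rbind, rows)
  se <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  structure(list(
    cif = cif,
    selected_features = selected_features,
    per_split = per_split,
    mean_auc = mean(per_split$auc, na.rm = TRUE),
    se_auc = se(per_split$auc),
    mean_brier = mean(per_split$brier),
    se_brier = se(per_split$brier),
    predictions = do.call(rbind, preds)
  ), class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("Backtest [%s]: mean AUC %.3f +/- %.3f, mean Brier %.3f +/- %.3f over %d splits\n",
              x$cif, x$mean_auc, x$se_auc %||% NA, x$mean_brier,
              x$se_brier %||% NA, nrow(x$per_split)))
  invisible(x)
}
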