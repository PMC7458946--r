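activity_schema <- c("activity_id", "year", "activity_type", "study_id",
                     "site_id")
study_schema <- c("study_id", "phase", "therapeutic_area", "randomized",
                  "design", "pediatric")
site_schema <- c("site_id", "study_id", "country", "patients_enrolled",
                 "screen_failure_rate", "active_screening_days_per_enrolled",
                 "parallel_trials_same_ta", "ae_reporting_latency_days")

#' Read the three analysis tables from delimited text files
#'
#' Reads `activities.csv`, `studies.csv` and `sites.csv` (comma-separated,
#' header row) from a directory, validates the schema and checks referential
#' integrity: every activity must reference an existing study and an
#' existing (site, study) pair.
#'
#' @param dir Directory containing the three files (as written by
#'   [write_dataset()]).
#' @return List with `activities`, `studies`, `sites` data frames.
#' @export
read_tables <- function(dir) {
  paths <- file.path(dir, c("activities.csv", "studies.csv", "sites.csv"))
  missing_f <- paths[!file.exists(paths)]
  if (length(missing_f)) stop("missing input file(s): ",
                              paste(missing_f, collapse = ", "))
  activities <- utils::read.csv(paths[1], stringsAsFactors = FALSE)
  studies <- utils::read.csv(paths[2], stringsAsFactors = FALSE)
  sites <- utils::read.csv(paths[3], stringsAsFactors = FALSE)
  check_schema <- function(df, required, what) {
    missing_c <- setdiff(required, names(df))
    if (length(missing_c)) {
      stop(what, ": schema mismatch, missing column(s): ",
           paste(missing_c, collapse = ", "))
    }
  }
  check_schema(activities, c(activity_schema, finding_cols()), "activities")
  check_schema(studies, study_schema, "studies")
  check_schema(sites, site_schema, "sites")
  bad_study <- setdiff(activities$study_id, studies$study_id)
  if (length(bad_study)) {
    stop("activities reference unknown study_id(s): ",
         paste(utils::head(bad_study, 10), collapse = ", "))
  }
  key <- paste(activities$site_id, activities$study_id)
  site_key <- paste(sites$site_id, sites$study_id)
  bad_site <- activities$activity_id[!key %in% site_key]
  if (length(bad_site)) {
    stop("activities reference unknown (site_id, study_id) pair(s); ",
         "offending activity id(s): ",
         paste(utils::head(bad_site, 10), collapse = ", "))
  }
  if (anyDuplicated(activities$activity_id)) stop("duplicate activity_id")
  list(activities = activities, studies = studies, sites = sites)
}

#' Run the full quality-risk analysis pipeline
#'
#' Orchestrates the whole analysis for all five CIFs: synthetic-data
#' generation (or user-supplied tables), binary feature engineering, forward
#' BIC feature selection on the early training window, time-series
#' cross-validated backtesting of the selected features, step-function
#' calibration of the pooled cross-validated predictions, and a final refit
#' of each model on all years. Deterministic for a fixed generator seed.
#'
#' @param config A [generator_config()]; ignored when `tables` is supplied.
#' @param tables Optional list with `activities`, `studies`, `sites` (e.g.
#'   from [read_tables()]); when given, no data are generated.
#' @param specs Feature specifications (default [default_feature_specs()]).
#' @param selection_years Years of the feature-selection window (default
#'   the first five configured years, 2011--2015 under defaults).
#' @param n_bins Number of calibration bins (default 4).
#' @param ci_level Calibration confidence level (default 0.75).
#' @param corr_threshold Collinearity screen threshold (default 0.3).
#' @param out_dir Optional directory; when given, intermediates are
#'   persisted (input tables, feature matrix, models, per-split metrics,
#'   calibration curves, report tables).
#' @return Object of class `"cif_run_report"`: `coefficients` (final
#'   coefficient table over all CIFs), `performance` (per-CIF mean AUC and
#'   Brier with SEs, calibrated prediction range, delta and base rate),
#'   `models`, `backtests`, `curves`, `selected`, and a `provenance` block
#'   (seed, selection window, package version).
#' @export
run_pipeline <- function(config = generator_config(),
                         tables = NULL,
                         specs = default_feature_specs(),
                         selection_years = NULL,
                         n_bins = 4L,
                         ci_level = 0.75,
                         corr_threshold = 0.3,
                         out_dir = NULL) {
  if (is.null(tables)) {
    ds <- generate_dataset(config)
    tables <- ds[c("activities", "studies", "sites")]
  } else {
    ds <- NULL
  }
  activities <- tables$activities
  studies <- tables$studies
  sites <- tables$sites
  years <- sort(unique(activities$year))
  if (is.null(selection_years)) {
    selection_years <- years[seq_len(min(5, length(years)))]
  }
  if (!all(selection_years %in% years)) {
    stop("selection window must be a subset of the observed years")
  }
  stopifnot(n_bins >= 2)

  fm <- build_feature_matrix(activities, studies, sites, specs)
  sel_rows <- activities$year %in% selection_years
  fm_sel <- subset_feature_matrix(fm, sel_rows)

  models <- list(); backtests <- list(); curves <- list(); selected <- list()
  perf <- list()
  for (cf in cif_names()) {
    y <- make_binary_outcome(activities, cf)$present
    sel <- select_features_bic(fm_sel, y[sel_rows], cif = cf,
                               train_years = range(selection_years),
                               corr_threshold = corr_threshold)
    selected[[cf]] <- names(sel$coefficients) %||% character(0)
    bt <- backtest(activities, fm, y, selected[[cf]], cif = cf)
    base_rate <- mean(y)
    if (length(selected[[cf]]) == 0) {
      # a feature-less model predicts a single probability per year; the
      # spread of its pooled cross-validated predictions is refit noise,
      # not risk differentiation, so the curve is the constant base rate
      curve <- constant_curve(base_rate, range(bt$predictions$predicted))
    } else {
      bins <- withCallingHandlers(
        bin_predictions(bt$predictions$predicted, bt$predictions$observed,
                        n_bins = n_bins, ci_level = ci_level),
        warning = function(w) {
          if (grepl("degenerate", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      curve <- fit_step_calibration(bins, base_rate, ci_level = ci_level)
    }
    final <- refit_on_all_data(sel, fm, y, train_years = range(years))
    models[[cf]] <- final
    backtests[[cf]] <- bt
    curves[[cf]] <- curve
    perf[[cf]] <- data.frame(
      cif = cf,
      n_features = length(selected[[cf]]),
      mean_auc = bt$mean_auc, se_auc = bt$se_auc,
      mean_brier = bt$mean_brier, se_brier = bt$se_brier,
      calibrated_min = curve$prediction_range[1],
      calibrated_max = curve$prediction_range[2],
      delta = curve$delta,
      base_rate = base_rate,
      stringsAsFactors = FALSE)
  }
  report <- structure(list(
    coefficients = coefficient_table(models),
    performance = do.call(rbind, perf),
    models = models,
    backtests = backtests,
    curves = curves,
    selected = selected,
    provenance = list(
      seed = if (!is.null(ds)) ds$truth$seed else NA_integer_,
      selection_years = selection_years,
      n_bins = n_bins, ci_level = ci_level,
      corr_threshold = corr_threshold,
      package_version = as.character(utils::packageVersion("cifrisk")))
  ), class = "cif_run_report")

  if (!is.null(out_dir)) persist_report(report, tables, fm, ds, out_dir)
  report
}

subset_feature_matrix <- function(fm, rows) {
  structure(list(activity_ids = fm$activity_ids[rows],
                 feature_names = fm$feature_names,
                 values = fm$values[rows, , drop = FALSE],
                 prevalence = fm$prevalence),
            class = "binary_feature_matrix")
}

persist_report <- function(report, tables, fm, ds, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(ds)) write_dataset(ds, file.path(out_dir, "data"))
  utils::write.csv(cbind(activity_id = fm$activity_ids,
                         as.data.frame(fm$values)),
                   file.path(out_dir, "feature_matrix.csv"),
                   row.names = FALSE)
  utils::write.csv(report$coefficients,
                   file.path(out_dir, "coefficients.csv"), row.names = FALSE)
  utils::write.csv(report$performance,
                   file.path(out_dir, "performance.csv"), row.names = FALSE)
  per_split <- do.call(rbind, lapply(report$backtests, function(b) {
    cbind(cif = b$cif, b$per_split)
  }))
  utils::write.csv(per_split, file.path(out_dir, "per_split_metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(report$models, function(m) {
      list(cif = m$cif, intercept = m$intercept,
           coefficients = as.list(m$coefficients),
           n_train = m$n_train, bic = m$bic,
           log_likelihood = m$log_likelihood)
    }),
    file.path(out_dir, "models.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    lapply(report$curves, function(cv) {
      list(steps = cv$steps, base_rate = cv$base_rate,
           delta = cv$delta, constant = cv$constant)
    }),
    file.path(out_dir, "calibration_curves.json"),
    auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.cif_run_report <- function(x, ...) {
  cat("CIF quality-risk run report\n")
  cat("  selection window:", paste(range(x$provenance$selection_years),
                                   collapse = "-"), "\n\n")
  perf <- x$performance
  for (i in seq_len(nrow(perf))) {
    cat(sprintf(
      "  %-30s %d features | AUC %.2f +/- %.2f | Brier %.3f +/- %.3f | calibrated %.0f-%.0f%% (delta %.0f%%) | base rate %.0f%%\n",
      perf$cif[i], perf$n_features[i], perf$mean_auc[i], perf$se_auc[i],
      perf$mean_brier[i], perf$se_brier[i],
      100 * perf$calibrated_min[i], 100 * perf$calibrated_max[i],
      100 * perf$delta[i], 100 * perf$base_rate[i]))
  }
  invisible(x)
}
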