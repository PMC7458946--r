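#' Binary outcome for one CIF
#'
#' The modeled target is the absence or presence of any number of findings:
#' 1 iff the activity has one or more findings of the given CIF.
#'
#' @param activities Activity table with a `findings_<cif>` column.
#' @param cif One of [cif_names()].
#' @return Data frame with `activity_id`, `cif`, `present` (0/1).
#' @export
make_binary_outcome <- function(activities, cif) {
  cif <- match.arg(cif, cif_names())
  col <- paste0("findings_", cif)
  if (!col %in% names(activities)) stop("missing column: ", col)
  counts <- activities[[col]]
  if (any(counts < 0)) stop("finding counts must be non-negative")
  data.frame(activity_id = activities$activity_id, cif = cif,
             present = as.integer(counts >= 1), stringsAsFactors = FALSE)
}

#' Fit a logistic regression for one CIF
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares (`stats::glm`, binomial family), with an explicit convergence
#' check (score norm below `1e-8` relative to n) and detection of perfect
#' separation. No regularization is used; the feature set is small and
#' hand-crafted, and penalized fits were deliberately avoided because they
#' absorb noise under a low signal-to-noise ratio.
#'
#' @param X A `"binary_feature_matrix"` (or 0/1 matrix) restricted to the
#'   candidate features; may have zero columns (null model).
#' @param y 0/1 outcome vector (or the `present` column of
#'   [make_binary_outcome()] output), same length as rows of `X`.
#' @param cif CIF label stored on the model (default `"unspecified"`).
#' @param train_years Optional year range metadata.
#' @return Object of class `"cif_model"`: `cif`, `intercept`,
#'   `coefficients` (named log-odds), `n_train`, `train_years`,
#'   `log_likelihood` and `bic` (`k log n - 2 logLik`, `k` counting the
#'   intercept).
#' @export
fit_logistic <- function(X, y, cif = "unspecified", train_years = NULL) {
  v <- if (inherits(X, "binary_feature_matrix")) X$values else X
  if (is.data.frame(y)) y <- y$present
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(v) == n || ncol(v) == 0)
  if (ncol(v) > 0) {
    const <- apply(v, 2, function(x) stats::sd(x) == 0)
    if (any(const)) stop("constant feature(s) in design: ",
                         paste(colnames(v)[const], collapse = ", "))
    if (n <= ncol(v) + 1) stop("more parameters than observations")
  }
  df <- data.frame(y = y, v, check.names = FALSE)
  form <- if (ncol(v)) stats::reformulate(sprintf("`%s`", colnames(v)),
                                          response = "y")
          else y ~ 1
  sep_warn <- FALSE
  fit <- withCallsHandlers_glm(form, df, function() sep_warn <<- TRUE)
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("aliased (collinear) feature(s): ",
                      paste(names(cf)[is.na(cf)], collapse = ", "))
  # score (gradient) of the Bernoulli log-likelihood at the optimum
  p <- stats::fitted(fit)
  design <- cbind(`(Intercept)` = 1, v)
  grad <- as.numeric(crossprod(design, y - p))
  if (sep_warn && max(abs(cf[-1]), 0) > 10) {
    worst <- names(cf[-1])[which.max(abs(cf[-1]))]
    stop("perfect separation detected; separating feature: ", worst)
  }
  if (!fit$converged) {
    stop("IRLS did not converge after ", fit$iter, " iterations")
  }
  if (max(abs(grad)) > 1e-8 * max(1, n)) {
    stop("gradient norm ", signif(max(abs(grad)), 3),
         " above tolerance after ", fit$iter, " iterations")
  }
  ll <- as.numeric(stats::logLik(fit))
  k <- length(cf)
  coefs <- cf[-1]
  names(coefs) <- colnames(v)
  new_cif_model(cif = cif, intercept = unname(cf[1]), coefficients = coefs,
                n_train = n, train_years = train_years,
                log_likelihood = ll, bic = k * log(n) - 2 * ll)
}

withCallsHandlers_glm <- function(form, df, on_sep) {
  withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        on_sep()
        invokeRestart("muffleWarning")
      }
    })
}

new_cif_model <- function(cif, intercept, coefficients, n_train, train_years,
                          log_likelihood, bic) {
  structure(list(cif = cif, intercept = intercept,
                 coefficients = coefficients, n_train = n_train,
                 train_years = train_years, log_likelihood = log_likelihood,
                 bic = bic),
            class = "cif_model")
}

#' @export
print.cif_model <- function(x, ...) {
  cat("CIF logistic model:", x$cif, "\n")
  cat(sprintf("  n = %d, logLik = %.3f, BIC = %.3f\n",
              x$n_train, x$log_likelihood, x$bic))
  cat(sprintf("  intercept = %.4f\n", x$intercept))
  if (length(x$coefficients)) {
    for (nm in names(x$coefficients)) {
      cat(sprintf("  %-32s %+.4f\n", nm, x$coefficients[[nm]]))
    }
  } else cat("  (no features selected)\n")
  invisible(x)
}

#' Greedy forward feature selection minimizing BIC
#'
#' Starting from the null (intercept-only) model, repeatedly adds the
#' candidate feature whose inclusion lowers the BIC the most, stopping when
#' no candidate lowers it. Candidate pairs flagged by the collinearity
#' screen (|Pearson r| above `corr_threshold`) are never co-selected. The
#' search is deterministic: candidates are scanned in alphabetical order and
#' ties are broken toward the alphabetically first name.
#'
#' @param X A `"binary_feature_matrix"` covering the training rows (the
#'   selection window, e.g. 2011--2015).
#' @param y 0/1 outcomes aligned with `X`.
#' @param candidates Candidate feature names (default: all columns of `X`).
#' @param cif,train_years Metadata stored on the returned model.
#' @param corr_threshold Collinearity screen threshold (default 0.3).
#' @return A `"cif_model"`; the null model (with a warning) if the candidate
#'   set is empty.
#' @export
select_features_bic <- function(X, y, candidates = NULL, cif = "unspecified",
                                train_years = NULL, corr_threshold = 0.3) {
  v <- if (inherits(X, "binary_feature_matrix")) X$values else X
  if (is.data.frame(y)) y <- y$present
  if (is.null(candidates)) candidates <- colnames(v)
  candidates <- sort(intersect(candidates, colnames(v)))
  null_model <- fit_logistic(v[, character(0), drop = FALSE], y, cif = cif,
                             train_years = train_years)
  if (length(candidates) == 0) {
    warning("empty candidate set; returning the null model")
    return(null_model)
  }
  flagged <- flagged_pairs(v[, candidates, drop = FALSE], corr_threshold)
  conflicts <- function(feat, selected) {
    any(vapply(flagged, function(p) feat %in% p && any(selected %in% p),
               logical(1)))
  }
  selected <- character(0)
  best <- null_model
  repeat {
    pool <- setdiff(candidates, selected)
    pool <- pool[!vapply(pool, conflicts, logical(1), selected = selected)]
    pool <- pool[vapply(pool, function(f) stats::sd(v[, f]) > 0, logical(1))]
    if (length(pool) == 0) break
    bics <- vapply(pool, function(f) {
      fit_logistic(v[, c(selected, f), drop = FALSE], y)$bic
    }, numeric(1))
    if (min(bics) >= best$bic) break
    add <- pool[which.min(bics)]  # pool is sorted: ties go alphabetical
    selected <- sort(c(selected, add))
    best <- fit_logistic(v[, selected, drop = FALSE], y, cif = cif,
                         train_years = train_years)
  }
  best
}

#' Refit a selected model on the full dataset
#'
#' Keeps the feature set chosen on the early training window and
#' re-estimates the coefficients on all years, giving the final coefficient
#' values.
#'
#' @param selected A `"cif_model"` from [select_features_bic()].
#' @param X_full Feature matrix over all activities.
#' @param y_full Outcomes aligned with `X_full`.
#' @param train_years Optional year range metadata for the refit.
#' @return A `"cif_model"` with the same features, refit coefficients.
#' @export
refit_on_all_data <- function(selected, X_full, y_full, train_years = NULL) {
  v <- if (inherits(X_full, "binary_feature_matrix")) X_full$values else X_full
  feats <- names(selected$coefficients)
  missing_f <- setdiff(feats, colnames(v))
  if (length(missing_f)) {
    stop("selected feature(s) absent from the full feature matrix: ",
         paste(missing_f, collapse = ", "))
  }
  fit_logistic(v[, feats, drop = FALSE], y_full, cif = selected$cif,
               train_years = train_years)
}

#' Predicted probability of at least one finding
#'
#' The risk carried by the coefficients is additive on the log-odds scale:
#' `plogis(intercept + sum(coef * x))`.
#'
#' @param model A `"cif_model"`.
#' @param x Named 0/1 vector, or a matrix / `"binary_feature_matrix"` with
#'   one row per activity; must contain every model feature.
#' @return Probability (vector) in (0, 1).
#' @export
predict_probability <- function(model, x) {
  v <- if (inherits(x, "binary_feature_matrix")) x$values
       else if (is.matrix(x)) x
       else matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  feats <- names(model$coefficients)
  missing_f <- setdiff(feats, colnames(v))
  if (length(missing_f)) stop("missing feature(s) in input: ",
                              paste(missing_f, collapse = ", "))
  lin <- model$intercept +
    if (length(feats)) as.numeric(v[, feats, drop = FALSE] %*%
                                    model$coefficients)
    else rep(0, nrow(v))
  stats::plogis(lin)
}

#' Coefficient table across CIF models
#'
#' @param models List of `"cif_model"`s (one per CIF).
#' @return Data frame with columns `cif`, `feature` (including
#'   `"(Intercept)"`), `estimate` — the final coefficient summary of the
#'   analysis.
#' @export
coefficient_table <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    data.frame(cif = m$cif,
               feature = c("(Intercept)", names(m$coefficients)),
               estimate = c(m$intercept, unname(m$coefficients)),
               stringsAsFactors = FALSE)
  }))
}
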