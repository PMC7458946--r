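#' Yeo-Johnson power transformation with ML-estimated lambda
#'
#' Transforms a continuous feature toward symmetry before quantile binning.
#' The Yeo-Johnson family extends the Box-Cox transform to non-positive
#' values: for x >= 0 it is ((x+1)^lambda - 1)/lambda (log(x+1) at
#' lambda = 0), and for x < 0 it is -(((-x+1)^(2-lambda) - 1))/(2-lambda)
#' (-log(-x+1) at lambda = 2). `lambda` is chosen by maximizing the profile
#' log-likelihood of a normal model over \[-3, 3\] (golden-section search),
#' and the transformed values are standardized to mean 0, variance 1.
#'
#' @param values Numeric vector with at least 2 distinct finite values.
#' @param lambda Optional fixed lambda; if `NULL` (default) it is estimated.
#' @param standardize Center and scale the output (default `TRUE`).
#' @return List with `transformed` (numeric vector) and `lambda`.
#' @export
#' @examples
#' yeo_johnson_transform(rlnorm(100))$lambda  # < 1 for right-skewed input
yeo_johnson_transform <- function(values, lambda = NULL, standardize = TRUE) {
  x <- values
  finite <- x[is.finite(x)]
  if (length(unique(finite)) < 2) {
    stop("cannot standardize a constant input")
  }
  if (is.null(lambda)) {
    ll <- function(lam) {
      z <- yj_apply(finite, lam)
      n <- length(z)
      # profile normal log-likelihood plus the Jacobian of the transform
      -n / 2 * log(mean((z - mean(z))^2)) +
        (lam - 1) * sum(sign(finite) * log1p(abs(finite)))
    }
    lambda <- stats::optimize(ll, interval = c(-3, 3), maximum = TRUE)$maximum
  }
  z <- yj_apply(x, lambda)
  if (standardize) {
    zf <- z[is.finite(z)]
    z <- (z - mean(zf)) / stats::sd(zf)
  }
  list(transformed = z, lambda = lambda)
}

yj_apply <- function(x, lambda) {
  out <- x
  pos <- !is.na(x) & x >= 0
  if (abs(lambda) > 1e-10) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(x[pos])
  }
  neg <- !is.na(x) & x < 0
  if (abs(lambda - 2) > 1e-10) {
    out[neg] <- -((-x[neg] + 1)^(2 - lambda) - 1) / (2 - lambda)
  } else {
    out[neg] <- -log1p(-x[neg])
  }
  out
}

#' Bin values into quantile segments
#'
#' Assigns each value to one of `n_segments` ordered segments with
#' boundaries at the empirical quantiles i/n_segments (inclusive lower /
#' exclusive upper, final segment closed). Intended for Yeo-Johnson
#' transformed features, but rank-based, so the segment of each observation
#' is invariant to any monotone transform.
#'
#' @param values Numeric vector.
#' @param n_segments Number of segments (default 5).
#' @return Ordered factor with levels `"seg1" < ... < "segk"`. If there are
#'   fewer distinct quantile boundaries than segments, bins collapse to the
#'   distinct boundaries with a warning.
#' @export
bin_into_segments <- function(values, n_segments = 5L) {
  stopifnot(n_segments >= 2)
  probs <- seq(0, 1, length.out = n_segments + 1)
  breaks <- stats::quantile(values, probs = probs, na.rm = TRUE, names = FALSE)
  ub <- unique(breaks)
  if (length(ub) < length(breaks)) {
    warning("fewer distinct values than segments; collapsing to ",
            max(1, length(ub) - 1), " bin(s)")
    breaks <- ub
  }
  if (length(breaks) < 2) {
    # all values identical: a single degenerate segment
    return(factor(rep("seg1", length(values)), levels = "seg1",
                  ordered = TRUE))
  }
  k <- length(breaks) - 1
  labs <- paste0("seg", seq_len(k))
  cut(values, breaks = breaks, labels = labs, include.lowest = TRUE,
      right = TRUE, ordered_result = TRUE)
}

#' Pool rare categorical levels into "other"
#'
#' Levels applying to less than `threshold` of the observations are replaced
#' by the pooled level `"other"`, so near-zero-variance indicators are never
#' produced downstream. The pooled level may itself remain below the
#' threshold when it is the only rare mass.
#'
#' @param labels Character or factor vector (NAs kept as NA).
#' @param threshold Prevalence threshold (default 0.05).
#' @return Character vector with rare levels pooled.
#' @export
group_rare_levels <- function(labels, threshold = 0.05) {
  x <- as.character(labels)
  stopifnot(length(x) > 0)
  tab <- table(x) / sum(!is.na(x))
  rare <- names(tab)[tab < threshold]
  x[x %in% rare] <- "other"
  x
}

#' Binarize a categorical feature
#'
#' Indicator of membership in `positive_levels`; missing values map to 0
#' (missing is treated as "no").
#'
#' @param labels Character or factor vector.
#' @param positive_levels Non-empty set of levels coded as 1.
#' @return Integer 0/1 vector.
#' @export
binarize <- function(labels, positive_levels) {
  stopifnot(length(positive_levels) > 0)
  x <- as.character(labels)
  out <- as.integer(!is.na(x) & x %in% as.character(positive_levels))
  out
}

#' Within-study site burden score
#'
#' Ranks the sites of one study by how many other sponsor trials in the same
#' therapeutic area run concurrently at the site, and converts the rank to a
#' cumulative-distribution rank in (0, 1]: score = average-tie rank / number
#' of sites. Higher score means more parallel trials at the site.
#'
#' @param sites_of_one_study Data frame of the sites of a single study, with
#'   columns `site_id`, `study_id`, `parallel_trials_same_ta`.
#' @return Data frame with `site_id`, `study_id`, `score`.
#' @export
#' @examples
#' s <- data.frame(site_id = letters[1:4], study_id = "S1",
#'                 parallel_trials_same_ta = c(0, 2, 2, 5))
#' site_burden_score(s)$score  # 0.25 0.625 0.625 1.0
site_burden_score <- function(sites_of_one_study) {
  s <- sites_of_one_study
  stopifnot(nrow(s) >= 1, length(unique(s$study_id)) == 1)
  r <- rank(s$parallel_trials_same_ta, ties.method = "average")
  data.frame(site_id = s$site_id, study_id = s$study_id,
             score = r / nrow(s), stringsAsFactors = FALSE)
}

#' Randomization-by-design interaction flags
#'
#' The one interaction hand-crafted into the models: non-randomized studies
#' carry different sponsor-oversight risk depending on design, so
#' randomization and design are combined into two mutually exclusive binary
#' features.
#'
#' @param randomized Logical vector.
#' @param design Character vector with levels among
#'   `parallel, sequential, single_group, crossover`.
#' @return List with integer 0/1 vectors `nonrand_parallel_or_sequential`
#'   (non-randomized and parallel or sequential design) and
#'   `nonrand_single_group` (non-randomized single-group design). At most
#'   one flag is 1 for any record.
#' @export
interaction_randomization_design <- function(randomized, design) {
  valid <- c("parallel", "sequential", "single_group", "crossover")
  bad <- setdiff(unique(design[!is.na(design)]), valid)
  if (length(bad)) stop("invalid design level(s): ", paste(bad, collapse = ", "))
  nr <- !is.na(randomized) & !randomized
  list(
    nonrand_parallel_or_sequential =
      as.integer(nr & design %in% c("parallel", "sequential")),
    nonrand_single_group = as.integer(nr & design == "single_group")
  )
}

#' Declare a binary feature
#'
#' A feature spec names one engineered 0/1 column of the model matrix and
#' the rule producing it from the joined activity/study/site table.
#'
#' @param name Unique feature name.
#' @param kind One of:
#'   * `"binary_level"` — indicator of `levels` of a categorical
#'     `source_column` (rare levels pooled first when `group_rare = TRUE`);
#'   * `"threshold"` — indicator `source_column <op> value` with `op` in
#'     `gt, ge, lt, le`;
#'   * `"binned_segment"` — Yeo-Johnson transform of `source_column`,
#'     quantile-binned into `n_segments`, indicator of the segments listed
#'     in `segments`;
#'   * `"burden_score_band"` — indicator `site burden score <op> value`
#'     (the score is computed per study from `parallel_trials_same_ta`);
#'   * `"flag"` — a logical `source_column` used directly;
#'   * `"interaction"` — one of the two randomization-by-design flags,
#'     chosen by `which`.
#' @param source_column Column of the joined table the rule reads (ignored
#'   for `burden_score_band` and `interaction`).
#' @param value,op Threshold parameters.
#' @param levels Positive levels for `binary_level`.
#' @param n_segments,segments Binning parameters for `binned_segment`.
#' @param which For `interaction`: `"nonrand_parallel_or_sequential"` or
#'   `"nonrand_single_group"`.
#' @param group_rare Pool rare levels before binarizing (default `TRUE`).
#' @return A list of class `"feature_spec"`.
#' @export
feature_spec <- function(name, kind, source_column = NULL, value = NULL,
                         op = "gt", levels = NULL, n_segments = 5L,
                         segments = NULL, which = NULL, group_rare = TRUE) {
  kind <- match.arg(kind, c("binary_level", "threshold", "binned_segment",
                            "burden_score_band", "flag", "interaction"))
  if (kind %in% c("binary_level", "threshold", "binned_segment", "flag") &&
      is.null(source_column)) {
    stop("feature spec '", name, "': source_column is required for kind ",
         kind)
  }
  if (kind %in% c("threshold", "burden_score_band") && is.null(value)) {
    stop("feature spec '", name, "': value is required")
  }
  if (kind == "binary_level" && is.null(levels)) {
    stop("feature spec '", name, "': levels is required")
  }
  if (kind == "binned_segment" && is.null(segments)) {
    stop("feature spec '", name, "': segments is required")
  }
  if (kind == "interaction") {
    which <- match.arg(which, c("nonrand_parallel_or_sequential",
                                "nonrand_single_group"))
  }
  structure(list(name = name, kind = kind, source_column = source_column,
                 value = value, op = match.arg(op, c("gt", "ge", "lt", "le")),
                 levels = levels, n_segments = n_segments,
                 segments = segments, which = which, group_rare = group_rare),
            class = "feature_spec")
}

apply_threshold <- function(x, op, value) {
  out <- switch(op,
                gt = x > value, ge = x >= value,
                lt = x < value, le = x <= value)
  out[is.na(out)] <- FALSE  # missing maps to "no"
  as.integer(out)
}

eval_feature_spec <- function(spec, d, rare_threshold) {
  get_col <- function() {
    if (is.null(spec$source_column) || !spec$source_column %in% names(d)) {
      stop("feature spec '", spec$name, "' cannot be resolved: column '",
           spec$source_column %||% "<null>", "' not found")
    }
    d[[spec$source_column]]
  }
  switch(spec$kind,
    binary_level = {
      x <- as.character(get_col())
      if (isTRUE(spec$group_rare)) x <- group_rare_levels(x, rare_threshold)
      binarize(x, spec$levels)
    },
    threshold = apply_threshold(get_col(), spec$op, spec$value),
    binned_segment = {
      x <- get_col()
      tr <- yeo_johnson_transform(x)$transformed
      seg <- bin_into_segments(tr, spec$n_segments)
      binarize(seg, paste0("seg", spec$segments))
    },
    burden_score_band = {
      need <- c("site_id", "study_id", "parallel_trials_same_ta")
      if (!all(need %in% names(d))) {
        stop("feature spec '", spec$name,
             "' cannot be resolved: burden score needs columns ",
             paste(setdiff(need, names(d)), collapse = ", "))
      }
      us <- unique(d[c("site_id", "study_id", "parallel_trials_same_ta")])
      sc <- do.call(rbind, lapply(split(us, us$study_id), site_burden_score))
      key <- paste(d$site_id, d$study_id)
      score <- sc$score[match(key, paste(sc$site_id, sc$study_id))]
      apply_threshold(score, spec$op, spec$value)
    },
    flag = {
      x <- get_col()
      as.integer(!is.na(x) & as.logical(x))
    },
    interaction = {
      inter <- interaction_randomization_design(d$randomized, d$design)
      inter[[spec$which]]
    })
}

#' Default feature specifications
#'
#' The hand-crafted binary features considered for the CIF models: study
#' attributes (US site, pediatric, therapeutic-area and phase indicators),
#' site operational thresholds (enrollment below 5 / above 32 patients,
#' screen-failure rate above 0.62, long active screening duration per
#' enrolled patient, AE reporting within 2 days, 3+ parallel trials in the
#' same therapeutic area), a high site-burden band, and the two
#' randomization-by-design interaction flags.
#'
#' @return List of [feature_spec()] objects.
#' @export
default_feature_specs <- function() {
  list(
    feature_spec("us_site", "binary_level", "country", levels = "US"),
    feature_spec("pediatric", "flag", "pediatric"),
    feature_spec("oncology", "binary_level", "therapeutic_area",
                 levels = "oncology"),
    feature_spec("autoimmune", "binary_level", "therapeutic_area",
                 levels = "autoimmune"),
    feature_spec("neuro_psych", "binary_level", "therapeutic_area",
                 levels = "neuroscience_psychiatry"),
    feature_spec("phase_1", "binary_level", "phase", levels = "I"),
    feature_spec("enrolled_lt_5", "threshold", "patients_enrolled",
                 value = 5, op = "lt"),
    feature_spec("enrolled_gt_32", "threshold", "patients_enrolled",
                 value = 32, op = "gt"),
    feature_spec("screen_failure_gt_0.62", "threshold", "screen_failure_rate",
                 value = 0.62, op = "gt"),
    feature_spec("long_screening", "threshold",
                 "active_screening_days_per_enrolled", value = 34, op = "gt"),
    feature_spec("ae_timely", "threshold", "ae_reporting_latency_days",
                 value = 2, op = "le"),
    feature_spec("multiple_parallel_trials", "threshold",
                 "parallel_trials_same_ta", value = 3, op = "ge"),
    feature_spec("high_site_burden", "burden_score_band", value = 0.75,
                 op = "gt"),
    feature_spec("nonrand_parallel_or_sequential", "interaction",
                 which = "nonrand_parallel_or_sequential"),
    feature_spec("nonrand_single_group", "interaction",
                 which = "nonrand_single_group")
  )
}

#' Build the binary feature matrix
#'
#' Joins the three input tables on study and site identifiers, evaluates
#' every feature spec, imputes missing source values to 0 ("no") and drops
#' any feature whose prevalence falls below the rare-level threshold (with a
#' warning) — the models only ever see 0/1 columns with at least 5% support.
#'
#' @param activities,studies,sites Input tables (see [generate_dataset()]
#'   for the schema).
#' @param specs List of [feature_spec()]s, names unique.
#' @param rare_threshold Minimum feature prevalence (default 0.05).
#' @return Object of class `"binary_feature_matrix"`: list with
#'   `activity_ids`, `feature_names`, `values` (0/1 matrix, rows in activity
#'   order) and `prevalence`.
#' @export
build_feature_matrix <- function(activities, studies, sites,
                                 specs = default_feature_specs(),
                                 rare_threshold = 0.05) {
  nm <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate feature names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  d <- join_tables(activities, studies, sites)
  cols <- lapply(specs, eval_feature_spec, d = d,
                 rare_threshold = rare_threshold)
  values <- if (length(cols)) {
    matrix(unlist(cols), nrow = nrow(d), dimnames = list(d$activity_id, nm))
  } else {
    matrix(integer(0), nrow = nrow(d), ncol = 0,
           dimnames = list(d$activity_id, NULL))
  }
  prevalence <- if (ncol(values)) colMeans(values) else numeric(0)
  drop <- prevalence < rare_threshold
  if (any(drop)) {
    warning("dropping feature(s) below the ", rare_threshold,
            " prevalence threshold: ",
            paste(sprintf("%s (%.3f)", nm[drop], prevalence[drop]),
                  collapse = ", "))
    values <- values[, !drop, drop = FALSE]
    prevalence <- prevalence[!drop]
  }
  structure(list(activity_ids = d$activity_id,
                 feature_names = colnames(values),
                 values = values,
                 prevalence = prevalence),
            class = "binary_feature_matrix")
}

#' Strongest pairwise feature correlation
#'
#' Pearson correlation over all pairs of feature columns; constant columns
#' are excluded with a warning. The analysis uses this as a collinearity
#' screen: pairs above the threshold are never co-selected into a model.
#'
#' @param matrix A `"binary_feature_matrix"` or plain numeric matrix.
#' @return List with `value` (maximum absolute correlation) and `pair`
#'   (the two feature names attaining it).
#' @export
max_abs_pairwise_correlation <- function(matrix) {
  v <- if (inherits(matrix, "binary_feature_matrix")) matrix$values else matrix
  keep <- apply(v, 2, function(x) stats::sd(x) > 0)
  if (any(!keep)) {
    warning("excluding constant feature(s): ",
            paste(colnames(v)[!keep], collapse = ", "))
    v <- v[, keep, drop = FALSE]
  }
  if (ncol(v) < 2) stop("need at least 2 non-constant features")
  cm <- stats::cor(v)
  diag(cm) <- 0
  idx <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
  list(value = abs(cm[idx[1], idx[2]]),
       pair = colnames(v)[c(idx[1], idx[2])])
}

# pairs of candidate features whose |Pearson r| exceeds the screen threshold
flagged_pairs <- function(values, threshold = 0.3) {
  keep <- apply(values, 2, function(x) stats::sd(x) > 0)
  v <- values[, keep, drop = FALSE]
  if (ncol(v) < 2) return(list())
  cm <- stats::cor(v)
  out <- list()
  nm <- colnames(v)
  for (i in seq_len(ncol(v) - 1)) {
    for (j in seq(i + 1, ncol(v))) {
      if (abs(cm[i, j]) > threshold) out[[length(out) + 1]] <- c(nm[i], nm[j])
    }
  }
  out
}
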