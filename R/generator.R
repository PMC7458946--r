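#' Configuration for the synthetic audit-data generator
#'
#' Builds a validated configuration for [generate_dataset()]. The defaults
#' emulate the published descriptive statistics of a large sponsor's
#' 2011--2018 good-clinical-practice quality-assurance dataset: about 86.7
#' audit/inspection activities per year over 8 years, roughly 13% of them
#' inspections, 5.9 findings per activity on average, and per-CIF rates of
#' activities with at least one finding of 55% (consent), 84% (data
#' integrity), 86% (protecting primary endpoints), 59% (safety) and 76%
#' (sponsor oversight).
#'
#' The generator plants a known risk structure: for each CIF, the presence of
#' one or more findings is Bernoulli with probability
#' `plogis(intercept + sum(true_coefficients * ground-truth features))`,
#' where the intercept is solved numerically so that the marginal presence
#' rate equals the configured base rate. Ground-truth features are binary
#' indicators computed from the simulated study and site profiles (see
#' [ground_truth_features()]).
#'
#' @param n_years Number of calendar years, starting at `first_year`.
#' @param first_year First calendar year of the span.
#' @param audits_per_year Expected number of activities per year (Poisson).
#' @param inspection_fraction Probability an activity is an inspection
#'   rather than an audit; inspections carry no separate risk effect
#'   (audits and inspections are pooled in the analysis).
#' @param mean_findings_per_audit Target mean total findings per activity,
#'   across all five CIFs. Must be at least `sum(cif_base_rates)` since each
#'   positive CIF contributes at least one finding.
#' @param cif_base_rates Named vector of per-CIF marginal presence rates,
#'   all strictly in (0, 1), names exactly [cif_names()].
#' @param n_studies Number of studies in the portfolio.
#' @param sites_per_study Integer range (length 2) of sites per study,
#'   sampled uniformly.
#' @param study_persistence Probability a study stops being auditable after
#'   each year; auditable duration is 1 + Geometric(study_persistence), so
#'   some studies are audited in several years (this is what makes the
#'   prior-audit exclusion rule of the cross-validation non-trivial).
#' @param true_coefficients Named list mapping CIF to a named numeric vector
#'   of log-odds coefficients on ground-truth features. Use
#'   `default_true_coefficients()` (the default) for effects mirroring the
#'   risk factors reported for the real dataset, or
#'   `null_true_coefficients()` for a pure-noise dataset.
#' @param feature_marginals Named vector of theoretical prevalences of the
#'   ground-truth features, each in \[0.05, 0.95\]; used by
#'   [intercept_for_base_rate()] for the independent-Bernoulli form of the
#'   intercept calculation.
#' @param seed Integer seed; fixing it fixes every output table bit-for-bit.
#'
#' @return A list of class `"generator_config"`.
#' @seealso [generate_dataset()], [intercept_for_base_rate()]
#' @export
generator_config <- function(n_years = 8L,
                             first_year = 2011L,
                             audits_per_year = 86.7,
                             inspection_fraction = 0.13,
                             mean_findings_per_audit = 5.9,
                             cif_base_rates = c(
                               consent = 0.55,
                               data_integrity = 0.84,
                               protecting_primary_endpoints = 0.86,
                               safety = 0.59,
                               sponsor_oversight = 0.76),
                             n_studies = 120L,
                             sites_per_study = c(2L, 6L),
                             study_persistence = 0.4,
                             true_coefficients = default_true_coefficients(),
                             feature_marginals = default_feature_marginals(),
                             seed = 1L) {
  stopifnot(n_years >= 1, audits_per_year > 0,
            inspection_fraction >= 0, inspection_fraction <= 1,
            mean_findings_per_audit > 0,
            n_studies >= 2, length(sites_per_study) == 2,
            sites_per_study[1] >= 1, sites_per_study[2] >= sites_per_study[1],
            study_persistence > 0, study_persistence <= 1)
  if (!setequal(names(cif_base_rates), cif_names())) {
    stop("cif_base_rates must be named exactly by cif_names()")
  }
  cif_base_rates <- cif_base_rates[cif_names()]
  if (any(cif_base_rates <= 0) || any(cif_base_rates >= 1)) {
    stop("all base rates must be strictly in (0, 1)")
  }
  if (mean_findings_per_audit < sum(cif_base_rates)) {
    stop("infeasible configuration: mean_findings_per_audit (",
         mean_findings_per_audit, ") is below the sum of CIF base rates (",
         round(sum(cif_base_rates), 3),
         "); each positive CIF contributes at least one finding")
  }
  if (any(feature_marginals < 0.05) || any(feature_marginals > 0.95)) {
    stop("all feature marginals must lie in [0.05, 0.95]")
  }
  if (!setequal(names(true_coefficients), cif_names())) {
    stop("true_coefficients must be a list named by cif_names()")
  }
  for (cf in cif_names()) {
    unknown <- setdiff(names(true_coefficients[[cf]]), names(feature_marginals))
    if (length(unknown)) {
      stop("true coefficient on unknown ground-truth feature: ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(list(
    n_years = as.integer(n_years),
    first_year = as.integer(first_year),
    audits_per_year = audits_per_year,
    inspection_fraction = inspection_fraction,
    mean_findings_per_audit = mean_findings_per_audit,
    cif_base_rates = cif_base_rates,
    n_studies = as.integer(n_studies),
    sites_per_study = as.integer(sites_per_study),
    study_persistence = study_persistence,
    true_coefficients = true_coefficients[cif_names()],
    feature_marginals = feature_marginals,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Default ground-truth coefficients
#'
#' Log-odds effects planted in the synthetic data, chosen to mirror the
#' direction of the risk factors reported for the real dataset: e.g. higher
#' consent risk for US sites and pediatric studies, lower data-integrity
#' risk for small sites with timely AE reporting, higher safety risk in
#' oncology, lower sponsor-oversight risk for non-randomized designs.
#'
#' @return Named list (by CIF) of named numeric vectors of log-odds.
#' @export
default_true_coefficients <- function() {
  list(
    consent = c(us_site = 0.5, pediatric = 0.7, autoimmune = -0.6,
                long_screening = -0.5),
    data_integrity = c(enrolled_lt_5 = -0.6, screen_failure_gt_0.62 = -0.5,
                       multiple_parallel_trials = 0.5, ae_timely = -0.6),
    protecting_primary_endpoints = c(phase_1 = 0.6, neuro_psych = 0.6,
                                     autoimmune = -0.5,
                                     multiple_parallel_trials = 0.5,
                                     screen_failure_gt_0.62 = -0.5,
                                     enrolled_gt_32 = -0.5),
    safety = c(oncology = 0.7, ae_timely = -0.7),
    sponsor_oversight = c(nonrand_parallel_or_sequential = -0.8,
                          nonrand_single_group = -0.4,
                          screen_failure_gt_0.62 = -0.5,
                          enrolled_gt_32 = -0.5)
  )
}

#' All-zero ground-truth coefficients (pure-noise dataset)
#' @return Named list (by CIF) of empty numeric vectors.
#' @export
null_true_coefficients <- function() {
  stats::setNames(lapply(cif_names(), function(x) numeric(0)), cif_names())
}

#' Theoretical prevalences of the ground-truth features
#'
#' Implied by the covariate distributions used by [generate_dataset()]:
#' categorical study attributes with fixed level probabilities, negative
#' binomial enrollment (size 2, mean 20), Beta(2, 3) screen-failure rate,
#' log-normal screening duration and AE-reporting latency, Poisson(2)
#' parallel-trial count. All lie in \[0.05, 0.95\] so every engineered
#' feature passes the 5% rare-level rule by construction.
#'
#' @return Named numeric vector of prevalences.
#' @export
default_feature_marginals <- function() {
  c(us_site = 0.55,
    pediatric = 0.12,
    oncology = 0.50,
    autoimmune = 0.20,
    neuro_psych = 0.15,
    phase_1 = 0.15,
    enrolled_lt_5 = stats::pnbinom(4, size = 2, mu = 20),
    enrolled_gt_32 = stats::pnbinom(32, size = 2, mu = 20,
                                    lower.tail = FALSE),
    screen_failure_gt_0.62 = stats::pbeta(0.62, 2, 3, lower.tail = FALSE),
    long_screening = stats::plnorm(34, 3, 0.8, lower.tail = FALSE),
    ae_timely = stats::plnorm(2, 0.5, 0.7),
    multiple_parallel_trials = stats::ppois(2, 2, lower.tail = FALSE),
    nonrand_parallel_or_sequential = 0.3 * 0.40,
    nonrand_single_group = 0.3 * 0.50)
}

#' Solve the logistic intercept that hits a target marginal rate
#'
#' Finds `b` such that the population-average probability
#' `E[plogis(b + x %*% coefficients)]` equals `target_rate`, where the
#' binary features `x` are independent Bernoulli with the given marginals.
#' The expectation is computed by exact enumeration over the joint support
#' of the features carrying non-zero coefficients (at most 2^k points), and
#' the root is found by [stats::uniroot()] to within 1e-6.
#'
#' @param target_rate Target marginal probability, strictly in (0, 1).
#' @param coefficients Named numeric vector of log-odds coefficients (may be
#'   empty, giving the closed-form `qlogis(target_rate)`).
#' @param feature_marginals Named vector of Bernoulli prevalences covering
#'   every coefficient name.
#' @return The intercept (log-odds scale).
#' @export
#' @examples
#' intercept_for_base_rate(0.5, numeric(0), numeric(0))   # 0
#' intercept_for_base_rate(0.84, numeric(0), numeric(0))  # log(.84/.16)
intercept_for_base_rate <- function(target_rate, coefficients,
                                    feature_marginals) {
  stopifnot(target_rate > 0, target_rate < 1)
  coefficients <- coefficients[coefficients != 0]
  if (length(coefficients) == 0) return(stats::qlogis(target_rate))
  missing_m <- setdiff(names(coefficients), names(feature_marginals))
  if (length(missing_m)) {
    stop("no marginal prevalence for feature(s): ",
         paste(missing_m, collapse = ", "))
  }
  if (length(coefficients) > 20) {
    stop("enumeration over >20 features is not supported")
  }
  p <- feature_marginals[names(coefficients)]
  # enumerate the 2^k binary support with cell probabilities
  grid <- as.matrix(expand.grid(rep(list(0:1), length(coefficients))))
  lin <- as.numeric(grid %*% coefficients)
  cellp <- apply(grid, 1, function(x) prod(ifelse(x == 1, p, 1 - p)))
  f <- function(b) sum(cellp * stats::plogis(b + lin)) - target_rate
  stats::uniroot(f, lower = -30, upper = 30, tol = 1e-9)$root
}

# intercept solved against realized feature rows rather than theoretical
# marginals: exact for the generated dataset whatever the covariate
# dependence structure is
intercept_for_rows <- function(target_rate, lin_predictor) {
  f <- function(b) mean(stats::plogis(b + lin_predictor)) - target_rate
  stats::uniroot(f, lower = -30, upper = 30, tol = 1e-9)$root
}

#' Ground-truth binary features of each activity
#'
#' The fixed-threshold indicators the generator uses as the true risk
#' drivers: study attributes (pediatric, phase I, therapeutic-area and
#' US-site indicators), site operations (enrollment below 5 / above 32,
#' screen-failure rate above 0.62, long active screening per enrolled
#' patient, timely AE reporting, three or more parallel trials in the same
#' therapeutic area) and the two randomization-by-design interaction flags.
#'
#' @param activities,studies,sites Tables as returned by [generate_dataset()].
#' @return Numeric 0/1 matrix, one row per activity, columns named as in
#'   [default_feature_marginals()].
#' @export
ground_truth_features <- function(activities, studies, sites) {
  d <- join_tables(activities, studies, sites)
  inter <- interaction_randomization_design(d$randomized, d$design)
  m <- cbind(
    us_site = as.numeric(d$country == "US"),
    pediatric = as.numeric(d$pediatric),
    oncology = as.numeric(d$therapeutic_area == "oncology"),
    autoimmune = as.numeric(d$therapeutic_area == "autoimmune"),
    neuro_psych = as.numeric(d$therapeutic_area == "neuroscience_psychiatry"),
    phase_1 = as.numeric(d$phase == "I"),
    enrolled_lt_5 = as.numeric(d$patients_enrolled < 5),
    enrolled_gt_32 = as.numeric(d$patients_enrolled > 32),
    screen_failure_gt_0.62 = as.numeric(d$screen_failure_rate > 0.62),
    long_screening = as.numeric(d$active_screening_days_per_enrolled > 34),
    ae_timely = as.numeric(d$ae_reporting_latency_days <= 2),
    multiple_parallel_trials = as.numeric(d$parallel_trials_same_ta >= 3),
    nonrand_parallel_or_sequential = inter$nonrand_parallel_or_sequential,
    nonrand_single_group = inter$nonrand_single_group
  )
  rownames(m) <- d$activity_id
  m
}

#' Generate a synthetic audit/study/site dataset
#'
#' Simulates the three tables of the analysis: a study portfolio, the sites
#' of each study, and one row per audit or inspection activity with per-CIF
#' finding counts. The yearly activity count is Poisson; each activity is
#' assigned to a study active that year (studies stay auditable for a
#' geometric number of years, so repeat audits of a study across years occur)
#' and to a uniformly sampled site of that study. For each CIF, presence of
#' at least one finding is Bernoulli with log-odds
#' `intercept + ground-truth features %*% true coefficients`, the intercept
#' solved so the marginal presence rate equals the configured base rate;
#' given presence, the finding count is `1 + Poisson(mu)` with `mu` shared
#' across CIFs and scaled so the expected total findings per activity equals
#' `mean_findings_per_audit`.
#'
#' @param config A [generator_config()].
#' @return A list of class `"cif_dataset"` with elements `activities`,
#'   `studies`, `sites` (data frames) and `truth` (ground-truth intercepts,
#'   coefficients and the configuration).
#' @export
#' @examples
#' ds <- generate_dataset(generator_config(n_years = 2, seed = 7))
#' colMeans(ds$activities[paste0("findings_", cif_names())] > 0)
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  years <- config$first_year + seq_len(config$n_years) - 1L

  studies <- simulate_studies(config, years)
  sites <- simulate_sites(config, studies)
  activities <- simulate_activity_schedule(config, studies, sites, years)

  gt <- ground_truth_features(activities, studies, sites)
  n <- nrow(activities)

  mu_extra <- config$mean_findings_per_audit / sum(config$cif_base_rates) - 1
  intercepts <- numeric(length(cif_names()))
  names(intercepts) <- cif_names()
  for (cf in cif_names()) {
    beta <- config$true_coefficients[[cf]]
    lin <- if (length(beta)) as.numeric(gt[, names(beta), drop = FALSE] %*% beta)
           else rep(0, n)
    b <- intercept_for_rows(config$cif_base_rates[[cf]], lin)
    intercepts[cf] <- b
    presence <- stats::rbinom(n, 1, stats::plogis(b + lin))
    counts <- presence * (1L + stats::rpois(n, mu_extra))
    activities[[paste0("findings_", cf)]] <- as.integer(counts)
  }

  structure(list(
    activities = activities,
    studies = studies,
    sites = sites,
    truth = list(intercepts = as.list(intercepts),
                 coefficients = lapply(config$true_coefficients, as.list),
                 seed = config$seed,
                 mu_extra = mu_extra)
  ), class = "cif_dataset")
}

simulate_studies <- function(config, years) {
  n <- config$n_studies
  phase <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                  prob = c(0.15, 0.30, 0.45, 0.10))
  ta <- sample(c("oncology", "autoimmune", "neuroscience_psychiatry", "other"),
               n, replace = TRUE, prob = c(0.50, 0.20, 0.15, 0.15))
  randomized <- stats::runif(n) < 0.7
  # design depends on randomization: non-randomized studies are mostly
  # single-group, randomized ones mostly parallel
  designs <- c("parallel", "sequential", "single_group", "crossover")
  design <- character(n)
  design[randomized] <- sample(designs, sum(randomized), replace = TRUE,
                               prob = c(0.60, 0.10, 0.15, 0.15))
  design[!randomized] <- sample(designs, sum(!randomized), replace = TRUE,
                                prob = c(0.30, 0.10, 0.50, 0.10))
  pediatric <- stats::runif(n) < 0.12
  entry <- sample(years, n, replace = TRUE)
  duration <- 1L + stats::rgeom(n, config$study_persistence)
  data.frame(
    study_id = sprintf("S%03d", seq_len(n)),
    phase = phase,
    therapeutic_area = ta,
    randomized = randomized,
    design = design,
    pediatric = pediatric,
    first_active_year = entry,
    last_active_year = pmin(entry + duration - 1L, max(years)),
    stringsAsFactors = FALSE
  )
}

simulate_sites <- function(config, studies) {
  countries <- c("US", "CH", "DE", "UK", "JP", "CA", "FR", "other")
  cprob <- c(0.55, 0.05, 0.07, 0.07, 0.06, 0.06, 0.06, 0.08)
  per_study <- sample(seq(config$sites_per_study[1], config$sites_per_study[2]),
                      nrow(studies), replace = TRUE)
  n <- sum(per_study)
  data.frame(
    site_id = sprintf("T%04d", seq_len(n)),
    study_id = rep(studies$study_id, per_study),
    country = sample(countries, n, replace = TRUE, prob = cprob),
    patients_enrolled = stats::rnbinom(n, size = 2, mu = 20),
    screen_failure_rate = stats::rbeta(n, 2, 3),
    active_screening_days_per_enrolled = stats::rlnorm(n, 3, 0.8),
    parallel_trials_same_ta = stats::rpois(n, 2),
    ae_reporting_latency_days = stats::rlnorm(n, 0.5, 0.7),
    stringsAsFactors = FALSE
  )
}

simulate_activity_schedule <- function(config, studies, sites, years) {
  out <- vector("list", length(years))
  for (i in seq_along(years)) {
    yr <- years[i]
    n_y <- stats::rpois(1, config$audits_per_year)
    eligible <- studies$study_id[studies$first_active_year <= yr &
                                 studies$last_active_year >= yr]
    if (length(eligible) == 0) eligible <- studies$study_id
    st <- sample(eligible, n_y, replace = TRUE)
    si <- vapply(st, function(s) {
      cand <- sites$site_id[sites$study_id == s]
      cand[sample.int(length(cand), 1)]
    }, character(1))
    out[[i]] <- data.frame(
      year = rep(yr, n_y),
      activity_type = ifelse(stats::runif(n_y) < config$inspection_fraction,
                             "inspection", "audit"),
      study_id = st,
      site_id = unname(si),
      stringsAsFactors = FALSE
    )
  }
  acts <- do.call(rbind, out)
  acts <- cbind(activity_id = sprintf("A%05d", seq_len(nrow(acts))), acts,
                stringsAsFactors = FALSE)
  rownames(acts) <- NULL
  acts
}

#' @keywords internal
join_tables <- function(activities, studies, sites) {
  d <- merge(activities, studies, by = "study_id", sort = FALSE)
  d <- merge(d, sites, by = c("site_id", "study_id"), sort = FALSE)
  # merge() does not preserve row order; restore the activity order
  d[match(activities$activity_id, d$activity_id), , drop = FALSE]
}

#' Write a synthetic dataset to delimited text files
#'
#' Writes `activities.csv`, `studies.csv`, `sites.csv` (comma-separated,
#' header row, UTF-8) and `truth.json` (ground-truth intercepts and
#' coefficients, for parameter-recovery checks) into `dir`.
#'
#' @param dataset A `"cif_dataset"` from [generate_dataset()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cif_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(dataset$activities, file.path(dir, "activities.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$studies, file.path(dir, "studies.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$sites, file.path(dir, "sites.csv"),
                   row.names = FALSE)
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
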