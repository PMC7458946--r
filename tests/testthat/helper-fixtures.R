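# Shared fixtures, all built in code.

# small but non-trivial generator configuration for fast tests
small_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_years = 4L, audits_per_year = 60, n_studies = 60L, seed = seed),
    list(...))
  do.call(generator_config, args)
}

# hand-built three-table fixture with known feature values
tiny_tables <- function() {
  studies <- data.frame(
    study_id = c("S1", "S2"),
    phase = c("I", "III"),
    therapeutic_area = c("oncology", "autoimmune"),
    randomized = c(TRUE, FALSE),
    design = c("parallel", "single_group"),
    pediatric = c(FALSE, TRUE),
    stringsAsFactors = FALSE)
  sites <- data.frame(
    site_id = c("T1", "T2", "T3", "T4"),
    study_id = c("S1", "S1", "S2", "S2"),
    country = c("US", "CH", "US", "DE"),
    patients_enrolled = c(10, 33, 40, 4),
    screen_failure_rate = c(0.5, 0.7, 0.3, 0.65),
    active_screening_days_per_enrolled = c(10, 40, 20, 35),
    parallel_trials_same_ta = c(0, 2, 2, 5),
    ae_reporting_latency_days = c(1, 3, 2, 10),
    stringsAsFactors = FALSE)
  activities <- data.frame(
    activity_id = paste0("A", 1:4),
    year = c(2011, 2011, 2012, 2012),
    activity_type = c("audit", "audit", "inspection", "audit"),
    study_id = c("S1", "S1", "S2", "S2"),
    site_id = c("T1", "T2", "T3", "T4"),
    findings_consent = c(0L, 3L, 1L, 0L),
    findings_data_integrity = c(1L, 0L, 2L, 1L),
    findings_protecting_primary_endpoints = c(0L, 1L, 1L, 1L),
    findings_safety = c(2L, 0L, 0L, 1L),
    findings_sponsor_oversight = c(0L, 1L, 0L, 0L),
    stringsAsFactors = FALSE)
  list(activities = activities, studies = studies, sites = sites)
}

# simulate a binary-feature design and Bernoulli outcome with known log-odds
simulate_logistic_data <- function(n, beta, intercept, prevalence, seed) {
  set.seed(seed)
  k <- length(beta)
  X <- matrix(rbinom(n * k, 1, rep(prevalence, each = n)), nrow = n,
              dimnames = list(NULL, names(beta)))
  p <- plogis(intercept + as.numeric(X %*% beta))
  list(X = X, y = rbinom(n, 1, p))
}

# brute-force AUC: enumerate every positive-negative pair
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
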