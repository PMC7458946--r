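test_that("Yeo-Johnson branches match closed forms at fixed lambda", {
  x <- c(-2, -0.5, 0, 0.5, exp(1) - 1, 3)
  # lambda = 1 is the identity before standardization
  tr1 <- yeo_johnson_transform(x, lambda = 1, standardize = FALSE)
  expect_equal(tr1$transformed, x)
  # lambda = 0: log branch for x >= 0
  tr0 <- yeo_johnson_transform(c(exp(1) - 1, 0, 1), lambda = 0,
                               standardize = FALSE)
  expect_equal(tr0$transformed, c(1, 0, log(2)))
  # lambda = 2: negative log branch for x < 0
  tr2 <- yeo_johnson_transform(c(-(exp(1) - 1), 1), lambda = 2,
                               standardize = FALSE)
  expect_equal(tr2$transformed[1], -1)
})

test_that("Yeo-Johnson reduces skewness of a right-skewed sample and standardizes", {
  set.seed(4)
  x <- exp(rnorm(500))
  tr <- yeo_johnson_transform(x)
  skew <- function(v) mean((v - mean(v))^3) / sd(v)^3
  expect_lt(tr$lambda, 1)
  expect_lt(abs(skew(tr$transformed)), abs(skew(x)))
  expect_equal(mean(tr$transformed), 0, tolerance = 1e-10)
  expect_equal(sd(tr$transformed), 1, tolerance = 1e-10)
  expect_error(yeo_johnson_transform(rep(2, 10)), "constant")
})

test_that("Yeo-Johnson lambda agrees with the car package MLE", {
  skip_if_not_installed("car")
  set.seed(11)
  for (x in list(exp(rnorm(300)), rnorm(300, 5, 2), rgamma(300, 2))) {
    lam_car <- unname(car::powerTransform(x, family = "yjPower")$lambda)
    lam_pkg <- yeo_johnson_transform(x)$lambda
    expect_equal(lam_pkg, lam_car, tolerance = 0.02)
  }
})

test_that("quantile binning partitions values into the expected segments", {
  seg <- bin_into_segments(1:100, 5)
  expect_equal(unname(table(seg)), rep(20L, 5), ignore_attr = TRUE)
  expect_true(is.ordered(seg))

  # boundaries for 1..10 fall after elements 2, 4, 6, 8
  seg10 <- bin_into_segments(1:10, 5)
  expect_equal(as.integer(seg10), rep(1:5, each = 2))

  expect_warning(res <- bin_into_segments(rep(3, 7), 5), "collapsing")
  expect_equal(length(unique(res)), 1L)
})

test_that("rare levels pool into 'other' at the 5% rule", {
  x <- c(rep("A", 50), rep("B", 47), rep("C", 3))
  expect_equal(sort(unique(group_rare_levels(x))), c("A", "B", "other"))
  expect_equal(sum(group_rare_levels(x) == "other"), 3)

  # a single rare level may leave "other" itself below the threshold
  y <- c(rep("A", 96), rep("B", 4))
  gy <- group_rare_levels(y)
  expect_equal(mean(gy == "other"), 0.04)

  # all levels rare: everything pools
  z <- rep(paste0("L", 1:21), length.out = 210)  # each level ~4.76%
  expect_true(all(group_rare_levels(z) == "other"))
})

test_that("binarize maps positive levels to 1 and missing to 0", {
  expect_equal(binarize(c("US", "CH", NA, "US"), "US"), c(1L, 0L, 0L, 1L))
  expect_equal(binarize(c("a", "b"), c("a", "b")), c(1L, 1L))
  # top-segment binarization equals direct quantile thresholding
  set.seed(21)
  x <- rlnorm(200)
  seg <- bin_into_segments(yeo_johnson_transform(x)$transformed, 5)
  top <- binarize(seg, "seg5")
  expect_equal(top, as.integer(x > quantile(x, 0.8)))
})

test_that("site burden score is the tie-averaged cumulative rank", {
  s4 <- data.frame(site_id = paste0("T", 1:4), study_id = "S1",
                   parallel_trials_same_ta = c(0, 2, 2, 5))
  expect_equal(site_burden_score(s4)$score, c(0.25, 0.625, 0.625, 1.0))

  s1 <- s4[1, ]
  expect_equal(site_burden_score(s1)$score, 1.0)

  ties <- transform(s4, parallel_trials_same_ta = 7)
  expect_equal(site_burden_score(ties)$score, rep(0.625, 4))

  # permutation invariance and monotonicity
  perm <- s4[c(3, 1, 4, 2), ]
  sc <- site_burden_score(perm)
  expect_equal(sc$score[match(s4$site_id, sc$site_id)],
               c(0.25, 0.625, 0.625, 1.0))
  inc <- transform(s4, parallel_trials_same_ta = c(1, 2, 3, 4))
  expect_true(all(diff(site_burden_score(inc)$score) > 0))
  expect_true(all(site_burden_score(s4)$score > 0))
})

test_that("randomization-by-design interaction produces the two exclusive flags", {
  cases <- expand.grid(
    randomized = c(TRUE, FALSE),
    design = c("parallel", "sequential", "single_group", "crossover"),
    stringsAsFactors = FALSE)
  out <- interaction_randomization_design(cases$randomized, cases$design)
  expect_equal(out$nonrand_parallel_or_sequential,
               as.integer(!cases$randomized &
                            cases$design %in% c("parallel", "sequential")))
  expect_equal(out$nonrand_single_group,
               as.integer(!cases$randomized & cases$design == "single_group"))
  # at most one flag set per record
  expect_true(all(out$nonrand_parallel_or_sequential +
                    out$nonrand_single_group <= 1))
  expect_error(interaction_randomization_design(TRUE, "adaptive"),
               "invalid design")
})

test_that("build_feature_matrix evaluates specs against the joined tables", {
  tt <- tiny_tables()
  specs <- list(
    feature_spec("enrolled_gt_32", "threshold", "patients_enrolled",
                 value = 32, op = "gt"),
    feature_spec("screen_failure_gt_0.62", "threshold",
                 "screen_failure_rate", value = 0.62, op = "gt"),
    feature_spec("us_site", "binary_level", "country", levels = "US",
                 group_rare = FALSE),
    feature_spec("nonrand_single_group", "interaction",
                 which = "nonrand_single_group"))
  fm <- build_feature_matrix(tt$activities, tt$studies, tt$sites, specs,
                             rare_threshold = 0)
  expect_equal(fm$activity_ids, tt$activities$activity_id)
  # sites T1..T4 enroll 10, 33, 40, 4
  expect_equal(unname(fm$values[, "enrolled_gt_32"]), c(0, 1, 1, 0))
  expect_equal(unname(fm$values[, "screen_failure_gt_0.62"]), c(0, 1, 0, 1))
  expect_equal(unname(fm$values[, "us_site"]), c(1, 0, 1, 0))
  # S2 is non-randomized single-group
  expect_equal(unname(fm$values[, "nonrand_single_group"]), c(0, 0, 1, 1))
  expect_true(all(fm$values %in% c(0, 1)))

  # empty spec list: zero columns, n rows
  fm0 <- build_feature_matrix(tt$activities, tt$studies, tt$sites, list())
  expect_equal(ncol(fm0$values), 0L)
  expect_equal(nrow(fm0$values), 4L)

  # unresolvable spec errors by name
  bad <- list(feature_spec("ghost", "threshold", "no_such_column", value = 1))
  expect_error(
    build_feature_matrix(tt$activities, tt$studies, tt$sites, bad),
    "ghost")
})

test_that("build_feature_matrix is invariant to input row order", {
  ds <- generate_dataset(small_config(seed = 8))
  # at this scale some features may fall below the prevalence rule; the
  # drop must be identical across row orders
  fm1 <- suppressWarnings(
    build_feature_matrix(ds$activities, ds$studies, ds$sites))
  shuffle <- function(df) df[sample(nrow(df)), , drop = FALSE]
  set.seed(99)
  fm2 <- suppressWarnings(
    build_feature_matrix(ds$activities, shuffle(ds$studies),
                         shuffle(ds$sites)))
  expect_identical(fm1$values, fm2$values)
  expect_identical(fm1$activity_ids, fm2$activity_ids)
})

test_that("features below the prevalence rule are dropped with a warning", {
  tt <- tiny_tables()
  n <- 40
  # exactly one activity out of 40 visits the single >99-patient site
  acts <- tt$activities[c(rep(1:3, length.out = n - 1), 4), ]
  acts$activity_id <- sprintf("A%03d", 1:n)
  sites <- tt$sites
  sites$patients_enrolled <- c(10, 12, 14, 100)
  specs <- list(
    feature_spec("big_site", "threshold", "patients_enrolled",
                 value = 99, op = "gt"),
    feature_spec("us_site", "binary_level", "country", levels = "US"))
  expect_warning(
    fm <- build_feature_matrix(acts, tt$studies, sites, specs),
    "big_site")
  expect_equal(fm$feature_names, "us_site")
})

test_that("strongest pairwise correlation is found, constants excluded", {
  set.seed(13)
  a <- rbinom(200, 1, 0.5)
  m <- cbind(a = a, b = rbinom(200, 1, 0.5), dup = a)
  res <- max_abs_pairwise_correlation(m)
  expect_equal(res$value, 1.0)
  expect_setequal(res$pair, c("a", "dup"))

  # a feature and its complement correlate -1, |r| = 1
  m2 <- cbind(a = a, comp = 1 - a)
  expect_equal(max_abs_pairwise_correlation(m2)$value, 1.0)

  # two independent Bernoulli(0.5) columns at n = 10,000
  set.seed(14)
  m3 <- cbind(x = rbinom(10000, 1, 0.5), y = rbinom(10000, 1, 0.5))
  expect_lt(max_abs_pairwise_correlation(m3)$value, 0.05)

  m4 <- cbind(a = a, k = rep(1, 200), b = rbinom(200, 1, 0.4))
  expect_warning(max_abs_pairwise_correlation(m4), "constant")
})

test_that("transform-bin-binarize pipeline equals direct rank thresholding", {
  # Yeo-Johnson is monotone, so segment membership only depends on ranks
  set.seed(31)
  for (i in 1:5) {
    x <- rgamma(150, shape = 0.8)
    tr <- yeo_johnson_transform(x)$transformed
    expect_equal(as.integer(bin_into_segments(tr, 5)),
                 as.integer(bin_into_segments(x, 5)))
  }
})
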