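test_that("binary outcome is the indicator of one or more findings", {
  tt <- tiny_tables()
  out <- make_binary_outcome(tt$activities, "consent")
  expect_equal(out$present, c(0L, 1L, 1L, 0L))  # counts 0, 3, 1, 0
  out2 <- make_binary_outcome(tt$activities, "data_integrity")
  expect_equal(out2$present, c(1L, 0L, 1L, 1L))
  bad <- tt$activities
  bad$findings_consent[1] <- -1L
  expect_error(make_binary_outcome(bad, "consent"), "non-negative")
})

test_that("logistic fit on a 2x2 table matches the closed-form log-odds", {
  # x = 0: 10 events / 30 non-events; x = 1: 30 events / 10 non-events
  x <- matrix(c(rep(0, 40), rep(1, 40)), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- c(rep(1, 10), rep(0, 30), rep(1, 30), rep(0, 10))
  fit <- fit_logistic(x, y)
  expect_equal(fit$intercept, log(1 / 3), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["f"]), log(9), tolerance = 1e-6)
  # BIC identity: k log(n) - 2 logLik with k = 1 + |coefficients|
  expect_equal(fit$bic, 2 * log(80) - 2 * fit$log_likelihood)
  expect_equal(fit$n_train, 80L)

  # predicted probabilities reproduce the cell rates
  expect_equal(predict_probability(fit, c(f = 0)), 0.25, tolerance = 1e-6)
  expect_equal(predict_probability(fit, c(f = 1)), 0.75, tolerance = 1e-6)
  expect_equal(predict_probability(fit, c(f = 1)), plogis(log(3)),
               tolerance = 1e-6)
})

test_that("null model intercept is the logit of the event rate", {
  y <- c(rep(1, 3), rep(0, 7))
  X <- matrix(numeric(0), nrow = 10, ncol = 0)
  fit <- fit_logistic(X, y)
  expect_equal(fit$intercept, qlogis(0.3), tolerance = 1e-8)
  expect_equal(length(fit$coefficients), 0L)
})

test_that("fit errors on constant features and perfect separation", {
  set.seed(2)
  X <- cbind(f = rbinom(50, 1, 0.5), k = rep(1, 50))
  y <- rbinom(50, 1, 0.5)
  expect_error(fit_logistic(X, y), "constant feature")

  # y perfectly determined by the feature
  Xs <- cbind(sep = c(rep(0, 25), rep(1, 25)),
              noise = rbinom(50, 1, 0.5))
  ys <- Xs[, "sep"]
  expect_error(fit_logistic(Xs, ys), "separation.*sep")
})

test_that("coefficients are recovered within 3 SE on simulated data", {
  beta <- c(a = 1.0, b = -0.8, c = 0.5)
  sim <- simulate_logistic_data(5000, beta, intercept = -0.3,
                                prevalence = c(0.4, 0.3, 0.5), seed = 17)
  fit <- fit_logistic(sim$X, sim$y)
  # standard errors from the observed information
  design <- cbind(1, sim$X)
  p <- predict_probability(fit, sim$X)
  info <- t(design) %*% (design * (p * (1 - p)))
  se <- sqrt(diag(solve(info)))[-1]
  expect_true(all(abs(fit$coefficients - beta) < 3 * se))
})

test_that("forward BIC selection keeps the null model under pure noise", {
  hits <- vapply(1:50, function(s) {
    sim <- simulate_logistic_data(2000, c(a = 0, b = 0, c = 0, d = 0, e = 0),
                                  intercept = 0.2,
                                  prevalence = rep(0.4, 5), seed = 3000 + s)
    m <- select_features_bic(sim$X, sim$y)
    length(m$coefficients) == 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("a strong single candidate is selected", {
  sim <- simulate_logistic_data(5000, c(sig = 1.0, n1 = 0, n2 = 0),
                                intercept = -0.5,
                                prevalence = c(0.3, 0.4, 0.5), seed = 5)
  m <- select_features_bic(sim$X, sim$y)
  expect_true("sig" %in% names(m$coefficients))
  expect_gt(unname(m$coefficients["sig"]), 0)
})

test_that("greedy selection matches the exhaustive BIC minimum almost always", {
  # exhaustive oracle over all 2^k subsets, k = 6
  exhaustive_bic <- function(X, y) {
    nm <- colnames(X)
    best <- Inf
    for (mask in 0:(2^length(nm) - 1)) {
      keep <- nm[bitwAnd(mask, 2^(seq_along(nm) - 1)) > 0]
      b <- fit_logistic(X[, keep, drop = FALSE], y)$bic
      if (b < best) best <- b
    }
    best
  }
  set.seed(77)
  match_count <- 0
  n_data <- 20
  for (i in 1:n_data) {
    beta <- setNames(round(runif(6, -1, 1), 2), letters[1:6])
    beta[abs(beta) < 0.3] <- 0
    sim <- simulate_logistic_data(800, beta, intercept = 0,
                                  prevalence = runif(6, 0.2, 0.6),
                                  seed = 500 + i)
    greedy <- select_features_bic(sim$X, sim$y)$bic
    oracle <- exhaustive_bic(sim$X, sim$y)
    if (abs(greedy - oracle) < 1e-8) match_count <- match_count + 1
    expect_gte(greedy, oracle - 1e-8)  # greedy can never beat the oracle
  }
  expect_gte(match_count / n_data, 0.95)
})

test_that("selection is invariant to row and column order", {
  sim <- simulate_logistic_data(1500, c(a = 0.9, b = -0.7, c = 0, d = 0),
                                intercept = 0, prevalence = rep(0.4, 4),
                                seed = 9)
  m1 <- select_features_bic(sim$X, sim$y)
  set.seed(1)
  perm <- sample(nrow(sim$X))
  m2 <- select_features_bic(sim$X[perm, ], sim$y[perm])
  expect_equal(names(m1$coefficients), names(m2$coefficients))
  m3 <- select_features_bic(sim$X[, c(3, 1, 4, 2)], sim$y)
  expect_equal(names(m1$coefficients), names(m3$coefficients))
  expect_equal(m1$coefficients, m3$coefficients, tolerance = 1e-8)
})

test_that("selected-model BIC never exceeds the null BIC and flagged pairs are never co-selected", {
  sim <- simulate_logistic_data(1200, c(a = 0.8, b = 0, c = 0),
                                intercept = 0, prevalence = rep(0.4, 3),
                                seed = 23)
  # add a near-duplicate of 'a' (correlation far above the screen threshold)
  X <- cbind(sim$X, a2 = sim$X[, "a"])
  flip <- seq_len(60)
  X[flip, "a2"] <- 1 - X[flip, "a2"]
  m <- select_features_bic(X, sim$y)
  null_bic <- fit_logistic(X[, character(0), drop = FALSE], sim$y)$bic
  expect_lte(m$bic, null_bic)
  expect_false(all(c("a", "a2") %in% names(m$coefficients)))

  expect_warning(m0 <- select_features_bic(X[, character(0), drop = FALSE],
                                           sim$y, candidates = character(0)),
                 "empty candidate set")
  expect_equal(length(m0$coefficients), 0L)
})

test_that("refit on all data keeps features and is idempotent on identical data", {
  sim <- simulate_logistic_data(2000, c(a = 1.0, b = -0.8),
                                intercept = 0, prevalence = c(0.4, 0.3),
                                seed = 31)
  sel <- select_features_bic(sim$X, sim$y)
  re <- refit_on_all_data(sel, sim$X, sim$y)
  expect_equal(re$coefficients, sel$coefficients, tolerance = 1e-8)
  expect_equal(re$intercept, sel$intercept, tolerance = 1e-8)

  X2 <- sim$X
  colnames(X2) <- c("a", "renamed")
  if ("b" %in% names(sel$coefficients)) {
    expect_error(refit_on_all_data(sel, X2, sim$y), "absent")
  }
})

test_that("full-data refit beats window-only fit in coefficient RMSE", {
  beta <- c(a = 0.9, b = -0.7)
  rmse_full <- rmse_win <- numeric(40)
  for (s in 1:40) {
    sim <- simulate_logistic_data(1600, beta, intercept = 0,
                                  prevalence = c(0.4, 0.3), seed = 7000 + s)
    win <- seq_len(600)
    fw <- fit_logistic(sim$X[win, ], sim$y[win])
    ff <- fit_logistic(sim$X, sim$y)
    rmse_win[s] <- sqrt(mean((fw$coefficients[names(beta)] - beta)^2))
    rmse_full[s] <- sqrt(mean((ff$coefficients[names(beta)] - beta)^2))
  }
  expect_lt(mean(rmse_full), mean(rmse_win))
})

test_that("predict_probability obeys the additive log-odds form", {
  m <- structure(list(cif = "consent", intercept = 0,
                      coefficients = c(f = 0), n_train = 10L,
                      train_years = NULL, log_likelihood = 0, bic = 0),
                 class = "cif_model")
  expect_equal(predict_probability(m, c(f = 1)), 0.5)
  expect_equal(predict_probability(m, c(f = 0)), 0.5)
  m$coefficients <- c(f = 2)
  m$intercept <- -1
  expect_equal(predict_probability(m, c(f = 1)), plogis(1))
  expect_error(predict_probability(m, c(g = 1)), "missing feature")
})
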