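test_that("quantile binning follows the distinct-value and quantile rules", {
  expect_equal(discretize_feature(1:100, 4), c(25.75, 50.5, 75.25))
  expect_equal(discretize_feature(rep(7, 50), 16), numeric(0))
  expect_equal(discretize_feature(rep(c(0, 1), 30), 64), 0.5)
  # every bin non-empty even under heavy ties
  v <- c(rep(0, 90), 1:10)
  e <- discretize_feature(v, 8)
  counts <- tabulate(findInterval(v, e) + 1L, length(e) + 1L)
  expect_true(all(counts > 0))
})

test_that("component evaluation uses half-open bins, right bin at thresholds", {
  cmp <- unit_component(c(10, 20, 30))  # thresholds at 1, 2
  expect_equal(evaluate_component(cmp, c(0.5, 1, 1.99, 2, 50, -3)),
               c(10, 20, 20, 30, 30, 10))
  cmp$missing_bin_value <- -5
  expect_equal(evaluate_component(cmp, c(NA, 1.5)), c(-5, 20))
})

test_that("a single binary feature recovers the closed-form logit contrast", {
  n <- 10000
  df <- withr::with_seed(11, {
    x <- rbinom(n, 1, 0.5)
    data.frame(x = x, outcome = rbinom(n, 1, ifelse(x == 1, 0.8, 0.2)))
  })
  tab <- patient_table(df, dataset_schema("outcome", c(x = "boolean")))
  m <- fit_gam(tab, fit_config(n_rounds = 300, learning_rate = 0.1,
                               seed = 3, early_stop_patience = 0))
  contrast <- diff(evaluate_component(m$components$x, c(0, 1)))
  # direct logistic-MLE oracle on the same data
  mle <- unname(coef(glm(outcome ~ x, binomial, data = df))["x"])
  expect_equal(contrast, qlogis(0.8) - qlogis(0.2), tolerance = 0.15)
  expect_equal(contrast, mle, tolerance = 0.15)
})

test_that("independent outcome yields flat components and base-rate intercept", {
  n <- 10000
  df <- withr::with_seed(21, {
    data.frame(x = runif(n), b = rbinom(n, 1, 0.5),
               outcome = rbinom(n, 1, 0.35))
  })
  tab <- patient_table(df, dataset_schema("outcome",
                                          c(x = "continuous", b = "boolean")))
  m <- fit_gam(tab, fit_config(n_rounds = 200, max_bins = 16, seed = 4,
                               early_stop_patience = 0))
  expect_lt(max(abs(unlist(lapply(m$components, `[[`, "values")))), 0.1)
  expect_equal(m$intercept, qlogis(mean(df$outcome)), tolerance = 0.1)
})

test_that("two independent additive effects are recovered jointly", {
  truth <- simulate_additive_cohort(8000, n_nuisance = 0, seed = 31)
  m <- fit_gam(truth$table, fit_config(n_rounds = 200, max_bins = 16,
                                       seed = 5, early_stop_patience = 0))
  err <- component_recovery_error(m, truth$table, truth$truth)
  expect_lt(max(err$rmse), 0.25)
})

test_that("fits are deterministic and components centered, predictions additive", {
  tab <- small_cohort(600, seed = 41)
  cfg <- fit_config(n_rounds = 60, max_bins = 8, seed = 9)
  m1 <- fit_gam(tab, cfg)
  m2 <- fit_gam(tab, cfg)
  expect_identical(m1$intercept, m2$intercept)
  expect_identical(lapply(m1$components, `[[`, "values"),
                   lapply(m2$components, `[[`, "values"))
  for (cmp in m1$components) {
    expect_lt(abs(weighted.mean(cmp$values, cmp$bin_counts)), 1e-9)
  }
  # the linear predictor is exactly intercept + sum of component values
  eta <- predict_logit(m1, tab)
  manual <- m1$intercept +
    evaluate_component(m1$components$x, tab$features$x) +
    evaluate_component(m1$components$b, tab$features$b)
  expect_equal(eta, manual, tolerance = 1e-12)
  expect_true(all(predict_prob(m1, tab) > 0 & predict_prob(m1, tab) < 1))
})

test_that("degenerate fits behave: n_rounds = 0, single class, missing bin", {
  tab <- small_cohort(200, seed = 51)
  m0 <- fit_gam(tab, fit_config(n_rounds = 0, seed = 1))
  expect_true(all(abs(unlist(lapply(m0$components, `[[`, "values"))) == 0))
  expect_equal(unique(predict_prob(m0, tab)), mean(tab$outcome),
               tolerance = 1e-9)

  df1 <- data.frame(x = 1:20, outcome = rep(1L, 20))
  t1 <- patient_table(df1, dataset_schema("outcome", c(x = "continuous")))
  expect_error(fit_gam(t1, fit_config(n_rounds = 5)), "single class")

  # missing continuous values route to a learned missing bin
  df2 <- withr::with_seed(61, {
    x <- runif(800, 0, 10)
    y <- rbinom(800, 1, plogis(-1 + 0.3 * x))
    x[sample(800, 120)] <- NA
    data.frame(x = x, outcome = y)
  })
  t2 <- patient_table(df2, dataset_schema("outcome", c(x = "continuous")))
  m2 <- fit_gam(t2, fit_config(n_rounds = 50, max_bins = 8, seed = 2,
                               early_stop_patience = 0))
  expect_false(is.null(m2$components$x$missing_bin_value))
  expect_true(all(is.finite(predict_logit(m2, t2))))
})

test_that("bagged fits give bands; degenerate data gives zero-width bands", {
  tab <- small_cohort(500, seed = 71)
  m <- fit_bagged_gam(tab, fit_config(n_rounds = 40, max_bins = 8, n_bags = 5,
                                      seed = 3, early_stop_patience = 0))
  cmp <- m$components$x
  expect_true(all(cmp$ci_lower <= cmp$values + 1e-9))
  expect_true(all(cmp$values <= cmp$ci_upper + 1e-9))

  # constant feature, identical rows: every bag fits the same (flat) model
  dfd <- data.frame(x = rep(1, 8), outcome = rep(c(0, 1), 4))
  td <- patient_table(dfd, dataset_schema("outcome", c(x = "continuous")))
  expect_warning(
    md <- fit_bagged_gam(td, fit_config(n_rounds = 10, n_bags = 3, seed = 1,
                                        early_stop_patience = 0)),
    "diversity")
  expect_equal(md$components$x$ci_lower, md$components$x$ci_upper)
})

test_that("log-likelihood matches closed forms and the brute-force oracle", {
  # intercept-only, intercept 0, half the outcomes are 1: n * log(0.5)
  n <- 10
  df <- data.frame(x = 1:n, outcome = rep(c(0L, 1L), n / 2))
  tab <- patient_table(df, dataset_schema("outcome", c(x = "continuous")))
  m0 <- additive_risk_model(
    0, list(component_function("x", numeric(0), 0)))
  expect_equal(log_likelihood(m0, tab), n * log(0.5), tolerance = 1e-12)

  model <- unit_model(c(-0.5, 0.3, 1.1, 0.2), intercept = -0.4)
  tab2 <- sample_from_model(model, 200, seed = 81)
  expect_equal(log_likelihood(model, tab2), brute_force_ll(model, tab2),
               tolerance = 1e-9)
  # override with the unmodified component is an identity
  expect_identical(log_likelihood(model, tab2, model$components$x),
                   log_likelihood(model, tab2))
})
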