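test_that("the benchmark generator is seeded and faithful to its model", {
  b1 <- simulate_additive_cohort(2000, n_nuisance = 2, seed = 3)
  b2 <- simulate_additive_cohort(2000, n_nuisance = 2, seed = 3)
  expect_identical(b1$table$features, b2$table$features)
  expect_identical(b1$table$outcome, b2$table$outcome)
  expect_named(b1$truth, c("x1", "x2", "z1", "z2"))
  # empirical event rate matches the generating model
  p <- plogis(b1$intercept + b1$truth$x1(b1$table$features$x1) +
                b1$truth$x2(b1$table$features$x2))
  expect_lt(abs(mean(b1$table$outcome) - mean(p)),
            3 * sqrt(mean(p * (1 - p)) / 2000))
})

test_that("recovery error is near zero when the fit equals the truth", {
  # hand-build a model matching the generating components exactly
  bench <- simulate_additive_cohort(4000, n_nuisance = 0, seed = 13)
  centered <- function(v, x, t) {
    w <- tabulate(findInterval(x, t) + 1, length(v))
    list(v = v - weighted.mean(v, w), w = w)
  }
  c1 <- centered(c(-0.9, 0.1, 1.1), bench$table$features$x1, c(3, 7))
  c2 <- centered(c(-1.0, -0.5, 0, 0.5, 1.0), bench$table$features$x2,
                 c(2, 4, 6, 8))
  f1 <- component_function("x1", c(3, 7), c1$v, bin_counts = c1$w)
  f2 <- component_function("x2", c(2, 4, 6, 8), c2$v, bin_counts = c2$w)
  m <- additive_risk_model(-1, list(f1, f2))
  err <- component_recovery_error(m, bench$table,
                                  bench$truth[c("x1", "x2")],
                                  intercept = bench$intercept)
  # bins align with the true thresholds, so targets equal the (centered)
  # true values and the hand-built model matches them up to centering
  expect_lt(max(err$rmse), 1e-6)
})

test_that("bootstrap bands cover the attainable targets of the benchmark", {
  expect_gte(run_band_coverage(n = 20000, seed = 1), 0.8)
})
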