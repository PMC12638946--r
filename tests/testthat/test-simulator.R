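test_that("untreated risk is a strictly increasing logistic curve", {
  p0 <- make_untreated_risk(a = -4, b = 1)
  expect_equal(p0(4), 0.5)
  x <- seq(0, 10, by = 0.1)
  expect_true(all(diff(p0(x)) > 0))
  expect_lt(p0(-50), 1e-10)
  expect_gt(p0(60), 1 - 1e-10)
  expect_error(make_untreated_risk(b = 0), "b > 0")
  expect_error(make_untreated_risk(b = -1), "b > 0")
})

test_that("the four benefit kinds honor their contracts", {
  p0 <- make_untreated_risk()
  x <- seq(0, 10, by = 0.5)

  flat <- make_treated_risk(benefit_curve("flattens_risk", level = 0.15), p0)
  expect_equal(flat(x), rep(0.15, length(x)))

  lim <- make_treated_risk(benefit_curve("limits_risk", cap = 0.3), p0)
  expect_equal(lim(x), pmin(p0(x), 0.3))

  red <- make_treated_risk(benefit_curve("reduces_biomarker", shift = 2), p0)
  expect_equal(red(x), p0(x - 2))

  cb <- make_treated_risk(benefit_curve("constant_benefit", offset = 1), p0)
  x_half <- 4  # p0 = 0.5 here
  expect_equal(cb(x_half), plogis(-1), tolerance = 1e-12)

  expect_error(benefit_curve("flattens_risk", level = 1.2), "in \\(0,1\\)")
  expect_error(benefit_curve("made_up_kind"))
})

test_that("population risk is the policy mixture with correct limits", {
  p0 <- make_untreated_risk()
  p1 <- make_treated_risk(benefit_curve("flattens_risk", level = 0.15), p0)
  never <- adherence_policy("strict", threshold = Inf)
  always <- adherence_policy("strict", threshold = -Inf)
  expect_equal(compose_population_risk(
    simulation_scenario(p0, p1, never))$p,
    p0(seq(0, 10, by = 0.05)))
  expect_equal(compose_population_risk(
    simulation_scenario(p0, p1, always))$p,
    p1(seq(0, 10, by = 0.05)))

  # strict policy above the crossing point: jump of size p0(tau) - level
  sc <- simulation_scenario(p0, p1, adherence_policy("strict", 5))
  cur <- compose_population_risk(sc)
  i <- which(cur$x == 5)
  expect_equal(cur$p[i - 1] - cur$p[i], p0(4.95) - 0.15, tolerance = 1e-12)
  # mixture bounds hold pointwise
  expect_true(all(cur$p >= pmin(cur$p0, cur$p1) - 1e-12))
  expect_true(all(cur$p <= pmax(cur$p0, cur$p1) + 1e-12))
})

test_that("optimal thresholds match closed forms and crossing flags", {
  p0 <- make_untreated_risk()
  flat <- make_treated_risk(benefit_curve("flattens_risk", level = 0.15), p0)
  sc <- simulation_scenario(p0, flat, adherence_policy("strict", 5))
  opt <- optimal_threshold(sc)
  expect_equal(opt$crossing, "crossing")
  # root of p0(x) = 0.15 is x = 4 + logit(0.15); grid resolution 0.05
  expect_equal(opt$x_star, 4 + qlogis(0.15), tolerance = 0.05)

  lim <- make_treated_risk(benefit_curve("limits_risk", cap = 0.3), p0)
  opt2 <- optimal_threshold(simulation_scenario(p0, lim,
                                                adherence_policy("strict", 5)))
  expect_equal(opt2$x_star, 4 + qlogis(0.3), tolerance = 0.051)

  cb <- make_treated_risk(benefit_curve("constant_benefit", offset = 1.5), p0)
  opt3 <- optimal_threshold(simulation_scenario(p0, cb,
                                                adherence_policy("strict", 5)))
  expect_equal(opt3$crossing, "treat_everyone")
  expect_equal(opt3$x_star, 0)

  worse <- make_risk_curve(function(x) plogis(qlogis(p0(x)) + 1))
  opt4 <- optimal_threshold(simulation_scenario(p0, worse,
                                                adherence_policy("strict", 5)))
  expect_equal(opt4$crossing, "no_crossing")

  # a treated curve crossing twice demands a refined scenario
  wig <- make_risk_curve(function(x) plogis(-4 + x + 1.5 * sin(x)))
  expect_error(optimal_threshold(simulation_scenario(p0, wig,
                                                     adherence_policy("strict", 5))),
               "sign")
})

test_that("excess risk is zero at the optimum and grows with misalignment", {
  p0 <- make_untreated_risk()
  p1 <- make_treated_risk(benefit_curve("flattens_risk", level = 0.15), p0)
  sc <- simulation_scenario(p0, p1, adherence_policy("strict", 5))
  x_star <- optimal_threshold(sc)$x_star
  expect_lt(abs(excess_risk(sc, adherence_policy("strict", x_star))), 1e-6)

  taus <- c(3, 4, 5, 6, 7)
  er <- vapply(taus, function(t)
    excess_risk(sc, adherence_policy("strict", t)), numeric(1))
  expect_true(all(er > 0))          # undertreatment above x*
  expect_true(all(diff(er) >= -1e-12))  # nondecreasing in tau - x*
  # overtreatment below x* also carries excess risk
  expect_gt(excess_risk(sc, adherence_policy("strict", 1)), 0)

  # independent quadrature oracle on the closed forms
  dp <- sc$density_params
  z <- pnorm((10 - dp$mean) / dp$sd) - pnorm((0 - dp$mean) / dp$sd)
  dens <- function(x) dnorm(x, dp$mean, dp$sd) / z
  oracle <- function(tau) {
    f <- function(x) {
      p_pol <- ifelse(x >= tau, 0.15, p0(x))
      p_opt <- ifelse(x >= x_star, 0.15, p0(x))
      (p_pol - p_opt) * dens(x)
    }
    integrate(f, 0, 10, subdivisions = 2000L, rel.tol = 1e-10)$value
  }
  for (tau in c(4, 6, 7)) {
    expect_lt(abs(excess_risk(sc, adherence_policy("strict", tau)) -
                    oracle(tau)), 2e-3)
  }
})

test_that("cohort sampling honors the policy, the risk curves, and the seed", {
  p0 <- make_untreated_risk()
  p1 <- make_treated_risk(benefit_curve("flattens_risk", level = 0.15), p0)
  sc <- simulation_scenario(p0, p1, adherence_policy("strict", 5))
  tab <- sample_cohort(sc, 20000, n_nuisance = 1, seed = 5)
  x <- tab$features$biomarker
  tr <- attr(tab, "treated")
  expect_equal(mean(tr[x >= 5]), 1)
  expect_equal(mean(tr[x < 5]), 0)
  expect_true(all(x >= 0 & x <= 10))

  # empirical outcome rate in a biomarker window within 3 SE of p(center)
  for (ctr in c(2, 4.5, 6)) {
    sel <- abs(x - ctr) < 0.25
    phat <- mean(tab$outcome[sel])
    pexp <- mean(compose_population_risk(sc)$p[abs(sc$grid - ctr) < 0.25])
    se <- sqrt(pexp * (1 - pexp) / sum(sel))
    expect_lt(abs(phat - pexp), 3 * se + 0.01)
  }

  tab2 <- sample_cohort(sc, 20000, n_nuisance = 1, seed = 5)
  expect_identical(tab2$features, tab$features)
  expect_identical(tab2$outcome, tab$outcome)
})

test_that("the scenario suite yields 8 bundles with the expected shapes", {
  bundles <- run_scenario_suite(suite_config(), sample_cohorts = FALSE)
  expect_length(bundles, 8L)
  jump_tol <- 0.02
  for (b in bundles) {
    cur <- b$curves
    expect_true(all(cur$p >= pmin(cur$p0, cur$p1) - 1e-12))
    expect_true(all(cur$p <= pmax(cur$p0, cur$p1) + 1e-12))
    i <- which(cur$x == 5)
    if (b$policy_kind == "strict") {
      expect_equal(b$expected_artifact, "discontinuity")
      expect_gt(abs(cur$p[i] - cur$p[i - 1]), jump_tol)
    } else {
      expect_equal(b$expected_artifact, "non_monotonicity")
      expect_lt(max(abs(diff(cur$p))), jump_tol)
    }
  }
})
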