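test_that("linearization is exact for collinear bins and ramps steps", {
  # collinear at representative points: linearized equals the base
  lin <- linearize_component(unit_component(c(0, 1, 2)), 2)
  expect_identical(lin$values, c(0, 1, 2))

  # a step gets an interpolated ramp value in the window
  step <- unit_component(c(0, 0, 2, 2))
  lin2 <- linearize_component(step, 2)
  expect_equal(lin2$values, c(0, 1, 2, 2))   # midpoint of neighbours
  lin3 <- linearize_component(step, 3)
  expect_equal(lin3$values, c(0, 0, 1, 2))
  # anchors are untouched: evaluation at the anchor points returns the
  # anchor values
  expect_equal(evaluate_component(lin2, step$bin_repr[1]), 0)
  expect_equal(evaluate_component(lin2, step$bin_repr[3]), 2)

  # boundary policy: outer bins cannot be linearized
  expect_error(linearize_component(step, 1), "interior")
  expect_error(linearize_component(step, 4), "interior")
  expect_error(linearize_component(unit_component(c(1, 2)), 2), "3 bins")
})

test_that("T_d is exactly zero on locally linear windows", {
  model <- unit_model(seq(-1, 1, length.out = 6))  # globally collinear
  tab <- sample_from_model(model, 500, seed = 1)
  for (k in 2:5) {
    expect_lt(abs(discontinuity_statistic(model, tab, "x", k)), 1e-12)
  }
})

test_that("T_d equals the independent brute-force likelihood difference", {
  model <- unit_model(c(-0.6, -0.5, 1.2, 1.3, 1.5), intercept = -0.3)
  tab <- sample_from_model(model, 400, seed = 2)
  for (k in 2:4) {
    lin <- linearize_component(model$components$x, k)
    model_lin <- model
    model_lin$components$x <- lin
    oracle <- brute_force_ll(model, tab) - brute_force_ll(model_lin, tab)
    expect_equal(discontinuity_statistic(model, tab, "x", k), oracle,
                 tolerance = 1e-9)
  }
})

test_that("an injected step is detected at, and maximal at, its bin", {
  # 1.0 log-odds step between bins 3 and 4 of a 7-bin component
  vals <- c(0, 0.05, 0.1, 1.1, 1.15, 1.2, 1.25)
  model <- unit_model(vals, intercept = -0.5)
  tab <- sample_from_model(model, 20000, seed = 3)
  td <- vapply(2:6, function(k) discontinuity_statistic(model, tab, "x", k),
               numeric(1))
  names(td) <- 2:6
  expect_true(all(td[c("3", "4")] > 0))
  expect_true(which.max(td) %in% c(2L, 3L))  # bins 3 or 4, adjacent to the jump
  expect_gt(max(td[c("3", "4")]), max(td[c("2", "5", "6")]))
})

test_that("T_d is invariant to constant shifts absorbed by the intercept", {
  model <- unit_model(c(-0.6, -0.5, 1.2, 1.3, 1.5), intercept = -0.3)
  tab <- sample_from_model(model, 300, seed = 4)
  shifted <- model
  shifted$components$x$values <- model$components$x$values + 0.7
  shifted$intercept <- model$intercept - 0.7
  for (k in 2:4) {
    expect_equal(discontinuity_statistic(shifted, tab, "x", k),
                 discontinuity_statistic(model, tab, "x", k),
                 tolerance = 1e-9)
  }
})

test_that("slopes and signs follow the monotone / tent / plateau patterns", {
  expect_equal(compute_slopes(unit_component(c(0, 1, 2, 4)))$signs,
               c(1L, 1L, 1L))
  expect_equal(compute_slopes(unit_component(c(0, 1, 0)))$signs, c(1L, -1L))
  expect_equal(compute_slopes(unit_component(c(0, 1, 1, 1, 0)))$signs,
               c(1L, 0L, 0L, -1L))
  s <- compute_slopes(unit_component(c(0, 1, 0)))
  expect_equal(s$slopes, c(1, -1))  # unit-width bins, midpoint representatives
})

test_that("changepoint detection respects the min-run noise guard", {
  expect_equal(detect_sign_changepoints(c(1, 1, 1, -1, -1, -1),
                                        min_run = 2)$right_index, 4L)
  expect_equal(nrow(detect_sign_changepoints(c(1, -1, 1, 1, 1), min_run = 2)),
               0L)
  expect_equal(nrow(detect_sign_changepoints(c(0, 0, 0, 0))), 0L)
  # zeros are removed before run detection: + + 0 0 - - still flips
  cp <- detect_sign_changepoints(c(1, 1, 0, 0, -1, -1), min_run = 2)
  expect_equal(cp$left_index, 2L)
  expect_equal(cp$right_index, 5L)
  expect_equal(cp$curvature, "concave")
})

test_that("curvature classification separates peaks from valleys", {
  tent <- detect_sign_changepoints(compute_slopes(
    unit_component(c(0, 1, 2, 1, 0))), min_run = 2)
  expect_equal(classify_curvature(tent[1, ]), "concave")
  vee <- detect_sign_changepoints(compute_slopes(
    unit_component(c(2, 1, 0, 1, 2))), min_run = 2)
  expect_equal(classify_curvature(vee[1, ]), "convex")
})

test_that("mirroring the feature axis maps concave results to concave", {
  for (seed in 1:5) {
    vals <- withr::with_seed(seed, cumsum(rnorm(9)))
    cmp <- unit_component(vals)
    mirrored <- component_function(
      "x", thresholds = -rev(cmp$thresholds), values = rev(vals),
      bin_repr = -rev(cmp$bin_repr), bin_counts = rev(cmp$bin_counts))
    cp <- detect_sign_changepoints(compute_slopes(cmp), min_run = 2)
    cpm <- detect_sign_changepoints(compute_slopes(mirrored), min_run = 2)
    expect_equal(sort(cpm$curvature), sort(cp$curvature))
    # a concave peak at bin k maps to a concave peak at bin m + 1 - k
    m <- length(vals)
    pk <- riskaudit:::changepoint_bins(cp, vals, "concave")
    pkm <- riskaudit:::changepoint_bins(cpm, rev(vals), "concave")
    expect_equal(sort(pkm), sort(m + 1L - pk))
  }
})

test_that("scanning an unbagged model warns and never flags", {
  tab <- small_cohort(500, seed = 91)
  m <- fit_gam(tab, fit_config(n_rounds = 40, max_bins = 8, seed = 1,
                               early_stop_patience = 0))
  expect_warning(rep <- scan_artifacts(m, tab), "point estimates")
  expect_false(any(rep$discontinuities$flagged))
  expect_false(any(rep$nonmonotonicities$flagged))
  expect_true(all(is.na(rep$discontinuities$bag_support)))
})

test_that("bagged scans produce ranked, serializable reports", {
  p0 <- make_untreated_risk()
  p1 <- make_treated_risk(benefit_curve("flattens_risk"), p0)
  sc <- simulation_scenario(p0, p1, adherence_policy("strict", 5))
  tab <- sample_cohort(sc, 4000, n_nuisance = 1, seed = 7)
  m <- fit_bagged_gam(tab, fit_config(n_rounds = 80, max_bins = 16,
                                      n_bags = 4, seed = 7,
                                      early_stop_patience = 0))
  rep <- scan_artifacts(m, tab, support_level = 0.95)
  d <- rep$discontinuities
  expect_equal(d$bag_support, sort(d$bag_support, decreasing = TRUE))
  top_support <- d[d$bag_support == d$bag_support[1], ]
  expect_equal(abs(top_support$t_d),
               sort(abs(top_support$t_d), decreasing = TRUE))
  expect_true(all(d$bag_support >= 0 & d$bag_support <= 1))
  # the protocol threshold dominates even in this small cohort
  expect_equal(d$feature[1], "biomarker")
  expect_lt(abs(d$threshold[1] - 5), 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_artifact_report(rep, path)
  rep2 <- read_artifact_report(path)
  expect_equal(rep2$discontinuities$t_d, d$t_d)
  expect_equal(rep2$nonmonotonicities$curvature, rep$nonmonotonicities$curvature)
})
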