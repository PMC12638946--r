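#' Intrinsic (untreated) risk curve
#'
#' Untreated biological risk is modelled as smoothly and strictly increasing
#' in the biomarker: `p0(x) = plogis(a + b * x)` with `b > 0`.
#'
#' @param a intercept on the log-odds scale.
#' @param b slope on the log-odds scale; must be positive.
#' @return a `risk_curve`: a function of the biomarker returning
#'   probabilities in (0, 1).
#' @export
make_untreated_risk <- function(a = -4, b = 1) {
  if (b <= 0)
    stop_ra("untreated risk must increase with the biomarker (b > 0)",
            class = "riskaudit_parameter_error")
  risk_curve(function(x) plogis(a + b * x),
             label = sprintf("logistic(a=%g, b=%g)", a, b))
}

#' Wrap an arbitrary risk function as a risk curve
#'
#' Escape hatch for non-monotone intrinsic risk (e.g. a U-shaped curve with
#' a healthy range in the middle), used to probe detector specificity.
#'
#' @param fun function of the biomarker returning probabilities in (0, 1).
#' @param label free-text description.
#' @return a `risk_curve`.
#' @export
make_risk_curve <- function(fun, label = "custom") {
  stopifnot(is.function(fun))
  risk_curve(fun, label)
}

risk_curve <- function(fun, label) {
  structure(fun, label = label, class = c("risk_curve", "function"))
}

#' Treatment benefit curve
#'
#' Four stylized short-term views of what treatment does to risk:
#' * `flattens_risk`: treated risk is a constant `level` regardless of the
#'   biomarker (a highly effective intervention caps risk outright);
#' * `limits_risk`: treated risk is `min(p0(x), cap)` (effective only above
#'   the cap);
#' * `reduces_biomarker`: treatment shifts the biomarker down, so
#'   `p1(x) = p0(x - shift)`;
#' * `constant_benefit`: a fixed log-odds reduction,
#'   `p1(x) = plogis(qlogis(p0(x)) - offset)`.
#'
#' @param kind one of `"flattens_risk"`, `"limits_risk"`,
#'   `"reduces_biomarker"`, `"constant_benefit"`.
#' @param level,cap,shift,offset kind-specific parameter (see above).
#' @return a `benefit_curve`.
#' @export
benefit_curve <- function(kind = c("flattens_risk", "limits_risk",
                                   "reduces_biomarker", "constant_benefit"),
                          level = NULL, cap = NULL, shift = NULL,
                          offset = NULL) {
  kind <- match.arg(kind)
  par <- switch(kind,
    flattens_risk = {
      level <- level %||% 0.15
      if (level <= 0 || level >= 1)
        stop_ra("level must be in (0,1)", class = "riskaudit_parameter_error")
      list(level = level)
    },
    limits_risk = {
      cap <- cap %||% 0.3
      if (cap <= 0 || cap >= 1)
        stop_ra("cap must be in (0,1)", class = "riskaudit_parameter_error")
      list(cap = cap)
    },
    reduces_biomarker = {
      shift <- shift %||% 2
      if (shift <= 0)
        stop_ra("shift must be positive", class = "riskaudit_parameter_error")
      list(shift = shift)
    },
    constant_benefit = {
      offset <- offset %||% 1.5
      if (offset <= 0)
        stop_ra("offset must be positive", class = "riskaudit_parameter_error")
      list(offset = offset)
    })
  structure(list(kind = kind, params = par), class = "benefit_curve")
}

#' Treated risk curve implied by a benefit curve
#'
#' @param benefit a [benefit_curve()].
#' @param p0 the untreated `risk_curve`.
#' @return a `risk_curve` for treated patients.
#' @export
make_treated_risk <- function(benefit, p0) {
  stopifnot(inherits(benefit, "benefit_curve"), is.function(p0))
  pr <- benefit$params
  fun <- switch(benefit$kind,
    flattens_risk = function(x) rep(pr$level, length(x)),
    limits_risk = function(x) pmin(p0(x), pr$cap),
    reduces_biomarker = function(x) p0(x - pr$shift),
    constant_benefit = function(x) plogis(qlogis(p0(x)) - pr$offset))
  risk_curve(fun, label = benefit$kind)
}

#' Treatment adherence policy
#'
#' The probability of receiving treatment as a function of the biomarker:
#' strict adherence is a step at the threshold, loose guidance is a logistic
#' ramp `plogis((x - threshold) / width)`.
#'
#' @param kind `"strict"` or `"loose"`.
#' @param threshold decision threshold in biomarker units.
#' @param width ramp width in biomarker units (loose only).
#' @return an `adherence_policy`: a function of the biomarker returning
#'   treatment probabilities.
#' @export
adherence_policy <- function(kind = c("strict", "loose"), threshold,
                             width = 0.5) {
  kind <- match.arg(kind)
  if (kind == "loose" && width <= 0)
    stop_ra("width must be positive", class = "riskaudit_parameter_error")
  fun <- if (kind == "strict") {
    function(x) as.numeric(x >= threshold)
  } else {
    function(x) plogis((x - threshold) / width)
  }
  structure(fun, kind = kind, threshold = threshold,
            width = if (kind == "loose") width,
            class = c("adherence_policy", "function"))
}

#' Assemble a treatment-threshold simulation scenario
#'
#' A scenario holds the untreated and treated risk curves, the adherence
#' policy, a biomarker grid with a sampling density, and the composed
#' population risk `p(x) = pi(x) p1(x) + (1 - pi(x)) p0(x)` — what an
#' observational dataset records when the treatment flag is hidden.
#'
#' @param p0 untreated `risk_curve`.
#' @param p1 treated `risk_curve` (see [make_treated_risk()]).
#' @param policy an [adherence_policy()].
#' @param domain biomarker domain, length-2 numeric.
#' @param step grid step.
#' @param density_mean,density_sd parameters of the truncated-normal
#'   biomarker sampling density on the domain.
#' @return a `simulation_scenario`.
#' @export
simulation_scenario <- function(p0, p1, policy, domain = c(0, 10),
                                step = 0.05, density_mean = 5,
                                density_sd = 2) {
  stopifnot(is.function(p0), is.function(p1), is.function(policy),
            length(domain) == 2L, domain[1] < domain[2], step > 0)
  grid <- seq(domain[1], domain[2], by = step)
  p0g <- p0(grid); p1g <- p1(grid); pig <- policy(grid)
  if (any(p0g <= 0 | p0g >= 1) || any(p1g <= 0 | p1g >= 1))
    stop_ra("risk curves must stay inside (0,1) on the domain",
            class = "riskaudit_parameter_error")
  if (any(pig < 0 | pig > 1))
    stop_ra("adherence policy must return probabilities",
            class = "riskaudit_parameter_error")
  dens <- truncnorm_density(grid, density_mean, density_sd, domain)
  structure(
    list(p0 = p0, p1 = p1, policy = policy, domain = domain, step = step,
         grid = grid, density = dens,
         density_params = list(mean = density_mean, sd = density_sd)),
    class = "simulation_scenario"
  )
}

truncnorm_density <- function(grid, mean, sd, domain) {
  z <- pnorm((domain[2] - mean) / sd) - pnorm((domain[1] - mean) / sd)
  dnorm(grid, mean, sd) / z
}

#' Observed population risk of a scenario
#'
#' @param scenario a [simulation_scenario()].
#' @return a data frame with columns `x`, `p0`, `p1`, `pi`, `p` on the grid.
#' @export
compose_population_risk <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  x <- scenario$grid
  p0 <- scenario$p0(x); p1 <- scenario$p1(x); pi_ <- scenario$policy(x)
  data.frame(x = x, p0 = p0, p1 = p1, pi = pi_,
             p = pi_ * p1 + (1 - pi_) * p0)
}

#' Optimal treatment threshold of a scenario
#'
#' The optimal threshold is where untreated risk crosses above treated risk:
#' the smallest grid point at which treatment is strictly beneficial
#' (`p0 > p1`), provided the benefit changes sign at most once on the grid.
#' When treatment is beneficial everywhere the lower domain bound is
#' returned with `crossing = "treat_everyone"`; when it never helps, the
#' upper bound with `crossing = "no_crossing"`.
#'
#' @param scenario a [simulation_scenario()].
#' @return a list with `x_star` and `crossing`
#'   (`"crossing"`, `"treat_everyone"`, or `"no_crossing"`).
#' @export
optimal_threshold <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  x <- scenario$grid
  d <- scenario$p0(x) - scenario$p1(x)
  eps <- 1e-12
  pos <- d > eps; neg <- d < -eps
  if (!any(pos))
    return(list(x_star = x[length(x)], crossing = "no_crossing"))
  first_pos <- which(pos)[1L]
  if (!any(neg)) {
    if (first_pos == 1L)
      return(list(x_star = x[1L], crossing = "treat_everyone"))
    return(list(x_star = x[first_pos], crossing = "crossing"))
  }
  if (any(neg[first_pos:length(x)]) || any(pos[seq_len(which(neg)[1L])]))
    stop_ra("p0 - p1 changes sign more than once; refine the scenario",
            class = "riskaudit_parameter_error")
  list(x_star = x[first_pos], crossing = "crossing")
}

#' Excess population risk of a policy relative to the optimal threshold
#'
#' The density-weighted integral of population risk under `policy` minus
#' population risk under strict adherence at the optimal threshold `x*`:
#' `integral of (p_policy(x) - p_optimal(x)) * density(x) dx`. Zero when the
#' policy coincides with the optimal strict policy; positive under either
#' undertreatment (threshold above `x*`) or overtreatment (below).
#'
#' @param scenario a [simulation_scenario()].
#' @param policy an [adherence_policy()]; defaults to the scenario's.
#' @param density optional density values on the scenario grid (normalized
#'   internally); defaults to the scenario's truncated-normal density.
#' @return nonnegative scalar (up to quadrature error).
#' @export
excess_risk <- function(scenario, policy = NULL, density = NULL) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  policy <- policy %||% scenario$policy
  opt <- optimal_threshold(scenario)
  # refine the grid just around the step discontinuities of the strict
  # policies, otherwise the trapezoid rule smears each jump over one cell
  steps <- opt$x_star
  if (identical(attr(policy, "kind"), "strict"))
    steps <- c(steps, attr(policy, "threshold"))
  dom <- scenario$domain
  steps <- steps[steps > dom[1] & steps < dom[2]]
  x <- sort(unique(c(scenario$grid, steps, steps - 1e-9)))
  dens <- if (is.null(density)) {
    dp <- scenario$density_params
    truncnorm_density(x, dp$mean, dp$sd, dom)
  } else {
    stats::approx(scenario$grid, density, xout = x, rule = 2)$y
  }
  dens <- dens / pracma::trapz(x, dens)
  p0 <- scenario$p0(x); p1 <- scenario$p1(x)
  pi_pol <- policy(x)
  pi_opt <- switch(opt$crossing,
    crossing = as.numeric(x >= opt$x_star),
    treat_everyone = rep(1, length(x)),
    no_crossing = rep(0, length(x)))
  p_pol <- pi_pol * p1 + (1 - pi_pol) * p0
  p_opt <- pi_opt * p1 + (1 - pi_opt) * p0
  pracma::trapz(x, (p_pol - p_opt) * dens)
}

#' Sample a patient-level synthetic cohort from a scenario
#'
#' Biomarker values are drawn from the scenario's truncated-normal density;
#' treatment is assigned by the adherence policy; the outcome is Bernoulli
#' with the treated or untreated risk accordingly. Nuisance features are
#' independent standard-normal draws (no relation to the outcome). The
#' treatment flag is generated but *excluded* from the exported feature set:
#' treatment acting as an unobserved confounder is precisely the condition
#' being emulated. The flag is retained in the `treated` attribute.
#'
#' @param scenario a [simulation_scenario()].
#' @param n cohort size.
#' @param n_nuisance number of nuisance features.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return a [patient_table()] with features `biomarker`,
#'   `nuisance_1..n_nuisance` and outcome `outcome`; attributes `treated`
#'   and `scenario_provenance`.
#' @export
sample_cohort <- function(scenario, n, n_nuisance = 2L, seed = 1L) {
  stopifnot(inherits(scenario, "simulation_scenario"), n >= 1)
  dp <- scenario$density_params
  dom <- scenario$domain
  dat <- withr::with_seed(as.integer(seed), {
    lo <- pnorm((dom[1] - dp$mean) / dp$sd)
    hi <- pnorm((dom[2] - dp$mean) / dp$sd)
    x <- dp$mean + dp$sd * qnorm(runif(n, lo, hi))
    treated <- rbinom(n, 1L, scenario$policy(x))
    p <- ifelse(treated == 1L, scenario$p1(x), scenario$p0(x))
    outcome <- rbinom(n, 1L, p)
    nuis <- if (n_nuisance > 0L)
      matrix(rnorm(n * n_nuisance), nrow = n) else NULL
    list(x = x, treated = treated, outcome = outcome, nuis = nuis)
  })
  df <- data.frame(biomarker = dat$x)
  kinds <- c(biomarker = "continuous")
  if (n_nuisance > 0L) {
    nn <- paste0("nuisance_", seq_len(n_nuisance))
    for (j in seq_len(n_nuisance)) df[[nn[j]]] <- dat$nuis[, j]
    kinds <- c(kinds, stats::setNames(rep("continuous", n_nuisance), nn))
  }
  df$outcome <- dat$outcome
  tab <- patient_table(df, dataset_schema("outcome", kinds))
  attr(tab, "treated") <- dat$treated
  attr(tab, "scenario_provenance") <- list(
    policy_kind = attr(scenario$policy, "kind"),
    threshold = attr(scenario$policy, "threshold"),
    seed = as.integer(seed), n = n, n_nuisance = n_nuisance)
  tab
}

#' Default parameters of the eight-scenario simulation suite
#'
#' Four treatment benefit kinds crossed with two adherence policies. The
#' decision threshold defaults to the round number 5 on a biomarker domain
#' of `[0, 10]` — deliberately misaligned above the optimal threshold for
#' every benefit kind, so strict scenarios carry a jump discontinuity at the
#' threshold and loose scenarios a concave non-monotonicity near the
#' population-risk peak.
#'
#' @param tau decision threshold.
#' @param width loose-policy ramp width.
#' @param n cohort size per scenario.
#' @param n_nuisance nuisance features per cohort.
#' @param seed base seed (scenario i uses `seed + i`).
#' @param a,b untreated-risk parameters (see [make_untreated_risk()]).
#' @param level,cap,shift,offset benefit parameters (see [benefit_curve()]).
#' @return a list of suite parameters.
#' @export
suite_config <- function(tau = 5, width = 0.5, n = 20000L, n_nuisance = 2L,
                         seed = 1L, a = -4, b = 1, level = 0.15, cap = 0.3,
                         shift = 2, offset = 1.5) {
  list(tau = tau, width = width, n = as.integer(n),
       n_nuisance = as.integer(n_nuisance), seed = as.integer(seed),
       a = a, b = b, level = level, cap = cap, shift = shift, offset = offset)
}

#' Generate the eight-scenario simulation suite
#'
#' Crosses the four benefit kinds with strict and loose adherence, yielding
#' eight scenario bundles. Each bundle holds the scenario, its composed
#' population-risk curve table, a sampled patient-level cohort, the optimal
#' threshold and the artifact class that threshold-guided treatment is
#' expected to imprint on observed risk: a discontinuity at the honored
#' threshold under strict adherence, a concave non-monotonicity under loose
#' guidance.
#'
#' @param config a [suite_config()].
#' @param sample_cohorts set `FALSE` to skip cohort sampling (curves only).
#' @return a named list of 8 bundles.
#' @export
run_scenario_suite <- function(config = suite_config(), sample_cohorts = TRUE) {
  p0 <- make_untreated_risk(config$a, config$b)
  kinds <- c("flattens_risk", "limits_risk", "reduces_biomarker",
             "constant_benefit")
  policies <- c("strict", "loose")
  bundles <- list()
  i <- 0L
  for (bk in kinds) {
    ben <- benefit_curve(bk, level = config$level, cap = config$cap,
                         shift = config$shift, offset = config$offset)
    p1 <- make_treated_risk(ben, p0)
    for (pk in policies) {
      i <- i + 1L
      pol <- adherence_policy(pk, threshold = config$tau,
                              width = config$width)
      sc <- simulation_scenario(p0, p1, pol)
      nm <- paste(bk, pk, sep = "_")
      bundles[[nm]] <- list(
        name = nm, benefit = ben, policy_kind = pk, scenario = sc,
        curves = compose_population_risk(sc),
        optimal = optimal_threshold(sc),
        expected_artifact = if (pk == "strict") "discontinuity"
                            else "non_monotonicity",
        cohort = if (sample_cohorts)
          sample_cohort(sc, config$n, config$n_nuisance,
                        seed = config$seed + i),
        seed = config$seed + i
      )
    }
  }
  bundles
}
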