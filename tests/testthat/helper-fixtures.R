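# Shared fixture builders. Everything is generated in code; no data files.

# A small patient table with one continuous and one boolean feature whose
# outcome actually depends on both (logit p = -1 + 1.2*(x > 5) + 0.8*b).
small_cohort <- function(n = 400, seed = 1) {
  df <- withr::with_seed(seed, {
    x <- runif(n, 0, 10)
    b <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, plogis(-1 + 1.2 * (x > 5) + 0.8 * b))
    data.frame(x = x, b = b, outcome = y)
  })
  patient_table(df, dataset_schema("outcome",
                                   c(x = "continuous", b = "boolean")))
}

# Hand-built component on unit-width bins with midpoint representatives.
unit_component <- function(values, feature = "x", start = 0) {
  m <- length(values)
  component_function(feature, thresholds = start + seq_len(m - 1L),
                     values = values,
                     bin_repr = start + seq_len(m) - 0.5,
                     bin_counts = rep(10, m))
}

# Hand-built one-component model over a known grid.
unit_model <- function(values, intercept = 0, feature = "x") {
  additive_risk_model(intercept, list(unit_component(values, feature)))
}

# Independent brute-force Bernoulli log-likelihood: per-row loop, own bin
# lookup, no reuse of the package's predict path.
brute_force_ll <- function(model, table) {
  y <- table$outcome
  total <- 0
  for (i in seq_len(table$n)) {
    eta <- model$intercept
    for (cmp in model$components) {
      xi <- table$features[[cmp$feature]][i]
      if (cmp$kind == "nominal") {
        v <- cmp$values[which(cmp$levels == as.character(xi))]
      } else if (is.na(xi)) {
        v <- if (is.null(cmp$missing_bin_value)) 0 else cmp$missing_bin_value
      } else {
        k <- sum(cmp$thresholds <= xi) + 1L
        v <- cmp$values[k]
      }
      eta <- eta + v
    }
    p <- min(max(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)
    total <- total + if (y[i] == 1) log(p) else log(1 - p)
  }
  total
}

# Cohort sampled from a hand-built piecewise-constant model (ground truth
# known exactly on the model's own bins).
sample_from_model <- function(model, n, seed, xmin = 0, xmax = NULL) {
  cmp <- model$components[[1L]]
  if (is.null(xmax)) xmax <- max(cmp$thresholds) + 1
  df <- withr::with_seed(seed, {
    x <- runif(n, xmin, xmax)
    p <- plogis(model$intercept + evaluate_component(cmp, x))
    data.frame(x = x, outcome = rbinom(n, 1, p))
  })
  names(df)[1] <- cmp$feature
  kinds <- stats::setNames("continuous", cmp$feature)
  patient_table(df, dataset_schema("outcome", kinds))
}
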