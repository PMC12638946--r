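#' Fitting configuration for the boosted additive risk model
#'
#' Defaults follow common practice for EBM-style tree-boosted GAMs: many weak
#' rounds at a small learning rate, quantile binning, and bootstrap bagging
#' for confidence bands. Early stopping monitors logistic log-loss on a
#' held-out validation split (or on out-of-bag rows inside [fit_bagged_gam()]).
#'
#' @param n_rounds maximum boosting rounds (each round visits every feature
#'   once, in round-robin order). `0` gives an intercept-only model.
#' @param learning_rate shrinkage applied to every stump update.
#' @param max_bins maximum quantile bins per continuous feature.
#' @param n_bags bootstrap bags for [fit_bagged_gam()].
#' @param bag_fraction fraction of rows drawn (with replacement) per bag.
#' @param seed integer seed; all randomness in fitting derives from it.
#' @param early_stop_patience stop when validation loss has not improved for
#'   this many rounds; `0` disables early stopping.
#' @param validation_fraction held-out fraction used for early stopping in
#'   [fit_gam()] (ignored by bags, which validate out-of-bag).
#' @param ci_level level of the empirical bootstrap confidence bands.
#' @param min_gain_mult minimum-gain rule for accepting a stump: a split is
#'   applied only when its squared-error gain improvement over the no-split
#'   fit, normalized by the current residual variance (a chi-square(1)-scale
#'   statistic for any one split under no signal), exceeds
#'   `min_gain_mult * log(number of candidate splits)` — the scan-statistic
#'   noise scale for the best of many candidate splits. Uninformative
#'   features thus keep near-flat components instead of slowly absorbing
#'   per-bin noise; real structure exceeds the gate by orders of magnitude.
#'   `0` disables the rule.
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(n_rounds = 500L, learning_rate = 0.1, max_bins = 64L,
                       n_bags = 100L, bag_fraction = 1.0, seed = 1L,
                       early_stop_patience = 50L, validation_fraction = 0.15,
                       ci_level = 0.95, min_gain_mult = 0.1) {
  stopifnot(n_rounds >= 0, learning_rate > 0, max_bins >= 1, n_bags >= 1,
            bag_fraction > 0, bag_fraction <= 1, early_stop_patience >= 0,
            validation_fraction >= 0, validation_fraction < 1,
            ci_level > 0, ci_level < 1, min_gain_mult >= 0)
  structure(
    list(n_rounds = as.integer(n_rounds),
         learning_rate = as.numeric(learning_rate),
         max_bins = as.integer(max_bins), n_bags = as.integer(n_bags),
         bag_fraction = as.numeric(bag_fraction), seed = as.integer(seed),
         early_stop_patience = as.integer(early_stop_patience),
         validation_fraction = as.numeric(validation_fraction),
         ci_level = as.numeric(ci_level),
         min_gain_mult = as.numeric(min_gain_mult)),
    class = "fit_config"
  )
}

#' Quantile bin edges for a continuous feature
#'
#' Cut points are quantiles of the observed values; when there are no more
#' distinct values than `max_bins`, edges are midpoints between consecutive
#' distinct values (so e.g. a 0/1 feature gets the single edge 0.5). Edges
#' that would bound an empty training bin are merged away. A constant feature
#' yields zero edges (a single bin, untestable for artifacts).
#'
#' @param values numeric vector (missing values ignored).
#' @param max_bins maximum number of bins.
#' @return numeric vector of strictly increasing bin edges (possibly empty).
#' @export
discretize_feature <- function(values, max_bins) {
  v <- values[is.finite(values)]
  d <- sort(unique(v))
  if (length(d) < 2L) return(numeric(0))
  if (length(d) <= max_bins) {
    edges <- (d[-length(d)] + d[-1L]) / 2
  } else {
    probs <- seq_len(max_bins - 1L) / max_bins
    edges <- unique(quantile(v, probs = probs, names = FALSE, type = 7))
  }
  # drop edges bounding empty bins (possible under heavy ties)
  repeat {
    idx <- findInterval(v, edges) + 1L
    counts <- tabulate(idx, length(edges) + 1L)
    if (!any(counts == 0L) || !length(edges)) break
    i <- which(counts == 0L)[1L]
    edges <- edges[-max(i - 1L, 1L)]
  }
  edges
}

# Per-feature bin structure shared by point fits and all bags.
prepare_bins <- function(table, max_bins) {
  feats <- table$schema$features
  out <- vector("list", nrow(feats))
  names(out) <- feats$name
  for (i in seq_len(nrow(feats))) {
    nm <- feats$name[i]; kind <- feats$kind[i]
    v <- table$features[[nm]]
    if (kind == "nominal") {
      levels <- sort(unique(v[!is.na(v)]))
      idx <- match(v, levels)
      nb <- length(levels)
      repr <- NULL; edges <- NULL
    } else {
      edges <- discretize_feature(as.numeric(v),
                                  if (kind == "boolean") 2L else max_bins)
      nb <- length(edges) + 1L
      idx <- ifelse(is.na(v), NA_integer_, findInterval(v, edges) + 1L)
      repr <- vapply(seq_len(nb), function(b) {
        xb <- v[!is.na(idx) & idx == b]
        if (length(xb)) mean(xb) else NA_real_
      }, numeric(1))
      fallback <- default_bin_repr(edges)
      repr[is.na(repr)] <- fallback[is.na(repr)]
    }
    out[[i]] <- list(name = nm, kind = kind, edges = edges, levels = levels_or_null(kind, v),
                     idx = idx, nbins = nb, repr = repr,
                     has_missing = anyNA(idx),
                     counts_full = tabulate(idx[!is.na(idx)], nb),
                     miss_full = sum(is.na(idx)))
  }
  out
}

levels_or_null <- function(kind, v) {
  if (kind == "nominal") sort(unique(v[!is.na(v)])) else NULL
}

clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# Damped Newton leaf value for the logistic loss: gradient sum over hessian
# sum, capped so near-pure leaves cannot produce runaway log-odds steps.
newton_step <- function(S, W, cap = 2) {
  pmin(pmax(S / W, -cap), cap)
}

log_loss <- function(y, p) {
  p <- clamp_prob(p)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Round-robin boosting core. Returns uncentered per-bin values plus the
# rounds actually run and the validation-loss trajectory.
boost_core <- function(y, bins, config, fit_rows, val_rows = integer(0)) {
  nf <- length(bins)
  lr <- config$learning_rate
  y_fit <- y[fit_rows]
  y_val <- y[val_rows]
  p_base <- clamp_prob(mean(y_fit), 1e-6)
  intercept <- logit(p_base)
  eta_fit <- rep(intercept, length(fit_rows))
  eta_val <- rep(intercept, length(val_rows))

  st <- lapply(bins, function(b) {
    idx <- b$idx[fit_rows]
    ok <- !is.na(idx)
    counts <- tabulate(idx[ok], b$nbins)
    # rows sorted by bin: per-bin gradient sums become a cumsum + diff
    ord <- order(idx, na.last = NA)
    list(idx = idx, ok = ok, all_ok = all(ok), counts = counts,
         ord = ord, ends = cumsum(counts),
         cumN = cumsum(counts)[-b$nbins],
         idx_val = b$idx[val_rows],
         miss_fit = which(!ok), n_miss = sum(!ok),
         vals = numeric(b$nbins),
         miss_val = if (b$has_missing) 0 else NULL)
  })

  monitor <- length(val_rows) > 0L && config$early_stop_patience > 0L
  best_loss <- Inf; best_round <- 0L; val_trace <- numeric(0)
  rounds_run <- 0L

  for (round in seq_len(config$n_rounds)) {
    for (f in seq_len(nf)) {
      b <- bins[[f]]; s <- st[[f]]
      if (b$nbins < 2L && !b$has_missing) next
      p <- plogis(eta_fit)
      resid <- y_fit - p
      wgt <- p * (1 - p)
      delta <- numeric(b$nbins)
      gate <- config$min_gain_mult * log(max(b$nbins - 1L, 1L))
      if (b$nbins >= 2L) {
        # per-bin gradient and hessian sums via one pass over sorted rows
        rs <- resid[s$ord]
        cs <- c(0, cumsum(rs))
        cw <- c(0, cumsum(wgt[s$ord]))
        ce <- cs[s$ends + 1L]; we <- cw[s$ends + 1L]
        S <- ce - c(0, ce[-b$nbins])
        W <- we - c(0, we[-b$nbins])
        totS <- sum(S); totW <- sum(W); totN <- sum(s$counts)
        # gate statistic: squared-error gain on gradients over the residual
        # variance. The variance includes still-unexplained signal from the
        # other features, so chance alignment with that signal in early
        # rounds does not open the gate.
        sigma2 <- sum(rs * rs) / max(totN, 1L)
        g0 <- totS^2 / totN
        if (b$kind == "nominal") {
          pos <- s$counts > 0L
          gimp <- sum(S[pos]^2 / s$counts[pos]) - g0
          if (gimp > gate * sigma2 && all(W[pos] > 0)) {
            delta[pos] <- lr * newton_step(S[pos], W[pos])
          }
        } else {
          cumS <- cumsum(S)[-b$nbins]
          cumN <- s$cumN
          cumW <- cumsum(W)[-b$nbins]
          valid <- cumN > 0L & (totN - cumN) > 0L & cumW > 0 &
            (totW - cumW) > 0
          if (any(valid)) {
            gain <- rep(-Inf, b$nbins - 1L)
            gain[valid] <- cumS[valid]^2 / cumN[valid] +
              (totS - cumS[valid])^2 / (totN - cumN[valid])
            sp <- which.max(gain)  # ties resolve to the smaller bin index
            if (gain[sp] - g0 > gate * sigma2) {
              vL <- newton_step(cumS[sp], cumW[sp])
              vR <- newton_step(totS - cumS[sp], totW - cumW[sp])
              delta <- lr * c(rep(vL, sp), rep(vR, b$nbins - sp))
            }
          }
        }
        if (any(delta != 0)) {
          s$vals <- s$vals + delta
          if (s$all_ok) {
            eta_fit <- eta_fit + delta[s$idx]
          } else {
            eta_fit[s$ok] <- eta_fit[s$ok] + delta[s$idx[s$ok]]
          }
          if (length(val_rows)) {
            vok <- !is.na(s$idx_val)
            eta_val[vok] <- eta_val[vok] + delta[s$idx_val[vok]]
          }
        }
      }
      if (b$has_missing && s$n_miss > 0L) {
        Sm <- sum(resid[s$miss_fit])
        Wm <- sum(wgt[s$miss_fit])
        sig2m <- sum(resid * resid) / length(resid)
        if (Wm > 0 && Sm^2 / s$n_miss > config$min_gain_mult * sig2m) {
          dmiss <- lr * newton_step(Sm, Wm)
          s$miss_val <- s$miss_val + dmiss
          eta_fit[s$miss_fit] <- eta_fit[s$miss_fit] + dmiss
          if (length(val_rows)) {
            vmiss <- is.na(s$idx_val)
            eta_val[vmiss] <- eta_val[vmiss] + dmiss
          }
        }
      }
      st[[f]] <- s
    }
    rounds_run <- round
    if (monitor) {
      loss <- log_loss(y_val, plogis(eta_val))
      val_trace <- c(val_trace, loss)
      if (loss < best_loss - 1e-10) {
        best_loss <- loss; best_round <- round
      } else if (round - best_round >= config$early_stop_patience) {
        break
      }
    }
  }
  list(intercept = intercept,
       vals = lapply(st, `[[`, "vals"),
       miss_vals = lapply(st, `[[`, "miss_val"),
       counts = lapply(st, `[[`, "counts"),
       n_miss = vapply(st, `[[`, integer(1), "n_miss"),
       rounds_run = rounds_run, val_trace = val_trace)
}

# Mean-center per-bin values with given weights; the intercept absorbs the
# shifts so predictions are unchanged.
center_fit <- function(fit, weights, miss_weights) {
  shift_total <- 0
  for (f in seq_along(fit$vals)) {
    w <- weights[[f]]
    mv <- fit$miss_vals[[f]]
    mw <- miss_weights[f]
    tot <- sum(w) + if (!is.null(mv)) mw else 0
    if (tot <= 0) next
    sh <- (sum(fit$vals[[f]] * w) + if (!is.null(mv)) mv * mw else 0) / tot
    fit$vals[[f]] <- fit$vals[[f]] - sh
    if (!is.null(mv)) fit$miss_vals[[f]] <- mv - sh
    shift_total <- shift_total + sh
  }
  fit$intercept <- fit$intercept + shift_total
  fit
}

#' Assemble an additive risk model from components
#'
#' Builds a model directly from an intercept and a list of
#' [component_function()]s — the entry point for auditing externally fitted
#' curves (e.g. re-imported with [import_component_curves()]) with
#' [log_likelihood()] and [discontinuity_statistic()], and for constructing
#' known ground-truth models in simulations.
#'
#' @param intercept log-odds intercept.
#' @param components list of [component_function()]s.
#' @param schema optional [dataset_schema()]; inferred from the components
#'   when omitted (outcome column `"outcome"`).
#' @param config a [fit_config()] (metadata only).
#' @return an `additive_risk_model`.
#' @export
additive_risk_model <- function(intercept, components, schema = NULL,
                                config = fit_config()) {
  stopifnot(is.finite(intercept), length(components) >= 0L)
  for (cmp in components) stopifnot(inherits(cmp, "component_function"))
  names(components) <- vapply(components, `[[`, character(1), "feature")
  if (is.null(schema)) {
    schema <- if (length(components)) {
      kinds <- vapply(components, `[[`, character(1), "kind")
      dataset_schema("outcome", kinds)
    } else {
      empty_schema("outcome")
    }
  }
  new_additive_risk_model(intercept, components, config, schema)
}

new_additive_risk_model <- function(intercept, components, fit_config, schema,
                                    meta = list(), bag_models = NULL) {
  structure(
    list(intercept = intercept, components = components,
         fit_config = fit_config, schema = schema, meta = meta,
         bag_models = bag_models),
    class = "additive_risk_model"
  )
}

#' Fit a piecewise-constant additive logistic risk model
#'
#' Round-robin gradient boosting: every round visits the features in a fixed
#' order; each visit fits the best single split (a depth-1 stump) on the
#' feature's bin grid to the current gradient of the logistic log-loss,
#' using damped Newton leaf values (per-leaf gradient sum over hessian sum),
#' shrinks the stump by the learning rate, and accumulates it into that
#' feature's piecewise-constant component. Splitting on every feature in turn
#' forces the features to share explained signal, which keeps hidden effects
#' visible in the component shapes. Missing continuous values occupy a
#' dedicated missing bin updated alongside the splits; nominal features get a
#' per-level update (categories have no split order). After boosting, each
#' component is centered to training-weighted mean zero and the intercept
#' absorbs the shifts.
#'
#' @param table a [patient_table()].
#' @param config a [fit_config()].
#' @return an `additive_risk_model` with one [component_function()] per
#'   schema feature.
#' @export
fit_gam <- function(table, config = fit_config()) {
  stopifnot(inherits(table, "patient_table"), inherits(config, "fit_config"))
  y <- table$outcome
  if (length(unique(y)) < 2L)
    stop_ra("outcome has a single class; cannot fit", class = "riskaudit_fit_error")
  bins <- prepare_bins(table, config$max_bins)
  n <- table$n
  rows <- seq_len(n)
  val_rows <- integer(0)
  if (config$early_stop_patience > 0L && config$validation_fraction > 0 &&
      config$n_rounds > 0L) {
    val_rows <- withr::with_seed(config$seed,
      sample.int(n, max(1L, round(n * config$validation_fraction))))
    rows <- setdiff(rows, val_rows)
    if (length(unique(y[rows])) < 2L)
      stop_ra("training split has a single outcome class",
              class = "riskaudit_fit_error")
  }
  fit <- boost_core(y, bins, config, rows, val_rows)
  fit <- center_fit(fit, fit$counts, fit$n_miss)
  components <- build_components(bins, fit, fit$counts, fit$n_miss)
  new_additive_risk_model(
    fit$intercept, components, config, table$schema,
    meta = list(n = n, n_fit = length(rows), rounds_run = fit$rounds_run,
                val_trace = fit$val_trace)
  )
}

build_components <- function(bins, fit, counts, n_miss,
                             ci_lower = NULL, ci_upper = NULL) {
  comps <- vector("list", length(bins))
  names(comps) <- names(bins)
  for (f in seq_along(bins)) {
    b <- bins[[f]]
    comps[[f]] <- component_function(
      b$name, thresholds = b$edges, values = fit$vals[[f]],
      bin_counts = counts[[f]], bin_repr = b$repr,
      ci_lower = ci_lower[[f]], ci_upper = ci_upper[[f]],
      missing_bin_value = fit$miss_vals[[f]],
      kind = b$kind, levels = b$levels
    )
  }
  comps
}

#' Fit a bagged additive risk model with bootstrap confidence bands
#'
#' Fits `n_bags` models on bootstrap resamples of the rows (all bags share
#' the bin grid computed on the full table, so per-bin values are directly
#' comparable across bags). Reported component values are bag means; the
#' confidence band is the empirical `ci_level` quantile interval across bags.
#' Each bag early-stops on its out-of-bag rows. The per-bag component sets
#' and resampled row indices are retained in `bag_models` — [scan_artifacts()]
#' uses them for bag-support estimation on out-of-bag data.
#'
#' @inheritParams fit_gam
#' @return an `additive_risk_model` with confidence bands and `bag_models`.
#' @export
fit_bagged_gam <- function(table, config = fit_config()) {
  stopifnot(inherits(table, "patient_table"), inherits(config, "fit_config"))
  if (config$n_bags < 2L)
    stop_ra("n_bags must be >= 2 for confidence bands", class = "riskaudit_fit_error")
  y <- table$outcome
  if (length(unique(y)) < 2L)
    stop_ra("outcome has a single class; cannot fit", class = "riskaudit_fit_error")
  n <- table$n
  if (n < 10L)
    warning("n < 10: bootstrap resamples will have little diversity")
  bins <- prepare_bins(table, config$max_bins)
  n_draw <- max(1L, round(n * config$bag_fraction))
  bag_rows <- withr::with_seed(config$seed,
    lapply(seq_len(config$n_bags), function(b) sample.int(n, n_draw, replace = TRUE)))
  counts_full <- lapply(bins, `[[`, "counts_full")
  miss_full <- vapply(bins, `[[`, numeric(1), "miss_full")

  bags <- vector("list", config$n_bags)
  for (b in seq_len(config$n_bags)) {
    rows <- bag_rows[[b]]
    oob <- setdiff(seq_len(n), unique(rows))
    if (config$early_stop_patience == 0L) oob <- integer(0)
    fit <- boost_core(y, bins, config, rows, oob)
    # center with full-table weights so curves are comparable across bags
    fit <- center_fit(fit, counts_full, miss_full)
    bags[[b]] <- list(intercept = fit$intercept, vals = fit$vals,
                      miss_vals = fit$miss_vals, rows = rows,
                      rounds_run = fit$rounds_run)
  }

  alpha <- (1 - config$ci_level) / 2
  mean_fit <- list(vals = vector("list", length(bins)),
                   miss_vals = vector("list", length(bins)),
                   intercept = mean(vapply(bags, `[[`, numeric(1), "intercept")))
  ci_lo <- vector("list", length(bins)); ci_hi <- vector("list", length(bins))
  for (f in seq_along(bins)) {
    vm <- do.call(cbind, lapply(bags, function(bg) bg$vals[[f]]))
    mean_fit$vals[[f]] <- rowMeans(vm)
    ci_lo[[f]] <- apply(vm, 1L, quantile, probs = alpha, names = FALSE)
    ci_hi[[f]] <- apply(vm, 1L, quantile, probs = 1 - alpha, names = FALSE)
    mv <- lapply(bags, function(bg) bg$miss_vals[[f]])
    mean_fit$miss_vals[f] <-
      list(if (is.null(mv[[1L]])) NULL else mean(unlist(mv)))
  }
  components <- build_components(bins, mean_fit, counts_full, miss_full,
                                 ci_lower = ci_lo, ci_upper = ci_hi)
  new_additive_risk_model(
    mean_fit$intercept, components, config, table$schema,
    meta = list(n = n, n_bags = config$n_bags,
                rounds_run = vapply(bags, `[[`, integer(1), "rounds_run")),
    bag_models = bags
  )
}

#' Predict log-odds and probabilities from an additive risk model
#'
#' The linear predictor is the intercept plus the sum of the per-feature
#' component contributions. Missing feature values use the component's
#' missing-bin value when one was learned; otherwise they contribute zero
#' (with a warning).
#'
#' @param model an `additive_risk_model`.
#' @param newdata a [patient_table()] or data frame with the schema's
#'   feature columns.
#' @return numeric vector of log-odds ([predict_logit()]) or probabilities in
#'   (0, 1) ([predict_prob()]).
#' @export
predict_logit <- function(model, newdata) {
  stopifnot(inherits(model, "additive_risk_model"))
  df <- if (inherits(newdata, "patient_table")) newdata$features else newdata
  eta <- rep(model$intercept, nrow(df))
  warned <- FALSE
  for (cmp in model$components) {
    if (!cmp$feature %in% names(df))
      stop_ra("feature '", cmp$feature, "' missing from newdata",
              class = "riskaudit_schema_error")
    contrib <- evaluate_component(cmp, df[[cmp$feature]])
    if (anyNA(contrib)) {
      if (!warned) {
        warning("missing values in '", cmp$feature,
                "' with no missing bin: contributing 0")
        warned <- TRUE
      }
      contrib[is.na(contrib)] <- 0
    }
    eta <- eta + contrib
  }
  eta
}

#' @rdname predict_logit
#' @export
predict_prob <- function(model, newdata) {
  plogis(predict_logit(model, newdata))
}

#' @export
print.additive_risk_model <- function(x, ...) {
  cat("<additive_risk_model> intercept ", signif(x$intercept, 4), ", ",
      length(x$components), " components",
      if (!is.null(x$bag_models)) paste0(", ", length(x$bag_models), " bags"),
      "\n", sep = "")
  invisible(x)
}

#' Bernoulli log-likelihood of a patient table under a model
#'
#' Computes `sum(y * log(p) + (1 - y) * log(1 - p))` with predicted
#' probabilities clipped to `[1e-12, 1 - 1e-12]` (with a warning if clipping
#' occurs). Optionally one component is replaced by `component_override`
#' (matched by feature name) — the form used by the discontinuity test, which
#' contrasts the fitted component against its linearized version with all
#' other components fixed.
#'
#' @param model an `additive_risk_model`.
#' @param table a [patient_table()].
#' @param component_override optional [component_function()] replacing the
#'   model's component for the same feature.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(model, table, component_override = NULL) {
  stopifnot(inherits(table, "patient_table"))
  if (!is.null(component_override)) {
    stopifnot(inherits(component_override, "component_function"))
    if (!component_override$feature %in% names(model$components))
      stop_ra("no component named '", component_override$feature, "'",
              class = "riskaudit_schema_error")
    model$components[[component_override$feature]] <- component_override
  }
  p <- plogis(predict_logit(model, table))
  if (any(p < 1e-12 | p > 1 - 1e-12))
    warning("predicted probabilities clipped to [1e-12, 1 - 1e-12]")
  p <- clamp_prob(p)
  y <- table$outcome
  sum(y * log(p) + (1 - y) * log(1 - p))
}
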