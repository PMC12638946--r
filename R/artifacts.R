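#' Locally linearize a component function around one interior bin
#'
#' The discontinuity test contrasts a fitted component against a version with
#' the local jump removed. For interior bin `k`, the linearized component
#' replaces the bin's value by the straight line through the two neighbouring
#' bins' (representative point, value) anchors, evaluated at bin `k`'s own
#' representative point; the component is untouched outside that window.
#' Likelihood evaluation anchors every observation in a bin at the bin's
#' representative point, so when the three bins are already collinear at
#' their representative points, the linearized component equals the base
#' component exactly and the test statistic is exactly zero.
#'
#' @param component a [component_function()] with at least 3 bins.
#' @param bin interior bin index (`2 <= bin <= m - 1`). Outer bins have no
#'   second anchor and cannot be linearized.
#' @return the linearized `component_function` (subclass
#'   `linearized_component`), with attributes `window_bin` and `base_value`.
#' @export
linearize_component <- function(component, bin) {
  stopifnot(inherits(component, "component_function"))
  if (component$kind == "nominal")
    stop_ra("nominal components have no ordered axis to linearize",
            class = "riskaudit_validation_error")
  m <- length(component$values)
  if (m < 3L)
    stop_ra("component needs at least 3 bins to linearize",
            class = "riskaudit_validation_error")
  if (bin < 2L || bin > m - 1L)
    stop_ra("bin must be interior (2..", m - 1L, "); got ", bin,
            class = "riskaudit_boundary_error")
  r <- component$bin_repr
  v <- component$values
  lin <- linear_interp(r[bin - 1L], v[bin - 1L], r[bin + 1L], v[bin + 1L], r[bin])
  out <- component
  out$values[bin] <- lin
  class(out) <- c("linearized_component", class(component))
  attr(out, "window_bin") <- as.integer(bin)
  attr(out, "base_value") <- v[bin]
  out
}

linear_interp <- function(x0, y0, x1, y1, x) {
  y0 + (x - x0) / (x1 - x0) * (y1 - y0)
}

#' Discontinuity test statistic for one component bin
#'
#' `T_d` is the Bernoulli log-likelihood of the table under the fitted model
#' minus the log-likelihood with the tested component locally linearized
#' (all other components and the intercept fixed). A positive `T_d` means
#' the jump is supported by the data; `T_d` is exactly zero when the
#' component is locally collinear (the linearized component then equals the
#' base). Because the two models differ only inside the window, the
#' statistic reduces to a sum over the patients whose feature value falls in
#' the tested bin.
#'
#' @param model an `additive_risk_model`.
#' @param table a [patient_table()].
#' @param feature feature name.
#' @param bin interior bin index of that feature's component.
#' @return scalar `T_d`.
#' @export
discontinuity_statistic <- function(model, table, feature, bin) {
  stopifnot(inherits(model, "additive_risk_model"))
  cmp <- model$components[[feature]]
  if (is.null(cmp))
    stop_ra("no component named '", feature, "'", class = "riskaudit_schema_error")
  lin <- linearize_component(cmp, bin)
  log_likelihood(model, table) - log_likelihood(model, table, lin)
}

#' Slopes of a component function across its thresholds
#'
#' For a component with bins `1..m`, the slope across threshold `j`
#' (`j = 1..m-1`) is the difference of the adjacent bin values divided by
#' the distance between their representative points. Slopes with magnitude
#' at most `slope_zero_tol` get sign 0 (plateaus); the remaining signs feed
#' [detect_sign_changepoints()].
#'
#' @param component a [component_function()] with at least 3 bins.
#' @param slope_zero_tol absolute slope (log-odds per feature unit) below
#'   which a slope counts as zero.
#' @return an object of class `slope_sequence` with elements `feature`,
#'   `index`, `thresholds`, `slopes`, `signs`.
#' @export
compute_slopes <- function(component, slope_zero_tol = 1e-8) {
  stopifnot(inherits(component, "component_function"))
  if (component$kind == "nominal")
    stop_ra("nominal components have no slopes", class = "riskaudit_validation_error")
  m <- length(component$values)
  if (m < 3L)
    stop_ra("component needs at least 3 bins for slopes",
            class = "riskaudit_validation_error")
  slope_sequence(component$feature, component$values, component$bin_repr,
                 component$thresholds, slope_zero_tol)
}

slope_sequence <- function(feature, values, repr, thresholds, slope_zero_tol) {
  m <- length(values)
  s <- diff(values) / diff(repr)
  signs <- sign(s)
  signs[abs(s) <= slope_zero_tol] <- 0
  structure(
    list(feature = feature, index = seq_len(m - 1L), thresholds = thresholds,
         slopes = s, signs = as.integer(signs)),
    class = "slope_sequence"
  )
}

#' Detect persistent sign changes in a slope sequence
#'
#' Zero signs (plateaus) are removed; the remaining signs are segmented into
#' runs, and a changepoint is reported between two adjacent runs of opposite
#' sign when both runs persist for at least `min_run` non-zero slopes — the
#' noise guard that suppresses isolated sign flips.
#'
#' @param slopes a [compute_slopes()] result, or an integer vector of signs.
#' @param min_run minimum run length on each side of a reported flip.
#' @return a data frame with one row per changepoint: `left_index` /
#'   `right_index` (threshold indices of the last slope of the old regime and
#'   first of the new), `from` / `to` (signs), and `curvature`.
#' @export
detect_sign_changepoints <- function(slopes, min_run = 2L) {
  signs <- if (inherits(slopes, "slope_sequence")) slopes$signs else as.integer(slopes)
  empty <- data.frame(left_index = integer(0), right_index = integer(0),
                      from = integer(0), to = integer(0),
                      curvature = character(0), stringsAsFactors = FALSE)
  nz <- which(signs != 0L)
  if (length(nz) < 2L) return(empty)
  r <- rle(signs[nz])
  if (length(r$lengths) < 2L) return(empty)
  ends <- cumsum(r$lengths)
  keep <- which(r$lengths[-length(r$lengths)] >= min_run &
                r$lengths[-1L] >= min_run)
  if (!length(keep)) return(empty)
  out <- data.frame(
    left_index = nz[ends[keep]],
    right_index = nz[ends[keep] + 1L],
    from = r$values[keep],
    to = r$values[keep + 1L],
    stringsAsFactors = FALSE
  )
  out$curvature <- ifelse(out$from > out$to, "concave", "convex")
  out
}

#' Classify the curvature of a slope-sign changepoint
#'
#' A rising-to-falling flip (`+` to `-`) is a peak, hence concave — the
#' counter-causal shape flagged as a treatment artifact. A falling-to-rising
#' flip is a valley, hence convex — the shape of a healthy reference range,
#' never flagged.
#'
#' @param changepoint one row of a [detect_sign_changepoints()] result (or
#'   any list with `from` and `to` signs).
#' @return `"concave"` or `"convex"`.
#' @export
classify_curvature <- function(changepoint) {
  if (changepoint$from > changepoint$to) "concave" else "convex"
}

# Per-bag linear predictor over all table rows, given shared bin indices.
bag_eta <- function(bag, bin_idx, n) {
  eta <- rep(bag$intercept, n)
  for (f in seq_along(bin_idx)) {
    idx <- bin_idx[[f]]
    ok <- !is.na(idx)
    eta[ok] <- eta[ok] + bag$vals[[f]][idx[ok]]
    if (any(!ok)) {
      mv <- bag$miss_vals[[f]] %||% 0
      eta[!ok] <- eta[!ok] + mv
    }
  }
  eta
}

ll_window <- function(y, eta) {
  p <- clamp_prob(plogis(eta))
  sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Scan a fitted model for threshold artifacts
#'
#' For every continuous component with at least three bins, every interior
#' bin is tested for a discontinuity (the `T_d` log-likelihood contrast) and
#' the slope-sign sequence is scanned for concave changepoints. With a
#' bagged model, both tests run once per bootstrap bag, using the bag's own
#' component values; discontinuity statistics are evaluated on the bag's
#' out-of-bag rows, so that chance structure fitted by a bag is not
#' re-scored on the rows that produced it. A discontinuity is flagged when
#' the fraction of bags with `T_d > 0` reaches `support_level` and the
#' median `T_d` is positive; a non-monotonicity is flagged when a concave
#' changepoint lands within one bin of the same location in at least
#' `support_level` of the bags. Convex changepoints (healthy-range valleys)
#' are reported but never flagged. Tests whose three-bin window holds fewer
#' than `min_window_count` training rows are marked low-confidence.
#'
#' Without bag models the scan falls back to point estimates with all flags
#' forced off (no support evidence), with a warning.
#'
#' @param model an `additive_risk_model`, ideally from [fit_bagged_gam()].
#' @param table the [patient_table()] to evaluate likelihoods on (normally
#'   the training table).
#' @param support_level bag-support fraction required to flag.
#' @param slope_zero_tol see [compute_slopes()].
#' @param min_run see [detect_sign_changepoints()].
#' @param min_window_count training-row threshold for the low-confidence mark.
#' @return an `artifact_report`: ranked data frames `discontinuities` and
#'   `nonmonotonicities` plus provenance.
#' @export
scan_artifacts <- function(model, table, support_level = 0.95,
                           slope_zero_tol = 1e-8, min_run = 2L,
                           min_window_count = 20L) {
  stopifnot(inherits(model, "additive_risk_model"),
            inherits(table, "patient_table"))
  y <- table$outcome
  n <- table$n
  bagged <- !is.null(model$bag_models)
  if (!bagged)
    warning("model has no bag models: reporting point estimates with all flags off")

  testable <- Filter(function(cmp)
    cmp$kind != "nominal" && length(cmp$values) >= 3L, model$components)
  feat_names <- names(model$components)

  # shared bin indices of the supplied table under the model's thresholds
  bin_idx <- lapply(model$components, function(cmp) {
    x <- table$features[[cmp$feature]]
    if (cmp$kind == "nominal") {
      match(as.character(x), cmp$levels)
    } else {
      x <- as.numeric(x)
      ifelse(is.na(x), NA_integer_, findInterval(x, cmp$thresholds) + 1L)
    }
  })
  names(bin_idx) <- feat_names

  disc_rows <- list(); nonmono_rows <- list()

  if (bagged) {
    bags <- model$bag_models
    nb <- length(bags)
    oob_masks <- lapply(bags, function(bg) tabulate(bg$rows, n) == 0L)
    etas <- lapply(bags, bag_eta, bin_idx = bin_idx, n = n)
  }

  for (cmp in testable) {
    f <- cmp$feature
    m <- length(cmp$values)
    idx <- bin_idx[[f]]
    interior <- 2L:(m - 1L)
    win_counts <- vapply(interior, function(k)
      sum(cmp$bin_counts[(k - 1L):(k + 1L)]), numeric(1))

    if (bagged) {
      td <- matrix(NA_real_, nrow = length(interior), ncol = nb)
      conc_peaks <- vector("list", nb)
      conv_valleys <- vector("list", nb)
      for (b in seq_len(nb)) {
        bg <- bags[[b]]
        v <- bg$vals[[f]]
        eta <- etas[[b]]
        oob <- oob_masks[[b]]
        for (ki in seq_along(interior)) {
          k <- interior[ki]
          rows <- which(oob & !is.na(idx) & idx == k)
          if (!length(rows)) next
          lin <- linear_interp(cmp$bin_repr[k - 1L], v[k - 1L],
                               cmp$bin_repr[k + 1L], v[k + 1L],
                               cmp$bin_repr[k])
          delta <- lin - v[k]
          td[ki, b] <- ll_window(y[rows], eta[rows]) -
            ll_window(y[rows], eta[rows] + delta)
        }
        sl <- slope_sequence(f, v, cmp$bin_repr, cmp$thresholds, slope_zero_tol)
        cps <- detect_sign_changepoints(sl, min_run)
        conc_peaks[[b]] <- changepoint_bins(cps, v, "concave")
        conv_valleys[[b]] <- changepoint_bins(cps, v, "convex")
      }
      support <- rowMeans(td > 0, na.rm = TRUE)
      support[is.nan(support)] <- 0
      med <- apply(td, 1L, median, na.rm = TRUE)
      disc_rows[[f]] <- data.frame(
        feature = f, bin = interior,
        threshold = vapply(interior, jump_threshold, numeric(1), cmp = cmp),
        t_d = med, bag_support = support,
        low_confidence = win_counts < min_window_count,
        flagged = support >= support_level & !is.na(med) & med > 0,
        stringsAsFactors = FALSE
      )
      nonmono_rows[[f]] <- aggregate_changepoints(
        f, cmp, conc_peaks, conv_valleys, nb, support_level)
    } else {
      tds <- vapply(interior, function(k)
        discontinuity_statistic(model, table, f, k), numeric(1))
      disc_rows[[f]] <- data.frame(
        feature = f, bin = interior,
        threshold = vapply(interior, jump_threshold, numeric(1), cmp = cmp),
        t_d = tds, bag_support = NA_real_,
        low_confidence = win_counts < min_window_count,
        flagged = FALSE, stringsAsFactors = FALSE
      )
      cps <- detect_sign_changepoints(
        compute_slopes(cmp, slope_zero_tol), min_run)
      nonmono_rows[[f]] <- point_changepoint_rows(f, cmp, cps)
    }
  }

  disc <- do.call(rbind, c(disc_rows, list(make.row.names = FALSE))) %||%
    empty_disc_df()
  if (is.null(disc) || !nrow(disc)) disc <- empty_disc_df()
  disc <- disc[order(-disc$bag_support, -abs(disc$t_d),
                     method = "radix", na.last = TRUE), , drop = FALSE]
  rownames(disc) <- NULL

  nonmono <- do.call(rbind, c(nonmono_rows, list(make.row.names = FALSE))) %||%
    empty_nonmono_df()
  if (is.null(nonmono) || !nrow(nonmono)) nonmono <- empty_nonmono_df()
  nonmono <- nonmono[order(-nonmono$bag_support, method = "radix",
                           na.last = TRUE), , drop = FALSE]
  rownames(nonmono) <- NULL

  structure(
    list(discontinuities = disc, nonmonotonicities = nonmono,
         provenance = list(
           n = n, bagged = bagged,
           n_bags = if (bagged) length(model$bag_models) else 0L,
           support_level = support_level, slope_zero_tol = slope_zero_tol,
           min_run = min_run, min_window_count = min_window_count,
           fit_config = unclass(model$fit_config))),
    class = "artifact_report"
  )
}

empty_disc_df <- function() {
  data.frame(feature = character(0), bin = integer(0), threshold = numeric(0),
             t_d = numeric(0), bag_support = numeric(0),
             low_confidence = logical(0), flagged = logical(0),
             stringsAsFactors = FALSE)
}

empty_nonmono_df <- function() {
  data.frame(feature = character(0), bin = integer(0), location = numeric(0),
             curvature = character(0), bag_support = numeric(0),
             flagged = logical(0), stringsAsFactors = FALSE)
}

# Threshold value reported for a tested bin: the adjacent bin edge with the
# larger jump in the (bag-mean) component.
jump_threshold <- function(k, cmp) {
  v <- cmp$values; t <- cmp$thresholds
  jl <- abs(v[k] - v[k - 1L])
  jr <- abs(v[k + 1L] - v[k])
  if (jl >= jr) t[k - 1L] else t[k]
}

# Peak (concave) / valley (convex) bin indices implied by a changepoint set.
# Within the span between the two slope regimes the extremum may sit on an
# exact plateau (stump boosting quantizes gentle hilltops); the middle of the
# tied region is then the natural location estimate.
changepoint_bins <- function(cps, values, which_curv) {
  cps <- cps[cps$curvature == which_curv, , drop = FALSE]
  if (!nrow(cps)) return(integer(0))
  vapply(seq_len(nrow(cps)), function(i) {
    span <- (cps$left_index[i] + 1L):(cps$right_index[i])
    v <- values[span]
    ext <- if (which_curv == "concave") max(v) else min(v)
    tied <- span[abs(v - ext) <= 1e-9]
    tied[ceiling(length(tied) / 2)]
  }, integer(1))
}

# Bag-support aggregation for changepoint locations: support at bin k is the
# fraction of bags with a matching changepoint within one bin of k; local
# maxima of the support profile with support >= 0.5 are reported.
aggregate_changepoints <- function(feature, cmp, conc_peaks, conv_valleys,
                                   nb, support_level) {
  m <- length(cmp$values)
  rows <- list()
  for (curv in c("concave", "convex")) {
    peaks <- if (curv == "concave") conc_peaks else conv_valleys
    support <- vapply(seq_len(m), function(k)
      mean(vapply(peaks, function(p) any(abs(p - k) <= 1L), logical(1))),
      numeric(1))
    cand <- which(support >= 0.5)
    if (!length(cand)) next
    groups <- split(cand, cumsum(c(1L, diff(cand) > 1L)))
    for (g in groups) {
      mx <- max(support[g])
      tied <- g[support[g] >= mx - 1e-12]
      k <- tied[ceiling(length(tied) / 2)]
      rows[[length(rows) + 1L]] <- data.frame(
        feature = feature, bin = k, location = cmp$bin_repr[k],
        curvature = curv, bag_support = support[k],
        flagged = curv == "concave" && support[k] >= support_level,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows)) do.call(rbind, rows) else empty_nonmono_df()
}

point_changepoint_rows <- function(feature, cmp, cps) {
  if (!nrow(cps)) return(empty_nonmono_df())
  bins <- c(changepoint_bins(cps, cmp$values, "concave"),
            changepoint_bins(cps, cmp$values, "convex"))
  curvs <- c(rep("concave", sum(cps$curvature == "concave")),
             rep("convex", sum(cps$curvature == "convex")))
  data.frame(feature = feature, bin = bins, location = cmp$bin_repr[bins],
             curvature = curvs, bag_support = NA_real_, flagged = FALSE,
             stringsAsFactors = FALSE)
}

#' @export
print.artifact_report <- function(x, ...) {
  cat("<artifact_report>\n")
  cat(" discontinuities (top 5 of ", nrow(x$discontinuities), "):\n", sep = "")
  print(head(x$discontinuities, 5L), row.names = FALSE)
  cat(" non-monotonicities (top 5 of ", nrow(x$nonmonotonicities), "):\n",
      sep = "")
  print(head(x$nonmonotonicities, 5L), row.names = FALSE)
  invisible(x)
}

#' Write / read an artifact report as JSON
#'
#' @param report an `artifact_report`.
#' @param path output path.
#' @return the path ([write_artifact_report()]) or the reconstructed report.
#' @export
write_artifact_report <- function(report, path) {
  stopifnot(inherits(report, "artifact_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", na = "null")
  invisible(path)
}

#' @rdname write_artifact_report
#' @export
read_artifact_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$discontinuities <- as.data.frame(obj$discontinuities,
                                       stringsAsFactors = FALSE)
  obj$nonmonotonicities <- as.data.frame(obj$nonmonotonicities,
                                         stringsAsFactors = FALSE)
  if (!nrow(obj$discontinuities)) obj$discontinuities <- empty_disc_df()
  if (!nrow(obj$nonmonotonicities)) obj$nonmonotonicities <- empty_nonmono_df()
  structure(obj, class = "artifact_report")
}
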