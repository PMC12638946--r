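#' Piecewise-constant component function of an additive risk model
#'
#' One feature's additive contribution to the log-odds of the outcome. For a
#' continuous feature with `m` bins, `thresholds` holds the `m - 1` strictly
#' increasing interior cut points; bin `i` covers the half-open interval
#' `[thresholds[i-1], thresholds[i])` (outer bins unbounded, last bin closed
#' above). `values` holds the per-bin log-odds contributions. `bin_repr`
#' holds a representative biomarker value per bin (the training-data mean of
#' the feature within the bin when fitted from data, midpoints for
#' hand-built components); representative points are the x-coordinates at
#' which linearization and slope calculations anchor each bin.
#'
#' After fitting, components are identifiable: the `bin_counts`-weighted mean
#' of `values` (including the missing bin, when present) is zero.
#'
#' @param feature feature name.
#' @param thresholds strictly increasing numeric vector (length `m - 1`),
#'   or `numeric(0)` for a single-bin component. `NULL` for nominal features.
#' @param values per-bin log-odds contributions (length `m`).
#' @param bin_counts training samples per bin (optional).
#' @param bin_repr representative feature value per bin (optional; defaults
#'   to bin midpoints, outer bins offset by half the median bin width).
#' @param ci_lower,ci_upper optional per-bin confidence band (log-odds).
#' @param missing_bin_value optional log-odds contribution for missing inputs.
#' @param kind `"continuous"`, `"boolean"` or `"nominal"`.
#' @param levels category labels (nominal features only; one value per level).
#' @return an object of class `component_function`.
#' @export
component_function <- function(feature, thresholds, values, bin_counts = NULL,
                               bin_repr = NULL, ci_lower = NULL,
                               ci_upper = NULL, missing_bin_value = NULL,
                               kind = "continuous", levels = NULL) {
  stopifnot(is.character(feature), length(feature) == 1L)
  values <- as.numeric(values)
  if (!all(is.finite(values)))
    stop_ra("component values must be finite", class = "riskaudit_validation_error")
  if (kind == "nominal") {
    if (is.null(levels) || length(levels) != length(values))
      stop_ra("nominal component needs one value per level",
              class = "riskaudit_validation_error")
    thresholds <- NULL
  } else {
    thresholds <- as.numeric(thresholds)
    if (length(thresholds) && any(diff(thresholds) <= 0))
      stop_ra("thresholds must be strictly increasing",
              class = "riskaudit_validation_error")
    if (length(values) != length(thresholds) + 1L)
      stop_ra("need length(values) == length(thresholds) + 1",
              class = "riskaudit_validation_error")
    if (is.null(bin_repr)) bin_repr <- default_bin_repr(thresholds)
  }
  if (!is.null(ci_lower) && !is.null(ci_upper)) {
    stopifnot(length(ci_lower) == length(values),
              length(ci_upper) == length(values))
    if (any(ci_lower > ci_upper + 1e-12))
      stop_ra("ci_lower must not exceed ci_upper", class = "riskaudit_validation_error")
  }
  structure(
    list(feature = feature, kind = kind, thresholds = thresholds,
         values = values, bin_counts = bin_counts, bin_repr = bin_repr,
         ci_lower = ci_lower, ci_upper = ci_upper,
         missing_bin_value = missing_bin_value, levels = levels),
    class = "component_function"
  )
}

# Midpoint representatives; outer (unbounded) bins sit half a typical bin
# width beyond the outermost threshold.
default_bin_repr <- function(thresholds) {
  m <- length(thresholds) + 1L
  if (m == 1L) return(0)
  h <- if (m >= 3L) median(diff(thresholds)) else 1
  if (!is.finite(h) || h <= 0) h <- 1
  inner <- if (m >= 3L)
    (thresholds[-length(thresholds)] + thresholds[-1L]) / 2
  else numeric(0)
  c(thresholds[1L] - h / 2, inner, thresholds[length(thresholds)] + h / 2)
}

#' Evaluate a component function at feature values
#'
#' Bins are half-open `[lo, hi)`: a value exactly equal to a threshold falls
#' in the bin to the threshold's right; the last bin is closed above and the
#' outer bins are unbounded. Missing values get `missing_bin_value` when the
#' component has one, otherwise `NA` (callers decide the fallback).
#'
#' @param component a [component_function()].
#' @param x vector of feature values (character for nominal features).
#' @return numeric vector of log-odds contributions.
#' @export
evaluate_component <- function(component, x) {
  stopifnot(inherits(component, "component_function"))
  if (component$kind == "nominal") {
    idx <- match(as.character(x), component$levels)
    out <- component$values[idx]
  } else {
    x <- as.numeric(x)
    out <- rep(NA_real_, length(x))
    ok <- !is.na(x)
    idx <- findInterval(x[ok], component$thresholds) + 1L
    out[ok] <- component$values[idx]
  }
  if (!is.null(component$missing_bin_value))
    out[is.na(x)] <- component$missing_bin_value
  out
}

#' @export
print.component_function <- function(x, ...) {
  m <- length(x$values)
  cat("<component_function> ", x$feature, " (", x$kind, "), ", m, " bin",
      if (m != 1L) "s", "\n", sep = "")
  if (x$kind != "nominal" && m > 1L)
    cat("  thresholds: ", paste(signif(head(x$thresholds, 6L), 4),
                                collapse = ", "),
        if (m - 1L > 6L) ", ...", "\n", sep = "")
  invisible(x)
}

# Bin left/right edges including unbounded outer sentinels.
component_edges <- function(component) {
  t <- component$thresholds
  list(left = c(-Inf, t), right = c(t, Inf))
}

#' Export fitted component curves as a CSV table
#'
#' One row per (feature, bin): left and right bin edges, log-odds value,
#' confidence band, training count and representative point. Unbounded outer
#' edges are written as the sentinels `-inf` / `+inf` (documented in a `#`
#' header comment). The table is re-importable with
#' [import_component_curves()] and is the interchange format for auditing
#' externally fitted curves.
#'
#' @param model a fitted [fit_gam()] / [fit_bagged_gam()] model.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
export_component_curves <- function(model, path) {
  stopifnot(inherits(model, "additive_risk_model"))
  rows <- lapply(model$components, function(cmp) {
    m <- length(cmp$values)
    if (cmp$kind == "nominal") {
      data.frame(feature = cmp$feature, kind = cmp$kind, bin = seq_len(m),
                 left = NA_character_, right = NA_character_,
                 level = cmp$levels, repr = NA_real_,
                 value = cmp$values,
                 ci_lower = cmp$ci_lower %||% rep(NA_real_, m),
                 ci_upper = cmp$ci_upper %||% rep(NA_real_, m),
                 count = cmp$bin_counts %||% rep(NA_real_, m),
                 stringsAsFactors = FALSE)
    } else {
      e <- component_edges(cmp)
      data.frame(feature = cmp$feature, kind = cmp$kind, bin = seq_len(m),
                 left = fmt_edge(e$left), right = fmt_edge(e$right),
                 level = NA_character_, repr = cmp$bin_repr,
                 value = cmp$values,
                 ci_lower = cmp$ci_lower %||% rep(NA_real_, m),
                 ci_upper = cmp$ci_upper %||% rep(NA_real_, m),
                 count = cmp$bin_counts %||% rep(NA_real_, m),
                 stringsAsFactors = FALSE)
    }
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# riskaudit component curve table v1",
    "# unbounded outer bin edges are encoded as the sentinels -inf / +inf",
    "# values, ci_lower, ci_upper are log-odds contributions; bins are [left, right)"
  ), con)
  write.csv(df, con, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

fmt_edge <- function(x) {
  out <- format(x, digits = 17, trim = TRUE, scientific = FALSE)
  out[x == -Inf] <- "-inf"
  out[x == Inf] <- "+inf"
  out
}

parse_edge <- function(s) {
  out <- suppressWarnings(as.numeric(s))
  out[s == "-inf"] <- -Inf
  out[s == "+inf"] <- Inf
  out
}

#' Re-import component curves exported by [export_component_curves()]
#'
#' @param path CSV path written by [export_component_curves()].
#' @return a named list of [component_function()] objects.
#' @export
import_component_curves <- function(path) {
  if (!file.exists(path))
    stop_ra("file not found: ", path, class = "riskaudit_input_error")
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                 na.strings = c("", "NA"),
                 colClasses = c(left = "character", right = "character"))
  comps <- lapply(split(df, df$feature), function(d) {
    d <- d[order(d$bin), , drop = FALSE]
    kind <- d$kind[1L]
    has_ci <- !all(is.na(d$ci_lower))
    if (kind == "nominal") {
      component_function(d$feature[1L], NULL, d$value, kind = "nominal",
                         levels = d$level,
                         bin_counts = if (!all(is.na(d$count))) d$count,
                         ci_lower = if (has_ci) d$ci_lower,
                         ci_upper = if (has_ci) d$ci_upper)
    } else {
      left <- parse_edge(d$left)
      component_function(d$feature[1L], left[-1L], d$value, kind = kind,
                         bin_repr = d$repr,
                         bin_counts = if (!all(is.na(d$count))) d$count,
                         ci_lower = if (has_ci) d$ci_lower,
                         ci_upper = if (has_ci) d$ci_upper)
    }
  })
  comps[unique(df$feature)]
}
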