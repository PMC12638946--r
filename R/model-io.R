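MODEL_FORMAT_VERSION <- "1"

#' Serialize / deserialize an additive risk model
#'
#' Models are written as version-tagged JSON. Numeric fields are written at
#' full double precision, so a serialize/deserialize round trip reproduces
#' thresholds, per-bin values, the intercept and metadata bit-identically.
#' Bag models (when present) are included so that a reloaded model can still
#' be audited with bootstrap support.
#'
#' @param model an `additive_risk_model`.
#' @param path output path (`.json`).
#' @return `serialize_model()` returns the path invisibly;
#'   `deserialize_model()` returns the reconstructed `additive_risk_model`.
#' @export
serialize_model <- function(model, path) {
  stopifnot(inherits(model, "additive_risk_model"))
  if (!is.finite(model$intercept))
    stop_ra("model intercept is not finite", class = "riskaudit_validation_error")
  obj <- list(
    format = "riskaudit_model",
    version = MODEL_FORMAT_VERSION,
    intercept = model$intercept,
    schema = list(outcome = model$schema$outcome,
                  features = list(name = model$schema$features$name,
                                  kind = model$schema$features$kind,
                                  units = model$schema$features$units)),
    fit_config = unclass(model$fit_config),
    meta = model$meta,
    components = lapply(model$components, function(cmp) {
      list(feature = cmp$feature, kind = cmp$kind,
           thresholds = cmp$thresholds, values = cmp$values,
           bin_counts = cmp$bin_counts, bin_repr = cmp$bin_repr,
           ci_lower = cmp$ci_lower, ci_upper = cmp$ci_upper,
           missing_bin_value = cmp$missing_bin_value, levels = cmp$levels)
    }),
    bag_models = if (!is.null(model$bag_models)) {
      lapply(model$bag_models, function(bg) {
        list(intercept = bg$intercept, vals = bg$vals,
             miss_vals = bg$miss_vals, rows = bg$rows,
             rounds_run = bg$rounds_run)
      })
    }
  )
  # digits = I(17): every double is written with 17 significant digits,
  # which strtod maps back to the identical bit pattern (digits = NA only
  # gives ~15 digits and loses the last ulp)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname serialize_model
#' @export
deserialize_model <- function(path) {
  if (!file.exists(path))
    stop_ra("file not found: ", path, class = "riskaudit_input_error")
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE),
    error = function(e) stop_ra("cannot parse model file: ", conditionMessage(e),
                                class = "riskaudit_parse_error")
  )
  if (!identical(obj$format, "riskaudit_model"))
    stop_ra("not a riskaudit model file", class = "riskaudit_parse_error")
  if (!identical(as.character(obj$version), MODEL_FORMAT_VERSION))
    stop_ra("unsupported model format version '", obj$version, "' (expected ",
            MODEL_FORMAT_VERSION, ")", class = "riskaudit_version_error")
  num_field <- function(x, field, where) {
    if (is.null(x)) return(NULL)
    x <- unlist(x)
    out <- suppressWarnings(as.numeric(x))
    if (anyNA(out) && !anyNA(x))
      stop_ra("corrupted numeric field '", field, "' in ", where,
              class = "riskaudit_parse_error")
    out
  }
  sf <- obj$schema$features
  schema <- if (length(sf$name)) {
    units <- sf$units %||% rep(NA_character_, length(sf$name))
    dataset_schema(obj$schema$outcome, stats::setNames(sf$kind, sf$name),
                   units = stats::setNames(as.character(units), sf$name))
  } else {
    empty_schema(obj$schema$outcome)
  }
  components <- lapply(obj$components, function(c0) {
    component_function(
      c0$feature,
      thresholds = num_field(c0$thresholds, "thresholds", c0$feature),
      values = num_field(c0$values, "values", c0$feature),
      bin_counts = num_field(c0$bin_counts, "bin_counts", c0$feature),
      bin_repr = num_field(c0$bin_repr, "bin_repr", c0$feature),
      ci_lower = num_field(c0$ci_lower, "ci_lower", c0$feature),
      ci_upper = num_field(c0$ci_upper, "ci_upper", c0$feature),
      missing_bin_value = c0$missing_bin_value,
      kind = c0$kind, levels = unlist(c0$levels)
    )
  })
  names(components) <- vapply(components, `[[`, character(1), "feature")
  fc <- obj$fit_config
  config <- fit_config(fc$n_rounds, fc$learning_rate, fc$max_bins, fc$n_bags,
                       fc$bag_fraction, fc$seed, fc$early_stop_patience,
                       fc$validation_fraction, fc$ci_level,
                       fc$min_gain_mult %||% 0.1)
  intercept <- num_field(obj$intercept, "intercept", "model")
  bag_models <- if (!is.null(obj$bag_models)) {
    lapply(obj$bag_models, function(bg) {
      list(intercept = num_field(bg$intercept, "intercept", "bag model"),
           vals = lapply(bg$vals, function(v) num_field(v, "vals", "bag model")),
           miss_vals = lapply(bg$miss_vals, function(v)
             if (is.null(v)) NULL else num_field(v, "miss_vals", "bag model")),
           rows = as.integer(unlist(bg$rows)),
           rounds_run = bg$rounds_run)
    })
  }
  new_additive_risk_model(intercept, components, config, schema,
                          meta = obj$meta, bag_models = bag_models)
}
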