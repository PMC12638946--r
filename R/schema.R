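#' Describe the columns of a patient table
#'
#' A schema names the binary outcome column and lists the model features with
#' their kinds. Feature kinds determine how columns are validated, binned and
#' audited: `"continuous"` features get quantile bins and are eligible for
#' artifact detection; `"boolean"` features are coerced to 0/1; `"nominal"`
#' features are unordered categories (fitted, but never tested for
#' discontinuities or non-monotonicities, which require an ordered axis).
#'
#' @param outcome name of the binary outcome column.
#' @param features named character vector or named list mapping feature name
#'   to kind, one of `"continuous"`, `"boolean"`, `"nominal"`.
#' @param units optional named character vector of free-text units, keyed by
#'   feature name.
#' @return an object of class `dataset_schema`.
#' @examples
#' dataset_schema("died", c(creatinine = "continuous", male = "boolean"),
#'                units = c(creatinine = "mg/dL"))
#' @export
dataset_schema <- function(outcome, features, units = NULL) {
  stopifnot(is.character(outcome), length(outcome) == 1L, nzchar(outcome))
  features <- unlist(features)
  if (is.null(names(features)) || any(!nzchar(names(features))))
    stop_ra("every feature must be named", class = "riskaudit_schema_error")
  kinds <- as.character(features)
  bad <- setdiff(kinds, c("continuous", "boolean", "nominal"))
  if (length(bad))
    stop_ra("unknown feature kind(s): ", paste(unique(bad), collapse = ", "),
            class = "riskaudit_schema_error")
  nm <- names(features)
  if (anyDuplicated(nm))
    stop_ra("feature names must be unique", class = "riskaudit_schema_error")
  if (outcome %in% nm)
    stop_ra("outcome column '", outcome, "' cannot also be a feature",
            class = "riskaudit_schema_error")
  if (length(nm) < 1L)
    stop_ra("schema needs at least one feature", class = "riskaudit_schema_error")
  u <- rep(NA_character_, length(nm))
  names(u) <- nm
  if (!is.null(units)) u[names(units)] <- units
  structure(
    list(outcome = outcome,
         features = data.frame(name = nm, kind = kinds, units = unname(u[nm]),
                               stringsAsFactors = FALSE)),
    class = "dataset_schema"
  )
}

# Degenerate schema for intercept-only models (no patient features).
empty_schema <- function(outcome) {
  structure(
    list(outcome = outcome,
         features = data.frame(name = character(0), kind = character(0),
                               units = character(0), stringsAsFactors = FALSE)),
    class = "dataset_schema"
  )
}

#' @export
print.dataset_schema <- function(x, ...) {
  cat("<dataset_schema> outcome:", x$outcome, "\n")
  print(x$features, row.names = FALSE)
  invisible(x)
}

#' Build a validated patient table from a data frame
#'
#' Checks a data frame against a [dataset_schema()]: the outcome must be
#' strictly 0/1 with no missing values, every schema feature must be present,
#' boolean columns are coerced to 0/1, and missing continuous values are kept
#' as `NA` (they are routed to a dedicated missing bin during fitting).
#' Columns not covered by the schema are dropped with a warning.
#'
#' @param data a data frame, one row per patient.
#' @param schema a [dataset_schema()].
#' @return an object of class `patient_table` with elements `outcome`
#'   (integer 0/1 vector), `features` (data frame of feature columns),
#'   `schema`, and `n`.
#' @export
patient_table <- function(data, schema) {
  stopifnot(inherits(schema, "dataset_schema"), is.data.frame(data))
  if (nrow(data) < 1L)
    stop_ra("patient table needs at least one row", class = "riskaudit_input_error")
  if (!schema$outcome %in% names(data))
    stop_ra("outcome column '", schema$outcome, "' not found",
            class = "riskaudit_schema_error")
  y_raw <- data[[schema$outcome]]
  y <- suppressWarnings(as.numeric(as.character(y_raw)))
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop_ra("outcome column '", schema$outcome, "' must contain only 0/1 values",
            class = "riskaudit_validation_error")
  feats <- schema$features
  missing_cols <- setdiff(feats$name, names(data))
  if (length(missing_cols))
    stop_ra("feature column(s) missing from data: ",
            paste(missing_cols, collapse = ", "),
            class = "riskaudit_schema_error")
  extra <- setdiff(names(data), c(schema$outcome, feats$name))
  if (length(extra))
    warning("ignoring column(s) not in schema: ", paste(extra, collapse = ", "))
  cols <- lapply(seq_len(nrow(feats)), function(i) {
    nm <- feats$name[i]; kind <- feats$kind[i]
    v <- data[[nm]]
    if (kind == "continuous") {
      v <- suppressWarnings(as.numeric(v))
      if (any(is.infinite(v)))
        stop_ra("continuous feature '", nm, "' contains infinite values",
                class = "riskaudit_validation_error")
      v
    } else if (kind == "boolean") {
      if (is.logical(v)) v <- as.numeric(v)
      v <- suppressWarnings(as.numeric(as.character(v)))
      if (anyNA(v) || !all(v %in% c(0, 1)))
        stop_ra("boolean feature '", nm, "' must contain only 0/1 (or TRUE/FALSE)",
                class = "riskaudit_validation_error")
      v
    } else {
      as.character(v)
    }
  })
  names(cols) <- feats$name
  structure(
    list(n = nrow(data),
         outcome = as.integer(y),
         features = as.data.frame(cols, stringsAsFactors = FALSE,
                                  check.names = FALSE),
         schema = schema),
    class = "patient_table"
  )
}

#' Read a patient table from a CSV file
#'
#' Comma-separated, UTF-8, header row required. Empty fields in continuous
#' columns become `NA`. Validation follows [patient_table()].
#'
#' @param path path to a CSV file.
#' @param schema a [dataset_schema()].
#' @return a `patient_table`.
#' @export
read_patient_table <- function(path, schema) {
  if (!file.exists(path))
    stop_ra("file not found: ", path, class = "riskaudit_input_error")
  if (file.size(path) == 0L)
    stop_ra("empty file: ", path, class = "riskaudit_input_error")
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (nrow(df) == 0L)
    stop_ra("no data rows in ", path, class = "riskaudit_input_error")
  patient_table(df, schema)
}

#' Write a patient table to CSV
#'
#' Inverse of [read_patient_table()]: missing continuous values are written
#' as empty fields.
#'
#' @param table a `patient_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_patient_table <- function(table, path) {
  stopifnot(inherits(table, "patient_table"))
  df <- table$features
  df[[table$schema$outcome]] <- table$outcome
  write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @export
print.patient_table <- function(x, ...) {
  cat("<patient_table> n =", x$n, ", outcome '", x$schema$outcome,
      "' (", sum(x$outcome), " events), ", nrow(x$schema$features),
      " features\n", sep = "")
  invisible(x)
}
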