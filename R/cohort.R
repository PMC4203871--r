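#' Build a cohort from a patient table
#'
#' A cohort bundles a patient-by-variable table with a binary outcome
#' (prolonged ICU stay) and a schema describing each candidate predictor.
#' The outcome can be supplied either as ICU length of stay in hours, from
#' which the adverse class (LOS >= `los_cutoff` hours) is derived, or as a
#' precomputed binary label. The adverse class is the positive class in all
#' downstream screening, scoring and evaluation.
#'
#' @param data data.frame of raw variables, one row per patient.
#' @param outcome name of the outcome column in `data`, or a vector of the
#'   same length as `nrow(data)`.
#' @param outcome_type `"los_hours"` (derive adverse as LOS >= cutoff) or
#'   `"binary"` (labels are 0/1, logical, or `"normal"`/`"adverse"`).
#' @param los_cutoff adverse-outcome cut-off in hours (default 120 h = 5
#'   days).
#' @param schema optional data.frame with columns `name`, `kind` (one of
#'   `"dichotomous"`, `"continuous"`, `"discrete"`) and optionally `role`
#'   (`"preoperative"`, `"intraoperative"`, `"postoperative"`,
#'   `"unspecified"`). When omitted, kinds are inferred: columns that are
#'   logical, factor, or take at most two distinct values are dichotomous;
#'   all other numeric columns are continuous.
#' @return an object of class `icu_cohort`: a list with elements `data`
#'   (typed predictors), `outcome` (factor `normal`/`adverse`), `los`
#'   (hours, or `NULL`), and `schema`.
#' @seealso [read_cohort()], [filter_complete()], [nb_scorecard()]
#' @export
cohort <- function(data, outcome,
                   outcome_type = c("binary", "los_hours"),
                   los_cutoff = 120, schema = NULL) {
  outcome_type <- match.arg(outcome_type)
  if (!is.data.frame(data)) stop_schema("cohort: data must be a data.frame")
  if (is.character(outcome) && length(outcome) == 1L) {
    if (!outcome %in% names(data)) {
      stop_schema("cohort: outcome column '", outcome, "' not found")
    }
    oc <- data[[outcome]]
    data <- data[setdiff(names(data), outcome)]
  } else {
    oc <- outcome
    if (length(oc) != nrow(data)) {
      stop_schema("cohort: outcome length does not match row count")
    }
  }

  los <- NULL
  if (outcome_type == "los_hours") {
    los <- as.numeric(oc)
    lab <- derive_outcome(los, los_cutoff)
  } else {
    lab <- outcome_factor(as_adverse(oc))
  }

  if (is.null(schema)) schema <- infer_schema(data)
  schema <- validate_schema(schema, data)
  data <- type_features(data, schema)

  structure(list(data = data, outcome = lab, los = los, schema = schema),
            class = "icu_cohort")
}

infer_schema <- function(data) {
  kind <- vapply(data, function(v) {
    u <- unique(v[!is.na(v)])
    if (is.logical(v) || is.factor(v) || is.character(v) || length(u) <= 2L) {
      "dichotomous"
    } else {
      "continuous"
    }
  }, character(1))
  data.frame(name = names(data), kind = unname(kind), role = "unspecified",
             stringsAsFactors = FALSE)
}

validate_schema <- function(schema, data) {
  if (!all(c("name", "kind") %in% names(schema))) {
    stop_schema("schema must have columns 'name' and 'kind'")
  }
  if (is.null(schema$role)) schema$role <- "unspecified"
  bad <- setdiff(schema$kind, c("dichotomous", "continuous", "discrete"))
  if (length(bad)) stop_schema("unknown feature kind: ", paste(bad, collapse = ", "))
  missing <- setdiff(schema$name, names(data))
  if (length(missing)) {
    stop_schema("declared column(s) absent from data: ",
                paste(missing, collapse = ", "))
  }
  schema[c("name", "kind", "role")]
}

# Coerce raw columns to the declared kind; keeps only declared features,
# in schema order.
type_features <- function(data, schema) {
  out <- lapply(seq_len(nrow(schema)), function(i) {
    nm <- schema$name[i]
    v <- data[[nm]]
    if (schema$kind[i] == "dichotomous") {
      if (is.logical(v)) v <- ifelse(v, "yes", "no")
      if (is.numeric(v)) {
        u <- unique(v[!is.na(v)])
        if (!all(u %in% c(0, 1))) {
          stop_schema("dichotomous column '", nm,
                      "' has numeric values outside {0, 1}")
        }
        v <- c("no", "yes")[v + 1L]
      }
      f <- factor(as.character(v))
      if (all(levels(f) %in% c("no", "yes"))) f <- factor(f, levels = c("no", "yes"))
      if (nlevels(f) > 2L) {
        stop_schema("dichotomous column '", nm, "' has ", nlevels(f), " levels")
      }
      f
    } else {
      if (is.character(v) || is.factor(v)) {
        vn <- suppressWarnings(as.numeric(as.character(v)))
        bad <- which(!is.na(v) & is.na(vn))
        if (length(bad)) {
          stop_schema("non-numeric value in numeric column '", nm,
                      "' at row ", bad[1])
        }
        v <- vn
      }
      as.numeric(v)
    }
  })
  names(out) <- schema$name
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Derive the adverse/normal outcome from ICU length of stay
#'
#' Adverse outcome is a prolonged ICU stay: LOS greater than or equal to
#' the cut-off (default 120 hours, i.e. 5 days).
#'
#' @param los_hours numeric vector of ICU stays in hours (non-negative).
#' @param cutoff cut-off in hours; must be positive.
#' @return factor with levels `c("normal", "adverse")`.
#' @export
#' @examples
#' derive_outcome(c(68, 119.99, 120)) # normal normal adverse
derive_outcome <- function(los_hours, cutoff = 120) {
  if (!is.numeric(los_hours)) stop_data("derive_outcome: LOS must be numeric")
  if (!is.finite(cutoff) || cutoff <= 0) stop_data("derive_outcome: cutoff must be > 0")
  if (any(los_hours < 0, na.rm = TRUE)) stop_data("derive_outcome: negative LOS")
  outcome_factor(los_hours >= cutoff)
}

#' Read a cohort from CSV plus a JSON schema
#'
#' The CSV must have a header row. The schema is a JSON document of the form
#' `{"outcome": {"column": ..., "type": "los_hours"|"binary",
#' "cutoff_hours": 120}, "features": [{"name": ..., "kind": ...,
#' "role": ...}, ...]}`.
#'
#' @param csv_path path to the patient CSV.
#' @param schema path to the schema JSON, or an already-parsed schema list.
#' @return an [cohort()] object; row order is preserved.
#' @export
read_cohort <- function(csv_path, schema) {
  if (is.character(schema)) schema <- jsonlite::read_json(schema, simplifyVector = TRUE)
  if (is.null(schema$outcome$column) || is.null(schema$features)) {
    stop_schema("schema must declare outcome$column and features")
  }
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE, check.names = FALSE)
  feats <- as.data.frame(schema$features, stringsAsFactors = FALSE)
  cohort(df,
         outcome = schema$outcome$column,
         outcome_type = schema$outcome$type %||% "binary",
         los_cutoff = schema$outcome$cutoff_hours %||% 120,
         schema = feats)
}

#' Write a cohort (and its schema) back to CSV/JSON
#'
#' @param x an `icu_cohort`.
#' @param csv_path output CSV path.
#' @param schema_path optional output path for the matching schema JSON.
#' @return `csv_path`, invisibly.
#' @export
write_cohort <- function(x, csv_path, schema_path = NULL) {
  stopifnot(inherits(x, "icu_cohort"))
  df <- x$data
  for (nm in names(df)) {
    if (is.factor(df[[nm]])) {
      df[[nm]] <- as.character(df[[nm]])
    } else if (is.double(df[[nm]])) {
      # full precision so a write/load round-trip is lossless
      df[[nm]] <- sprintf("%.17g", df[[nm]])
    }
  }
  if (!is.null(x$los)) {
    df$los_hours <- sprintf("%.17g", x$los)
    oc <- list(column = "los_hours", type = "los_hours", cutoff_hours = 120)
  } else {
    df$outcome <- as.character(x$outcome)
    oc <- list(column = "outcome", type = "binary")
  }
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(schema_path)) {
    jsonlite::write_json(list(outcome = oc, features = x$schema),
                         schema_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}

#' Complete-case filter
#'
#' Drops every record missing a value for any declared feature (or the
#' outcome), mirroring the exclusion of records with insufficient data from
#' classifier design; no imputation is performed. The exclusion report is
#' attached as attribute `"exclusions"`.
#'
#' @param x an `icu_cohort`.
#' @return the filtered cohort; `attr(, "exclusions")` is a data.frame with
#'   columns `row` (original index) and `missing` (comma-separated field
#'   names), and `attr(, "excluded_fraction")` the fraction dropped.
#' @export
filter_complete <- function(x) {
  stopifnot(inherits(x, "icu_cohort"))
  miss <- is.na(x$data)
  miss_out <- is.na(x$outcome)
  drop <- rowSums(miss) > 0L | miss_out
  fields <- apply(miss, 1L, function(r) paste(colnames(miss)[r], collapse = ","))
  fields[miss_out] <- ifelse(nzchar(fields[miss_out]),
                             paste0(fields[miss_out], ",outcome"), "outcome")
  report <- data.frame(row = which(drop), missing = fields[drop],
                       stringsAsFactors = FALSE)
  if (all(drop)) stop_data("filter_complete: all records excluded")
  out <- x
  out$data <- x$data[!drop, , drop = FALSE]
  rownames(out$data) <- NULL
  out$outcome <- x$outcome[!drop]
  if (!is.null(x$los)) out$los <- x$los[!drop]
  attr(out, "exclusions") <- report
  attr(out, "excluded_fraction") <- mean(drop)
  out
}

#' @export
print.icu_cohort <- function(x, ...) {
  n <- length(x$outcome)
  nad <- sum(x$outcome == "adverse")
  cat(sprintf("ICU cohort: %d patients, %d features (%d dichotomous, %d non-dichotomous)\n",
              n, nrow(x$schema), sum(x$schema$kind == "dichotomous"),
              sum(x$schema$kind != "dichotomous")))
  cat(sprintf("Adverse outcome (prolonged stay): %d (%.1f%%)\n", nad, 100 * nad / n))
  invisible(x)
}

#' @export
dim.icu_cohort <- function(x) c(length(x$outcome), nrow(x$schema))
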