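# Classed error helpers: the CLI maps these onto distinct exit codes.

stop_schema <- function(...) {
  stop(errorCondition(paste0(...), class = c("icuscore_schema_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("icuscore_data_error", "error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("icuscore_numeric_error", "error")))
}

# Coerce outcome labels to a logical vector (TRUE = adverse, the positive
# class everywhere in the package: sensitivity is the adverse-class rate).
as_adverse <- function(labels) {
  if (is.logical(labels)) {
    y <- labels
  } else if (is.factor(labels) || is.character(labels)) {
    lv <- as.character(labels)
    ok <- lv %in% c("adverse", "normal")
    if (!all(ok)) {
      stop_data("outcome labels must be 'adverse'/'normal' (got: ",
                paste(unique(lv[!ok]), collapse = ", "), ")")
    }
    y <- lv == "adverse"
  } else if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      stop_data("numeric outcome labels must be 0/1 (1 = adverse)")
    }
    y <- labels == 1
  } else {
    stop_data("unsupported outcome label type: ", class(labels)[1])
  }
  if (anyNA(y)) stop_data("outcome labels contain missing values")
  y
}

outcome_factor <- function(adverse) {
  factor(ifelse(adverse, "adverse", "normal"), levels = c("normal", "adverse"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
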