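#' Reference results from the original development cohort
#'
#' Small bundled tables with the results published for the original
#' development cohort of 3256 adult cardiac-surgery patients: the
#' univariate odds-ratio screening intervals of all 52 candidate
#' predictors, the per-step AUC trace of the forward selection, the
#' weights of the 7 selected features, and the testing-set confusion
#' matrix. The underlying patient-level data is not public; these printed
#' summaries serve as worked-example inputs (e.g. replaying the stopping
#' rule on the published AUC sequence, or recomputing sensitivity and
#' specificity from the published confusion matrix) and as the pattern the
#' synthetic generator emulates.
#'
#' @return `reference_screening()`: data.frame with `variable`, `kind`,
#'   `ci_low`, `ci_high` (99% odds-ratio interval after median
#'   dichotomization) and `cutoff` (the published median cut-off,
#'   non-dichotomous variables only).
#' @name reference
NULL

ref_file <- function(name) {
  system.file("extdata", name, package = "icuscore", mustWork = TRUE)
}

#' @rdname reference
#' @export
reference_screening <- function() {
  utils::read.csv(ref_file("reference_screening.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference
#' @return `reference_weights()`: list of two data.frames, `dichotomous`
#'   (weights for the no/yes categories) and `quartile` (weights for the
#'   four quartile intervals).
#' @export
reference_weights <- function() {
  list(dichotomous = utils::read.csv(ref_file("reference_weights_dichotomous.csv"),
                                     stringsAsFactors = FALSE),
       quartile = utils::read.csv(ref_file("reference_weights_quartile.csv"),
                                  stringsAsFactors = FALSE))
}

#' @rdname reference
#' @return `reference_selection()`: data.frame with `step`, `variable`,
#'   `auc` -- the published forward-selection trace.
#' @export
reference_selection <- function() {
  utils::read.csv(ref_file("reference_selection.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference
#' @return `reference_confusion()`: a `confusion` object with the
#'   published testing-set counts.
#' @export
reference_confusion <- function() {
  x <- utils::read.csv(ref_file("reference_confusion.csv"))
  structure(list(tn = x$tn, fp = x$fp, fn = x$fn, tp = x$tp),
            class = "confusion")
}
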