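# Contribution matrix for a candidate set: column j holds each patient's
# weight for feature j, fitted on the whole cohort. In a naive-Bayes model
# a feature's weights do not depend on which other features are in the
# model, so forward selection only re-sums columns of this matrix.
contribution_matrix <- function(x, features, alpha, priors) {
  model <- nb_scorecard(x, features = features, alpha = alpha, priors = priors)
  predict(model, x, type = "contrib")
}

#' One step of forward AUC-driven selection
#'
#' Fits, for every candidate, the scoring model on the current feature set
#' plus that candidate, computes the resubstitution AUC on the cohort, and
#' returns the candidate with the largest AUC. Ties are broken by candidate
#' order (first declared wins), making the procedure deterministic.
#'
#' @param x an `icu_cohort`.
#' @param current character vector of features already in the model (may be
#'   empty).
#' @param candidates non-empty character vector of candidate features,
#'   disjoint from `current`.
#' @param alpha,priors passed to [nb_scorecard()].
#' @return list with `feature` (the best candidate) and `auc` (the
#'   resubstitution AUC of the augmented model).
#' @export
forward_step <- function(x, current, candidates, alpha = 0.5,
                         priors = c(0.5, 0.5)) {
  if (length(candidates) == 0L) stop_data("forward_step: no candidates")
  if (length(intersect(current, candidates))) {
    stop_data("forward_step: candidates overlap the current feature set")
  }
  contrib <- contribution_matrix(x, c(current, candidates), alpha, priors)
  base <- if (length(current)) rowSums(contrib[, current, drop = FALSE]) else
    numeric(length(x$outcome))
  y <- x$outcome
  aucs <- vapply(candidates, function(f) auc(base + contrib[, f], y), numeric(1))
  best <- which.max(aucs)
  list(feature = candidates[best], auc = unname(aucs[best]))
}

#' Stopping rule on a sequence of per-step AUC values
#'
#' The search halts after the first step `k > window` at which the
#' cumulative AUC increment over the last `window` steps,
#' `AUC(k) - AUC(k - window)`, falls below `delta`; all features entered up
#' to and including step `k` are retained. With the defaults (window 3,
#' delta 0.01) this is the "cumulative increment over three consecutive
#' steps below 1%" rule, with 1% read as an absolute AUC increment of 0.01;
#' `relative = TRUE` instead divides the increment by `AUC(k - window)`.
#'
#' @param aucs numeric vector of AUC values after each selection step.
#' @param window number of consecutive steps the increment is accumulated
#'   over.
#' @param delta minimum cumulative gain to continue.
#' @param relative interpret `delta` as a relative gain.
#' @return list with `step` (number of steps retained) and `triggered`
#'   (`TRUE` if the window rule fired, `FALSE` if the sequence ended
#'   first).
#' @export
#' @examples
#' selection_stop(c(0.7442, 0.8342, 0.8507, 0.8551, 0.8589, 0.8612, 0.8631))
selection_stop <- function(aucs, window = 3, delta = 0.01, relative = FALSE) {
  n <- length(aucs)
  if (n == 0L) stop_data("selection_stop: empty AUC sequence")
  for (k in seq_len(n)) {
    if (k <= window) next
    inc <- aucs[k] - aucs[k - window]
    if (relative) inc <- inc / aucs[k - window]
    if (inc < delta) return(list(step = k, triggered = TRUE))
  }
  list(step = n, triggered = FALSE)
}

#' Forward stepwise feature selection maximizing AUC
#'
#' Starting from the empty model, repeatedly enters the candidate giving
#' the best resubstitution AUC ([forward_step()]) and stops when the
#' cumulative AUC increment over `window` consecutive steps drops below
#' `delta` ([selection_stop()]), when no candidate improves the AUC, or
#' when the candidates are exhausted. All features entered before the rule
#' fires are retained, including those of the triggering window.
#'
#' Selection uses resubstitution AUC on the full cohort; assess the
#' selected model afterwards with [cross_validate()], which re-estimates
#' weights on training folds only. A nested, per-fold selection is not
#' performed here; resubstitution AUC during selection is optimistic, and
#' the cross-validated AUC is the honest performance figure.
#'
#' @param x an `icu_cohort`.
#' @param candidates candidate feature names in priority (schema) order;
#'   default: all features retained by nothing, i.e. every declared
#'   feature. Typically the output of [screen_features()].
#' @param window,delta,relative stopping-rule parameters, see
#'   [selection_stop()].
#' @param alpha,priors passed to [nb_scorecard()].
#' @return a `selection_trace`: data.frame with columns `step`, `feature`,
#'   `auc`, plus attributes `stop_reason` (`"window_rule"`,
#'   `"no_improvement"` or `"candidates_exhausted"`), `window` and `delta`.
#' @export
forward_select <- function(x, candidates = NULL, window = 3, delta = 0.01,
                           relative = FALSE, alpha = 0.5,
                           priors = c(0.5, 0.5)) {
  stopifnot(inherits(x, "icu_cohort"))
  candidates <- candidates %||% x$schema$name
  if (length(candidates) == 0L) stop_data("forward_select: no candidates")
  contrib <- contribution_matrix(x, candidates, alpha, priors)
  y <- x$outcome
  base <- numeric(length(y))
  remaining <- candidates
  steps <- list()
  last_auc <- -Inf
  stop_reason <- "candidates_exhausted"
  while (length(remaining)) {
    aucs <- vapply(remaining, function(f) auc(base + contrib[, f], y), numeric(1))
    best <- which.max(aucs)
    if (length(steps) > 0L && aucs[best] < last_auc - 1e-12) {
      stop_reason <- "no_improvement"
      break
    }
    steps[[length(steps) + 1L]] <- data.frame(
      step = length(steps) + 1L, feature = remaining[best],
      auc = unname(aucs[best]), stringsAsFactors = FALSE)
    base <- base + contrib[, remaining[best]]
    last_auc <- aucs[best]
    remaining <- remaining[-best]
    seq_auc <- vapply(steps, `[[`, numeric(1), "auc")
    halt <- selection_stop(seq_auc, window, delta, relative)
    if (halt$triggered) {
      stop_reason <- "window_rule"
      break
    }
  }
  trace <- do.call(rbind, steps)
  class(trace) <- c("selection_trace", "data.frame")
  attr(trace, "stop_reason") <- stop_reason
  attr(trace, "window") <- window
  attr(trace, "delta") <- delta
  trace
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Forward stepwise selection (AUC criterion)\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  cat(sprintf("Stopped: %s (window = %d, delta = %g)\n",
              attr(x, "stop_reason"), attr(x, "window"), attr(x, "delta")))
  invisible(x)
}
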