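# Frozen per-feature discretizers. A spec records everything needed to map
# a raw value to a category index identically at fit time and at scoring
# time: factor levels for dichotomous features, quartile edges for the rest.
build_specs <- function(x, features) {
  lapply(features, function(nm) {
    i <- match(nm, x$schema$name)
    if (is.na(i)) stop_schema("feature '", nm, "' not declared in cohort schema")
    kind <- x$schema$kind[i]
    v <- x$data[[nm]]
    if (kind == "dichotomous") {
      list(name = nm, kind = kind, categories = levels(v), edges = NULL)
    } else {
      e <- quartile_edges(v)
      list(name = nm, kind = kind,
           categories = c("Q1", "Q2", "Q3", "Q4"),
           edges = as.numeric(e))
    }
  })
}

# Raw data.frame -> integer category matrix (n x p) under frozen specs.
discretize_records <- function(data, specs) {
  cols <- lapply(specs, function(sp) {
    if (!sp$name %in% names(data)) {
      stop_schema("record(s) missing model feature '", sp$name, "'")
    }
    v <- data[[sp$name]]
    if (anyNA(v)) stop_data("missing value for feature '", sp$name, "'")
    if (sp$kind == "dichotomous") {
      if (!is.factor(v)) v <- factor(as.character(v), levels = sp$categories)
      idx <- match(as.character(v), sp$categories)
      if (anyNA(idx)) {
        stop_data("unknown category for feature '", sp$name, "': ",
                  paste(setdiff(unique(as.character(v)), sp$categories),
                        collapse = ", "))
      }
      idx
    } else {
      if (any(!is.finite(v))) stop_data("non-finite value for feature '", sp$name, "'")
      assign_bin(v, sp$edges)
    }
  })
  matrix(unlist(cols), ncol = length(specs),
         dimnames = list(NULL, vapply(specs, `[[`, "", "name")))
}

#' Class-conditional category counts
#'
#' Cross-tabulates every feature's categories against the outcome classes.
#' These counts are the sufficient statistics of the scoring system: the
#' whole model can be rebuilt from them, which is what makes incremental
#' updating exact.
#'
#' @param x an `icu_cohort`.
#' @param features feature names to tabulate (default: all declared).
#' @return list with `specs` (frozen discretizers), `counts` (per feature a
#'   K x 2 matrix with columns `adverse`, `normal`) and `class_totals`
#'   (named vector `c(adverse, normal)`).
#' @export
estimate_counts <- function(x, features = NULL) {
  stopifnot(inherits(x, "icu_cohort"))
  features <- features %||% x$schema$name
  specs <- build_specs(x, features)
  bins <- discretize_records(x$data, specs)
  y <- x$outcome == "adverse"
  counts <- lapply(seq_along(specs), function(j) {
    k <- length(specs[[j]]$categories)
    m <- cbind(adverse = tabulate(bins[y, j], nbins = k),
               normal  = tabulate(bins[!y, j], nbins = k))
    rownames(m) <- specs[[j]]$categories
    m
  })
  names(counts) <- features
  list(specs = specs, counts = counts,
       class_totals = c(adverse = sum(y), normal = sum(!y)))
}

#' Log-likelihood-ratio weights from class-conditional counts
#'
#' The weight of category k of a feature is
#' `w_k = log((n_k1 + alpha) / (n_1 + alpha K)) -
#'        log((n_k2 + alpha) / (n_2 + alpha K))`,
#' the log ratio of the (optionally smoothed) class-conditional category
#' frequencies; K is the number of categories. With `alpha = 0` these are
#' the pure maximum-likelihood weight-of-evidence values, which are
#' infinite whenever a category is unobserved in one class; the default
#' Jeffreys smoothing `alpha = 0.5` of [nb_scorecard()] keeps them finite.
#'
#' @param counts K x 2 matrix of counts, columns ordered (adverse, normal).
#' @param class_totals numeric vector `c(n_adverse, n_normal)`.
#' @param alpha additive smoothing count, >= 0.
#' @return numeric vector of K weights.
#' @export
#' @examples
#' weights_from_counts(cbind(c(30, 70), c(10, 90)), c(100, 100), alpha = 0)
weights_from_counts <- function(counts, class_totals, alpha = 0) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 2L) stop_data("weights_from_counts: counts must have 2 columns")
  if (any(class_totals <= 0)) stop_data("weights_from_counts: class totals must be > 0")
  if (alpha < 0) stop_data("weights_from_counts: alpha must be >= 0")
  if (alpha == 0 && any(counts == 0)) {
    stop_numeric("zero class-conditional count with alpha = 0 gives an ",
                 "infinite weight; set alpha > 0")
  }
  k <- nrow(counts)
  w <- log((counts[, 1] + alpha) / (class_totals[1] + alpha * k)) -
       log((counts[, 2] + alpha) / (class_totals[2] + alpha * k))
  unname(w)
}

#' Prior log-odds term of the decision rule
#'
#' `log(p1 / p2)` where `p1`, `p2` are the prior probabilities of the
#' adverse and normal classes. With the default equal priors the term is 0
#' and the decision threshold of the score sits at zero.
#'
#' @param p1 prior probability of the adverse class.
#' @param p2 prior probability of the normal class; must sum to 1 with `p1`.
#' @return `log(p1 / p2)`.
#' @export
prior_term <- function(p1, p2 = 1 - p1) {
  if (!is.finite(p1) || !is.finite(p2) || p1 <= 0 || p2 <= 0) {
    stop_data("prior_term: priors must be positive")
  }
  if (abs(p1 + p2 - 1) > 1e-9) stop_data("prior_term: priors must sum to 1")
  log(p1 / p2)
}

#' Fit a naive-Bayes scoring system
#'
#' Fits the additive scoring system for prolonged ICU stay: every feature
#' is discretized (dichotomous features as-is; continuous/discrete features
#' into the four quartile intervals of the training sample), each category
#' receives a log-likelihood-ratio weight estimated from class-conditional
#' counts, and a patient's score is the sum of the weights of their
#' categories plus the prior log-odds term. The patient is classified as
#' adverse (prolonged stay) when the score is greater than or equal to
#' zero; with the default equal priors this is the naive-Bayes decision
#' rule with threshold zero.
#'
#' Counts are the source of truth: weights are cached but always
#' re-derivable, so the model can be updated incrementally with
#' [update.nb_scorecard()] by adding or removing records, and serialized as
#' human-readable descriptive tables ([write_scorecard()],
#' [weight_table()]).
#'
#' @param x an `icu_cohort` (complete-case).
#' @param features names of the predictors to include (default: all
#'   declared features, e.g. after [screen_features()] and
#'   [forward_select()]).
#' @param alpha additive smoothing count per category (default 0.5,
#'   Jeffreys); use 0 for pure maximum-likelihood weights.
#' @param priors prior class probabilities `c(adverse, normal)`; default
#'   `c(0.5, 0.5)` which places the decision threshold at score 0.
#' @return an object of class `nb_scorecard` with elements `specs`,
#'   `counts`, `class_totals`, `alpha`, `priors`, `weights` and
#'   `prior_term`.
#' @seealso [predict.nb_scorecard()], [update.nb_scorecard()],
#'   [forward_select()], [cross_validate()]
#' @export
nb_scorecard <- function(x, features = NULL, alpha = 0.5,
                         priors = c(0.5, 0.5)) {
  stopifnot(inherits(x, "icu_cohort"))
  if (anyNA(x$data)) stop_data("nb_scorecard: cohort has missing values; run filter_complete()")
  est <- estimate_counts(x, features)
  if (any(est$class_totals == 0)) {
    stop_data("nb_scorecard: both outcome classes must be present")
  }
  model <- structure(list(specs = est$specs, counts = est$counts,
                          class_totals = est$class_totals,
                          alpha = alpha,
                          priors = c(adverse = priors[1], normal = priors[2]),
                          weights = NULL,
                          prior_term = prior_term(priors[1], priors[2]),
                          call = match.call()),
                     class = "nb_scorecard")
  refresh_weights(model)
}

refresh_weights <- function(model) {
  model$weights <- lapply(model$counts, function(m) {
    w <- weights_from_counts(m, model$class_totals, model$alpha)
    names(w) <- rownames(m)
    w
  })
  model
}

#' Score patients with a fitted scorecard
#'
#' Raw values are discretized with the model's frozen discretizers (the
#' training quartile edges are reused verbatim), then each feature
#' contributes its category weight. A record missing any model feature is
#' an error naming the feature.
#'
#' @param object a fitted `nb_scorecard`.
#' @param newdata an `icu_cohort` or a data.frame of raw feature values.
#' @param type `"score"` for the total score (weights + prior term),
#'   `"class"` for the predicted class (adverse iff score >= 0; a score of
#'   exactly 0 classifies adverse, the conservative choice for a risk
#'   screen), or `"contrib"` for the n x p matrix of per-feature weight
#'   contributions (attribute `"prior_term"` holds the additive constant).
#' @param ... unused.
#' @return numeric scores, a factor of classes, or a contribution matrix.
#' @export
predict.nb_scorecard <- function(object, newdata,
                                 type = c("score", "class", "contrib"), ...) {
  type <- match.arg(type)
  data <- if (inherits(newdata, "icu_cohort")) newdata$data else newdata
  bins <- discretize_records(data, object$specs)
  contrib <- vapply(seq_along(object$specs), function(j) {
    object$weights[[j]][bins[, j]]
  }, numeric(nrow(bins)))
  contrib <- matrix(contrib, nrow = nrow(bins),
                    dimnames = list(NULL, names(object$counts)))
  if (type == "contrib") {
    attr(contrib, "prior_term") <- object$prior_term
    return(contrib)
  }
  score <- rowSums(contrib) + object$prior_term
  if (type == "score") score else outcome_factor(score >= 0)
}

#' Score a single patient record
#'
#' Convenience wrapper around [predict.nb_scorecard()] returning the full
#' breakdown for one patient.
#'
#' @param object a fitted `nb_scorecard`.
#' @param record a one-row data.frame (or a named list) of raw values.
#' @return list with `total_score`, `contributions` (named per-feature
#'   weights applied), `prior_term` and `decision`.
#' @export
score_patient <- function(object, record) {
  if (!is.data.frame(record)) record <- as.data.frame(record, stringsAsFactors = FALSE)
  if (nrow(record) != 1L) stop_data("score_patient: exactly one record expected")
  contrib <- predict(object, record, type = "contrib")
  total <- sum(contrib[1, ]) + object$prior_term
  list(total_score = total,
       contributions = contrib[1, ],
       prior_term = object$prior_term,
       decision = outcome_factor(total >= 0))
}

#' Update a scorecard by adding and/or removing patient records
#'
#' The defining convenience of the count-based scoring system: entering new
#' and removing older data only increments or decrements the descriptive
#' count tables, after which the weights are recomputed exactly. The frozen
#' discretizer edges are kept unless `refit = TRUE`, in which case the
#' model is refitted from scratch on `full_cohort` (edges re-estimated).
#'
#' @param object a fitted `nb_scorecard`.
#' @param add,remove `icu_cohort` objects (or `NULL`). Removed records must
#'   have been counted previously: a decrement below zero is a consistency
#'   error.
#' @param refit if `TRUE`, refit on `full_cohort` instead of updating
#'   counts.
#' @param full_cohort the complete updated cohort, required when
#'   `refit = TRUE`.
#' @param ... unused.
#' @return the updated `nb_scorecard`.
#' @export
update.nb_scorecard <- function(object, add = NULL, remove = NULL,
                                refit = FALSE, full_cohort = NULL, ...) {
  if (refit) {
    if (is.null(full_cohort)) stop_data("update: refit = TRUE requires full_cohort")
    return(nb_scorecard(full_cohort, features = names(object$counts),
                        alpha = object$alpha,
                        priors = unname(object$priors)))
  }
  apply_delta <- function(model, coh, sign) {
    stopifnot(inherits(coh, "icu_cohort"))
    bins <- discretize_records(coh$data, model$specs)
    y <- coh$outcome == "adverse"
    for (j in seq_along(model$specs)) {
      k <- length(model$specs[[j]]$categories)
      model$counts[[j]][, "adverse"] <- model$counts[[j]][, "adverse"] +
        sign * tabulate(bins[y, j], nbins = k)
      model$counts[[j]][, "normal"] <- model$counts[[j]][, "normal"] +
        sign * tabulate(bins[!y, j], nbins = k)
    }
    model$class_totals <- model$class_totals +
      sign * c(adverse = sum(y), normal = sum(!y))
    model
  }
  if (!is.null(add)) object <- apply_delta(object, add, +1L)
  if (!is.null(remove)) object <- apply_delta(object, remove, -1L)
  if (any(unlist(object$counts) < 0) || any(object$class_totals < 0)) {
    stop_data("update: removal would drive a count below zero; ",
              "removed records were never part of the model")
  }
  refresh_weights(object)
}

#' @export
coef.nb_scorecard <- function(object, ...) {
  unlist(object$weights)
}

#' @export
print.nb_scorecard <- function(x, ...) {
  cat(sprintf("Naive-Bayes scoring system: %d features, fitted on %d patients (%d adverse / %d normal)\n",
              length(x$counts), sum(x$class_totals),
              x$class_totals["adverse"], x$class_totals["normal"]))
  cat(sprintf("Smoothing alpha = %g; priors (adverse, normal) = (%g, %g); decision threshold 0\n",
              x$alpha, x$priors["adverse"], x$priors["normal"]))
  invisible(x)
}

#' @export
summary.nb_scorecard <- function(object, ...) {
  structure(list(model = object, tables = weight_table(object)),
            class = "summary.nb_scorecard")
}

#' @export
print.summary.nb_scorecard <- function(x, ...) {
  print(x$model)
  if (nrow(x$tables$dichotomous)) {
    cat("\nWeights of dichotomous features:\n")
    print(x$tables$dichotomous, digits = 4, row.names = FALSE)
  }
  if (nrow(x$tables$quartile)) {
    cat("\nWeights of quartile-discretized features:\n")
    print(x$tables$quartile, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Per-feature contribution profile plot
#'
#' Plots each feature's category weights, the additive score
#' contributions; for quartile-discretized features the profile is
#' typically monotone from the first to the fourth quartile interval.
#'
#' @param x a fitted `nb_scorecard`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.nb_scorecard <- function(x, ...) {
  w <- x$weights
  k <- max(vapply(w, length, 1L))
  m <- vapply(w, function(v) c(v, rep(NA, k - length(v))), numeric(k))
  graphics::matplot(seq_len(k), m, type = "b", pch = 19, lty = 1,
                    xlab = "category index", ylab = "weight (log-likelihood ratio)",
                    xaxt = "n", ...)
  graphics::axis(1, at = seq_len(k))
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topleft", legend = names(w), col = seq_along(w),
                   lty = 1, pch = 19, cex = 0.7, bty = "n")
  invisible(x)
}

#' Residuals of a fitted scorecard
#'
#' Classification residuals on a cohort: observed class indicator (1 =
#' adverse) minus the model's posterior probability of the adverse class
#' implied by the score, `plogis(score)`.
#'
#' @param object a fitted `nb_scorecard`.
#' @param newdata an `icu_cohort`; required.
#' @param ... unused.
#' @export
residuals.nb_scorecard <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "icu_cohort"))
  s <- predict(object, newdata, type = "score")
  as.numeric(newdata$outcome == "adverse") - stats::plogis(s)
}
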