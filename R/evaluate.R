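#' Area under the ROC curve (Mann-Whitney statistic)
#'
#' AUC as the probability that a randomly chosen adverse patient scores
#' above a randomly chosen normal patient, ties counted one half;
#' identical to the trapezoidal area under the empirical ROC curve.
#' Computed from midranks in O(n log n).
#'
#' @param scores numeric scores (higher = more adverse).
#' @param labels outcome labels (see [cohort()]); both classes must be
#'   present.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc(c(3, 1, 2, 0), c("adverse", "adverse", "normal", "normal")) # 0.75
auc <- function(scores, labels) {
  y <- as_adverse(labels)
  n1 <- as.numeric(sum(y)); n2 <- as.numeric(sum(!y))
  if (n1 == 0 || n2 == 0) stop_data("auc: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Empirical ROC curve
#'
#' One operating point per distinct score threshold (prediction rule:
#' adverse iff score >= threshold), anchored at (0, 0) and (1, 1). The
#' trapezoidal area under the returned points equals [auc()] to numerical
#' precision.
#'
#' @inheritParams auc
#' @return data.frame with columns `fpr` and `tpr`, both non-decreasing.
#' @export
roc_points <- function(scores, labels) {
  y <- as_adverse(labels)
  n1 <- sum(y); n2 <- sum(!y)
  if (n1 == 0L || n2 == 0L) stop_data("roc_points: both classes must be present")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]
  grp <- !duplicated(scores[o])          # first index of each distinct score
  tp <- cumsum(ys); fp <- cumsum(!ys)
  last <- c(which(grp)[-1] - 1L, length(ys))  # last index of each score group
  data.frame(fpr = c(0, fp[last] / n2), tpr = c(0, tp[last] / n1))
}

#' Confusion matrix at a score threshold
#'
#' Predicts adverse iff `score >= threshold` (default 0, the equal-priors
#' decision threshold). Rows of the conceptual matrix are the actual
#' classes (normal, adverse), columns the predictions, so the counts are
#' `tn`, `fp`, `fn`, `tp`.
#'
#' @inheritParams auc
#' @param threshold decision threshold on the score.
#' @return object of class `confusion`: list with counts `tn`, `fp`, `fn`,
#'   `tp`.
#' @export
confusion_matrix <- function(scores, labels, threshold = 0) {
  y <- as_adverse(labels)
  pred <- scores >= threshold
  structure(list(tn = sum(!y & !pred), fp = sum(!y & pred),
                 fn = sum(y & !pred), tp = sum(y & pred)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, 2, byrow = TRUE,
              dimnames = list(c("actual normal", "actual adverse"),
                              c("pred normal", "pred adverse")))
  print(m)
  met <- classification_metrics(x)
  cat(sprintf("SP = %d%%, SE = %d%%, overall = %d%%\n",
              met$sp_pct, met$se_pct, met$accuracy_pct))
  invisible(x)
}

#' Sensitivity, specificity and overall accuracy
#'
#' Sensitivity is the correct-classification rate among adverse (prolonged
#' stay) patients, specificity the rate among normal patients. Percentages
#' are rounded to the configured number of digits (default whole percent,
#' the conventional reporting precision); the raw proportions are always
#' returned alongside.
#'
#' @param cm a `confusion` object, or numeric vector `c(tn, fp, fn, tp)`.
#' @param digits rounding for the percentage fields.
#' @return list with raw proportions `sensitivity`, `specificity`,
#'   `accuracy` and rounded percentages `se_pct`, `sp_pct`, `accuracy_pct`.
#' @export
#' @examples
#' classification_metrics(c(2403, 492, 93, 268))
classification_metrics <- function(cm, digits = 0) {
  if (!inherits(cm, "confusion")) {
    cm <- structure(list(tn = cm[1], fp = cm[2], fn = cm[3], tp = cm[4]),
                    class = "confusion")
  }
  if (cm$tp + cm$fn == 0 || cm$tn + cm$fp == 0) {
    stop_data("classification_metrics: a class row is empty")
  }
  se <- cm$tp / (cm$tp + cm$fn)
  sp <- cm$tn / (cm$tn + cm$fp)
  acc <- (cm$tp + cm$tn) / (cm$tn + cm$fp + cm$fn + cm$tp)
  list(sensitivity = se, specificity = sp, accuracy = acc,
       se_pct = round(100 * se, digits), sp_pct = round(100 * sp, digits),
       accuracy_pct = round(100 * acc, digits))
}

#' Random k-fold assignment
#'
#' A seeded random permutation split into `k` folds whose sizes differ by
#' at most one; folds are disjoint and exhaustive.
#'
#' @param n number of records.
#' @param k number of folds (default 5).
#' @param seed optional integer seed; when given, the assignment is fully
#'   reproducible.
#' @return integer vector of fold ids in `1..k`.
#' @export
kfold <- function(n, k = 5, seed = NULL) {
  if (n < k) stop_data("kfold: need n >= k")
  if (!is.null(seed)) set.seed(seed)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  rep(seq_len(k), sizes)[sample.int(n)]
}

#' @export
`[.icu_cohort` <- function(x, i, ...) cohort_subset(x, i)

cohort_subset <- function(x, idx) {
  out <- x
  out$data <- x$data[idx, , drop = FALSE]
  rownames(out$data) <- NULL
  out$outcome <- x$outcome[idx]
  if (!is.null(x$los)) out$los <- x$los[idx]
  out
}

# Fit counts on a cohort under pre-built (frozen) discretizer specs.
fit_with_specs <- function(x, specs, alpha, priors) {
  bins <- discretize_records(x$data, specs)
  y <- x$outcome == "adverse"
  counts <- lapply(seq_along(specs), function(j) {
    k <- length(specs[[j]]$categories)
    m <- cbind(adverse = tabulate(bins[y, j], nbins = k),
               normal = tabulate(bins[!y, j], nbins = k))
    rownames(m) <- specs[[j]]$categories
    m
  })
  names(counts) <- vapply(specs, `[[`, "", "name")
  model <- structure(list(specs = specs, counts = counts,
                          class_totals = c(adverse = sum(y), normal = sum(!y)),
                          alpha = alpha,
                          priors = c(adverse = priors[1], normal = priors[2]),
                          weights = NULL,
                          prior_term = prior_term(priors[1], priors[2]),
                          call = NULL),
                     class = "nb_scorecard")
  refresh_weights(model)
}

#' Five-fold cross-validation of a scoring system
#'
#' The feature set is fixed beforehand (screening and stepwise selection
#' happen once, on the full sample); cross-validation then assesses how
#' the scoring system performs when its weights are estimated on data
#' different from the testing data. In each of the `k` rounds the weights
#' -- and, by default, the quartile edges and category definitions -- are
#' re-estimated on the k-1 training folds and the held-out fold is scored.
#' Every record is scored out-of-fold exactly once; the pooled out-of-fold
#' scores give the testing-set AUC and confusion matrix.
#'
#' @param x an `icu_cohort`.
#' @param features the selected feature names.
#' @param k number of folds (default 5).
#' @param seed optional seed for the fold assignment.
#' @param alpha,priors passed to the per-fold fits.
#' @param stratified assign folds within each outcome class (useful for
#'   small cohorts where a plain random split can leave a fold without
#'   adverse patients).
#' @param refit_discretizers re-estimate quartile edges on each training
#'   split (default). `FALSE` freezes the full-sample edges, the
#'   deployment-scoring convention.
#' @param threshold decision threshold for the pooled confusion matrix.
#' @return object of class `cv_result`: list with `fold` (assignment),
#'   `fold_auc` (held-out AUC per fold), `train_auc` (per-fold training
#'   AUC), `scores` (pooled out-of-fold scores, original record order),
#'   `labels`, `pooled_auc`, `mean_auc` (average of `fold_auc`, the
#'   non-pooled alternative), `confusion` and `metrics`.
#' @export
cross_validate <- function(x, features, k = 5, seed = NULL, alpha = 0.5,
                           priors = c(0.5, 0.5), stratified = FALSE,
                           refit_discretizers = TRUE, threshold = 0) {
  stopifnot(inherits(x, "icu_cohort"))
  n <- length(x$outcome)
  if (!is.null(seed)) set.seed(seed)
  if (stratified) {
    fold <- integer(n)
    for (cl in levels(x$outcome)) {
      idx <- which(x$outcome == cl)
      fold[idx] <- kfold(length(idx), k)
    }
  } else {
    fold <- kfold(n, k)
  }
  frozen <- if (!refit_discretizers) build_specs(x, features) else NULL
  scores <- numeric(n)
  fold_auc <- train_auc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    if (length(unique(x$outcome[tr])) < 2L || length(unique(x$outcome[te])) < 2L) {
      stop_data("cross_validate: fold ", f, " is missing an outcome class; ",
                "try stratified = TRUE")
    }
    train <- cohort_subset(x, tr)
    model <- if (is.null(frozen)) {
      nb_scorecard(train, features = features, alpha = alpha, priors = priors)
    } else {
      fit_with_specs(train, frozen, alpha, priors)
    }
    scores[te] <- predict(model, cohort_subset(x, te), type = "score")
    fold_auc[f] <- auc(scores[te], x$outcome[te])
    train_auc[f] <- auc(predict(model, train, type = "score"), x$outcome[tr])
  }
  cm <- confusion_matrix(scores, x$outcome, threshold)
  structure(list(fold = fold, fold_auc = fold_auc, train_auc = train_auc,
                 scores = scores, labels = x$outcome,
                 pooled_auc = auc(scores, x$outcome),
                 mean_auc = mean(fold_auc),
                 confusion = cm,
                 metrics = classification_metrics(cm)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  k <- length(x$fold_auc)
  cat(sprintf("%d-fold cross-validation\n", k))
  cat(sprintf("Per-fold testing AUC: %s\n",
              paste(sprintf("%.3f", x$fold_auc), collapse = " ")))
  cat(sprintf("Pooled out-of-fold AUC: %.4f (mean per-fold %.4f; mean training %.4f)\n",
              x$pooled_auc, x$mean_auc, mean(x$train_auc)))
  print(x$confusion)
  invisible(x)
}
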