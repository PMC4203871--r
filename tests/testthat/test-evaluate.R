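test_that("AUC matches the pairwise definition on hand and random fixtures", {
  expect_equal(auc(c(3, 1, 2, 0), c("adverse", "adverse", "normal", "normal")),
               0.75)
  expect_equal(auc(c(5, 6, 1, 2), outcome_factor_vec(c(TRUE, TRUE, FALSE, FALSE))),
               1)
  expect_equal(auc(rep(2, 10), outcome_factor_vec(rep(c(TRUE, FALSE), 5))), 0.5)
  expect_error(auc(1:3, outcome_factor_vec(c(TRUE, TRUE, TRUE))),
               class = "icuscore_data_error")
  for (seed in 1:25) {
    f <- random_scores(n = 30, seed = seed, ties = seed %% 2 == 0)
    y <- f$labels == "adverse"
    expect_equal(auc(f$scores, f$labels), auc_bruteforce(f$scores, y),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  f <- random_scores(n = 60, seed = 3)
  a0 <- auc(f$scores, f$labels)
  expect_equal(auc(exp(f$scores), f$labels), a0, tolerance = 1e-12)
  expect_equal(auc(5 * f$scores - 2, f$labels), a0, tolerance = 1e-12)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  f <- random_scores(n = 200, seed = 8, ties = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = f$labels, predictor = f$scores,
    levels = c("normal", "adverse"), direction = "<", quiet = TRUE)))
  expect_equal(auc(f$scores, f$labels), ref, tolerance = 1e-12)
})

test_that("ROC points are monotone, anchored and integrate to the AUC", {
  p <- roc_points(c(1, 2), outcome_factor_vec(c(FALSE, TRUE)))
  expect_equal(nrow(p), 3L)
  expect_equal(p$fpr[1], 0); expect_equal(p$tpr[nrow(p)], 1)
  trapz <- function(p) sum(diff(p$fpr) * (head(p$tpr, -1) + tail(p$tpr, -1)) / 2)
  for (seed in 1:500) {
    f <- random_scores(n = 25, seed = seed, ties = seed %% 3 == 0)
    p <- roc_points(f$scores, f$labels)
    expect_true(all(diff(p$fpr) >= 0) && all(diff(p$tpr) >= 0))
    expect_equal(trapz(p), auc(f$scores, f$labels), tolerance = 1e-12)
  }
})

test_that("confusion matrix stores the published testing-set layout", {
  ref <- reference_confusion()
  expect_equal(c(ref$tn, ref$fp, ref$fn, ref$tp), c(2403, 492, 93, 268))
  # scores engineered to reproduce those counts through the threshold rule
  scores <- c(rep(-1, 2403), rep(1, 492), rep(-1, 93), rep(1, 268))
  labels <- outcome_factor_vec(c(rep(FALSE, 2895), rep(TRUE, 361)))
  cm <- confusion_matrix(scores, labels, threshold = 0)
  expect_equal(cm[c("tn", "fp", "fn", "tp")], ref[c("tn", "fp", "fn", "tp")])

  all_adv <- confusion_matrix(scores, labels, threshold = -Inf)
  expect_equal(all_adv$tn + all_adv$fn, 0L)

  for (seed in 1:200) {   # loop oracle
    f <- random_scores(n = 40, seed = seed, ties = TRUE)
    cm <- confusion_matrix(f$scores, f$labels, threshold = 3)
    y <- f$labels == "adverse"
    tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
    for (i in seq_along(y)) {
      pred <- f$scores[i] >= 3
      if (y[i] && pred) tp <- tp + 1L else if (y[i]) fn <- fn + 1L
      else if (pred) fp <- fp + 1L else tn <- tn + 1L
    }
    expect_equal(c(cm$tn, cm$fp, cm$fn, cm$tp), c(tn, fp, fn, tp))
  }
})

test_that("sensitivity/specificity/accuracy follow their definitions", {
  m <- classification_metrics(c(2403, 492, 93, 268))
  expect_equal(c(m$sp_pct, m$se_pct, m$accuracy_pct), c(83, 74, 82))
  perfect <- classification_metrics(c(50, 0, 0, 10))
  expect_equal(c(perfect$se_pct, perfect$sp_pct, perfect$accuracy_pct),
               c(100, 100, 100))
  # overall = prevalence-weighted mix of SE and SP, exactly, before rounding
  n_adv <- 361; n_norm <- 2895
  expect_equal(m$accuracy,
               (m$sensitivity * n_adv + m$specificity * n_norm) / (n_adv + n_norm),
               tolerance = 1e-12)
  expect_error(classification_metrics(c(0, 0, 3, 7)),
               class = "icuscore_data_error")
})

test_that("k-fold assignment partitions with near-equal sizes", {
  f <- kfold(3256, 5, seed = 1)
  expect_equal(sort(tabulate(f, 5), decreasing = TRUE),
               c(652, 651, 651, 651, 651))
  expect_equal(tabulate(kfold(5, 5, seed = 2), 5), rep(1L, 5))
  expect_identical(kfold(100, 5, seed = 7), kfold(100, 5, seed = 7))
  expect_false(identical(kfold(100, 5, seed = 7), kfold(100, 5, seed = 8)))
  expect_error(kfold(3, 5), class = "icuscore_data_error")
  for (seed in 1:5) {
    f <- kfold(101, 5, seed = seed)
    expect_equal(sort(unique(f)), 1:5)              # exhaustive
    expect_lte(diff(range(tabulate(f, 5))), 1)      # balanced
  }
})

test_that("cross-validation scores every record exactly once", {
  coh <- random_cohort(n = 600, d = 2, c = 2, seed = 14)
  cv <- cross_validate(coh, c("bin1", "num1"), k = 5, seed = 3)
  expect_equal(length(cv$scores), 600L)
  expect_true(all(is.finite(cv$scores)))
  expect_equal(length(cv$fold_auc), 5L)
  expect_equal(cv$pooled_auc, auc(cv$scores, coh$outcome), tolerance = 1e-12)
  # fold assignment partitions the cohort for every seed
  for (s in 1:4) {
    cvs <- cross_validate(coh, "bin1", k = 4, seed = s)
    expect_equal(sort(unique(cvs$fold)), 1:4)
  }
})

test_that("null cohorts cross-validate to chance AUC", {
  set.seed(99)
  n <- 3000
  df <- data.frame(a = rnorm(n), b = rnorm(n),
                   c = factor(sample(c("no", "yes"), n, TRUE),
                              levels = c("no", "yes")))
  coh <- cohort(df, outcome = outcome_factor_vec(runif(n) < 0.15),
                schema = data.frame(name = c("a", "b", "c"),
                                    kind = c("continuous", "continuous",
                                             "dichotomous"),
                                    role = "unspecified"))
  cv <- cross_validate(coh, c("a", "b", "c"), k = 5, seed = 17)
  expect_lt(abs(cv$pooled_auc - 0.5), 0.03)
})

test_that("training AUC exceeds testing AUC on average (optimism)", {
  diffs <- numeric(20)
  for (seed in 1:20) {
    coh <- random_cohort(n = 500, d = 2, c = 2, shift = 0.6,
                         prev = 0.2, seed = 100 + seed)
    cv <- cross_validate(coh, coh$schema$name, k = 5, seed = seed)
    diffs[seed] <- mean(cv$train_auc) - cv$pooled_auc
  }
  expect_gt(mean(diffs), 0)
})

test_that("a fold without adverse patients is a clear error", {
  df <- data.frame(a = rnorm(40))
  y <- rep(FALSE, 40); y[1] <- TRUE
  coh <- cohort(df, outcome = outcome_factor_vec(y))
  expect_error(cross_validate(coh, "a", k = 5, seed = 1), "stratified",
               class = "icuscore_data_error")
})
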