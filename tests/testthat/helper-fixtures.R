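# Fixture builders shared across test files. Everything is generated in
# code; no stored binary data.

# Minimal hand-checkable cohort: one dichotomous, one continuous feature.
toy_cohort <- function() {
  df <- data.frame(
    dialysis = c("yes", "yes", "no", "no", "no", "no", "yes", "no"),
    creat = c(2.1, 1.3, 0.9, 1.1, 0.7, 1.0, 1.8, 0.8),
    stringsAsFactors = FALSE)
  y <- c("adverse", "normal", "adverse", "normal",
         "normal", "normal", "adverse", "normal")
  cohort(df, outcome = y,
         schema = data.frame(name = c("dialysis", "creat"),
                             kind = c("dichotomous", "continuous"),
                             role = "unspecified", stringsAsFactors = FALSE))
}

# Random cohort with d dichotomous and c continuous features; `shift`
# controls how informative the continuous features are.
random_cohort <- function(n = 500, d = 2, c = 2, shift = 1, prev = 0.3,
                          seed = 1) {
  set.seed(seed)
  y <- runif(n) < prev
  cols <- list()
  for (j in seq_len(d)) {
    p <- ifelse(y, pmin(0.9, 0.2 + 0.3 * shift), 0.2)
    cols[[paste0("bin", j)]] <- factor(ifelse(runif(n) < p, "yes", "no"),
                                       levels = c("no", "yes"))
  }
  for (j in seq_len(c)) {
    cols[[paste0("num", j)]] <- rnorm(n, mean = ifelse(y, shift, 0))
  }
  cohort(as.data.frame(cols), outcome = outcome_factor_vec(y))
}

outcome_factor_vec <- function(adverse) {
  factor(ifelse(adverse, "adverse", "normal"), levels = c("normal", "adverse"))
}

# Score/label fixture for ROC tests.
random_scores <- function(n = 40, seed = 1, ties = FALSE) {
  set.seed(seed)
  y <- runif(n) < 0.4
  if (!any(y)) y[1] <- TRUE
  if (all(y)) y[1] <- FALSE
  s <- if (ties) sample(1:5, n, replace = TRUE) else rnorm(n) + y
  list(scores = s, labels = outcome_factor_vec(y))
}

# Brute-force pairwise AUC: the independent oracle for auc().
auc_bruteforce <- function(scores, adverse) {
  s1 <- scores[adverse]; s2 <- scores[!adverse]
  tot <- 0
  for (a in s1) for (b in s2) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s2))
}
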