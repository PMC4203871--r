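#' BCa bootstrap confidence interval
#'
#' Bias-corrected and accelerated bootstrap percentile interval for an
#' arbitrary statistic of a sample. Records are resampled with replacement
#' (rows of a data.frame or matrix, elements of a vector), so paired
#' quantities such as score/label stay attached. The bias correction is
#' `z0 = qnorm(#\{theta* < theta_hat\} / B)` with the proportion clipped to
#' `[1/(B+1), B/(B+1)]`; the acceleration `a` comes from the jackknife
#' skewness formula
#' `a = sum(d^3) / (6 * sum(d^2)^{3/2})`, `d_i = mean(theta_(-i)) - theta_(-i)`.
#' Interval endpoints are the bootstrap quantiles at the BCa-adjusted
#' percentile levels. When `z0 = 0` and `a = 0` this reduces to the plain
#' percentile interval.
#'
#' A resample on which the statistic cannot be evaluated (e.g. an AUC
#' resample containing a single outcome class) is redrawn, up to
#' `max_retry` attempts per replicate.
#'
#' @param data vector, matrix or data.frame of records.
#' @param statistic function of one argument (the resampled data)
#'   returning a scalar.
#' @param B number of bootstrap replicates (default 1000).
#' @param level two-sided confidence level (default 0.95).
#' @param seed optional integer seed.
#' @param max_retry redraw budget per degenerate replicate.
#' @return object of class `bca_ci`: list with `estimate`, `median_boot`
#'   (median of the replicates), `ci_low`, `ci_high`, `level`, `B`, `z0`,
#'   `a` and `replicates`.
#' @export
bca_ci <- function(data, statistic, B = 1000, level = 0.95, seed = NULL,
                   max_retry = 100) {
  if (B < 1) stop_data("bca_ci: B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- NROW(data)
  take <- function(idx) {
    if (is.null(dim(data))) data[idx] else data[idx, , drop = FALSE]
  }
  theta_hat <- statistic(data)
  if (!is.finite(theta_hat)) stop_numeric("bca_ci: statistic not finite on the data")

  theta_star <- numeric(B)
  for (b in seq_len(B)) {
    val <- NA_real_
    for (try in seq_len(max_retry)) {
      idx <- sample.int(n, n, replace = TRUE)
      val <- tryCatch(statistic(take(idx)), error = function(e) NA_real_)
      if (is.finite(val)) break
    }
    if (!is.finite(val)) {
      stop_numeric("bca_ci: statistic failed on ", max_retry,
                   " consecutive resamples")
    }
    theta_star[b] <- val
  }

  prop <- sum(theta_star < theta_hat) / B
  prop <- min(max(prop, 1 / (B + 1)), B / (B + 1))
  z0 <- stats::qnorm(prop)

  jack <- vapply(seq_len(n), function(i) statistic(take(-i)), numeric(1))
  d <- mean(jack) - jack
  denom <- sum(d^2)^1.5
  a_hat <- if (denom > 0) sum(d^3) / (6 * denom) else 0

  zalpha <- stats::qnorm(c((1 - level) / 2, 1 - (1 - level) / 2))
  adj <- stats::pnorm(z0 + (z0 + zalpha) / (1 - a_hat * (z0 + zalpha)))
  adj <- pmin(pmax(adj, 0), 1)
  ci <- unname(stats::quantile(theta_star, adj, type = 7))

  structure(list(estimate = theta_hat,
                 median_boot = unname(stats::median(theta_star)),
                 ci_low = ci[1], ci_high = ci[2],
                 level = level, B = B, z0 = z0, a = a_hat,
                 replicates = theta_star),
            class = "bca_ci")
}

#' @export
print.bca_ci <- function(x, ...) {
  cat(sprintf("BCa bootstrap (B = %d): estimate %.4f, median %.4f, %g%% CI [%.4f, %.4f]\n",
              x$B, x$estimate, x$median_boot, 100 * x$level, x$ci_low, x$ci_high))
  cat(sprintf("  z0 = %.4f, a = %.4f\n", x$z0, x$a))
  invisible(x)
}

#' BCa confidence interval for an AUC
#'
#' Convenience wrapper: bootstraps score/label pairs and returns the BCa
#' interval of the AUC.
#'
#' @param scores,labels as in [auc()].
#' @inheritParams bca_ci
#' @return a `bca_ci` object.
#' @export
auc_ci <- function(scores, labels, B = 1000, level = 0.95, seed = NULL) {
  df <- data.frame(score = scores, y = as_adverse(labels))
  bca_ci(df, function(d) auc(d$score, d$y), B = B, level = level, seed = seed)
}
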