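#' Cross-tabulate a binary exposure against the outcome
#'
#' Builds the 2x2 table used for odds-ratio screening, with the fixed
#' orientation `a` = exposed & adverse, `b` = unexposed & adverse, `c` =
#' exposed & normal, `d` = unexposed & normal.
#'
#' @param exposure logical vector, or a 2-level factor whose second level
#'   is taken as exposed.
#' @param labels outcome labels (see [cohort()]).
#' @return object of class `table2x2`: list with integer counts `a`, `b`,
#'   `c`, `d`.
#' @export
contingency_2x2 <- function(exposure, labels) {
  y <- as_adverse(labels)
  if (is.factor(exposure)) {
    if (nlevels(exposure) > 2L) stop_data("contingency_2x2: exposure not binary")
    e <- exposure == levels(exposure)[nlevels(exposure)]
  } else if (is.numeric(exposure)) {
    if (!all(exposure %in% c(0, 1))) stop_data("contingency_2x2: exposure not binary")
    e <- exposure == 1
  } else {
    e <- as.logical(exposure)
  }
  if (length(e) != length(y)) stop_data("contingency_2x2: length mismatch")
  if (anyNA(e)) stop_data("contingency_2x2: missing exposure values")
  structure(list(a = sum(e & y), b = sum(!e & y),
                 c = sum(e & !y), d = sum(!e & !y)),
            class = "table2x2")
}

#' Odds ratio with a log-normal (Woolf) confidence interval
#'
#' OR = (a d)/(b c); the interval is
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` with `z` the
#' standard-normal quantile for the requested two-sided confidence
#' (2.5758 at 99%). If any cell is zero, the Haldane-Anscombe correction
#' adds 0.5 to every cell first and the result is flagged `corrected`.
#'
#' @param tab a `table2x2` from [contingency_2x2()], or a numeric vector
#'   `c(a, b, c, d)`.
#' @param conf.level two-sided confidence level, default 0.99 as used for
#'   univariate screening.
#' @return object of class `or_ci`: list with `estimate`, `ci_low`,
#'   `ci_high`, `conf.level`, `significant` (interval excludes 1) and
#'   `corrected`.
#' @export
#' @examples
#' odds_ratio_ci(c(10, 90, 5, 95))
odds_ratio_ci <- function(tab, conf.level = 0.99) {
  if (inherits(tab, "table2x2")) tab <- c(tab$a, tab$b, tab$c, tab$d)
  if (length(tab) != 4L || any(tab < 0)) stop_data("odds_ratio_ci: need 4 non-negative counts")
  a <- tab[1]; b <- tab[2]; cc <- tab[3]; d <- tab[4]
  if (a + b == 0 || cc + d == 0) stop_data("odds_ratio_ci: degenerate class margin")
  if (a + cc == 0 || b + d == 0) stop_data("odds_ratio_ci: degenerate exposure margin")
  corrected <- any(c(a, b, cc, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  lo <- exp(log(or) - z * se)
  hi <- exp(log(or) + z * se)
  structure(list(estimate = or, ci_low = lo, ci_high = hi,
                 conf.level = conf.level,
                 significant = lo > 1 || hi < 1,
                 corrected = corrected, se_log = se),
            class = "or_ci")
}

#' @export
print.or_ci <- function(x, ...) {
  cat(sprintf("OR = %.4g, %g%% CI (%.4g, %.4g)%s%s\n", x$estimate,
              100 * x$conf.level, x$ci_low, x$ci_high,
              if (x$significant) " *" else "",
              if (x$corrected) " [0.5 added to all cells]" else ""))
  invisible(x)
}

#' Univariate odds-ratio screening of candidate predictors
#'
#' Each dichotomous variable is tested as-is; each non-dichotomous variable
#' is first dichotomized at its median cut-off ([median_cutoff()]). A
#' variable is retained when the two-sided confidence interval of its odds
#' ratio excludes 1 (equivalently p < 1 - `conf.level`). Constant variables
#' cannot be tested and are excluded with a warning. Retained
#' non-dichotomous variables proceed to modelling in 4-category quartile
#' form, not in the dichotomized form used here.
#'
#' @param x an `icu_cohort` (complete-case; see [filter_complete()]).
#' @param conf.level screening confidence level, default 0.99.
#' @param features optional subset of feature names to screen.
#' @return a `screening_report` data.frame, one row per screened feature in
#'   input order, with columns `feature`, `kind`, `cutoff` (median used for
#'   dichotomization; `NA` for dichotomous variables), `or`, `ci_low`,
#'   `ci_high`, `corrected` and `retained`.
#' @export
screen_features <- function(x, conf.level = 0.99, features = NULL) {
  stopifnot(inherits(x, "icu_cohort"))
  features <- features %||% x$schema$name
  rows <- lapply(features, function(nm) {
    kind <- x$schema$kind[match(nm, x$schema$name)]
    v <- x$data[[nm]]
    cutoff <- NA_real_
    if (kind == "dichotomous") {
      expo <- v
    } else {
      cutoff <- median_cutoff(v)
      expo <- dichotomize(v, cutoff)
    }
    if (length(unique(expo[!is.na(expo)])) < 2L) {
      warning("screen_features: '", nm, "' is constant; excluded")
      return(data.frame(feature = nm, kind = kind, cutoff = cutoff,
                        or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        corrected = NA, retained = FALSE,
                        stringsAsFactors = FALSE))
    }
    res <- odds_ratio_ci(contingency_2x2(expo, x$outcome), conf.level)
    data.frame(feature = nm, kind = kind, cutoff = cutoff,
               or = res$estimate, ci_low = res$ci_low, ci_high = res$ci_high,
               corrected = res$corrected, retained = res$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("screening_report", "data.frame")
  attr(out, "conf.level") <- conf.level
  out
}

#' Reconstruct a 2x2 table from a reported odds-ratio interval
#'
#' Inverts the Woolf interval: given a published confidence interval
#' `(lo, hi)` and the class margins, finds integer cell counts whose
#' log-odds-ratio and standard error reproduce the interval as closely as
#' possible. Useful for re-analysing published univariate screening
#' results when only the intervals, not the counts, are reported.
#'
#' @param lo,hi published interval bounds.
#' @param n1,n2 adverse and normal class sizes (rows of the table).
#' @param conf.level confidence level of the published interval.
#' @return a `table2x2` (counts `a`, `b`, `c`, `d`).
#' @export
table_from_or_ci <- function(lo, hi, n1, n2, conf.level = 0.99) {
  if (!(lo > 0 && hi > lo)) stop_data("table_from_or_ci: need 0 < lo < hi")
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  lor <- (log(lo) + log(hi)) / 2
  se2 <- ((log(hi) - log(lo)) / (2 * z))^2
  obj <- function(p) {
    a <- stats::plogis(p[1]) * n1; cc <- stats::plogis(p[2]) * n2
    b <- n1 - a; d <- n2 - cc
    f1 <- log(a * d / (b * cc)) - lor
    f2 <- (1 / a + 1 / b + 1 / cc + 1 / d) - se2
    f1^2 + (f2 / se2)^2
  }
  best <- NULL
  for (st in list(c(-2, -2), c(-1, -3), c(0, -2), c(-3, -1))) {
    fit <- stats::optim(st, obj, control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  a0 <- stats::plogis(best$par[1]) * n1
  c0 <- stats::plogis(best$par[2]) * n2
  cand <- expand.grid(a = pmax(1, round(a0) + (-2:2)),
                      c = pmax(1, round(c0) + (-2:2)))
  errs <- mapply(function(a, cc) {
    r <- odds_ratio_ci(c(a, n1 - a, cc, n2 - cc), conf.level)
    (log(r$ci_low) - log(lo))^2 + (log(r$ci_high) - log(hi))^2
  }, cand$a, cand$c)
  i <- which.min(errs)
  structure(list(a = cand$a[i], b = n1 - cand$a[i],
                 c = cand$c[i], d = n2 - cand$c[i]),
            class = "table2x2")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("Univariate odds-ratio screening at %g%% confidence\n",
              100 * attr(x, "conf.level")))
  cat(sprintf("Retained %d of %d candidate predictors\n\n",
              sum(x$retained), nrow(x)))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
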