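#' Median cut-off of a clinical variable
#'
#' Sample median under the linear-interpolation quantile convention
#' (`stats::quantile()` type 7). This is the cut-off used to dichotomize
#' non-dichotomous variables before univariate odds-ratio screening.
#'
#' @param x numeric vector with at least one finite value.
#' @return the median cut-off (a single number).
#' @seealso [dichotomize()], [quartile_edges()]
#' @export
#' @examples
#' median_cutoff(c(1, 2, 3, 4)) # 2.5
median_cutoff <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop_data("median_cutoff: no finite values")
  unname(stats::quantile(x, 0.5, type = 7, names = FALSE))
}

#' Dichotomize a variable at a cut-off
#'
#' Values less than or equal to the cut-off map to `"low"`, values above it
#' to `"high"`. Ties at the cut-off fall in the low category; this single
#' rule is fixed so that saved models discretize new data identically.
#'
#' @param x numeric vector (finite values).
#' @param cutoff the cut-off point, typically [median_cutoff()] of the
#'   training sample.
#' @return factor with levels `c("low", "high")`.
#' @export
dichotomize <- function(x, cutoff) {
  if (!is.numeric(x)) stop_data("dichotomize: x must be numeric")
  if (any(!is.finite(x))) stop_data("dichotomize: non-finite value in input")
  if (!is.finite(cutoff)) stop_data("dichotomize: non-finite cutoff")
  factor(ifelse(x <= cutoff, "low", "high"), levels = c("low", "high"))
}

#' Quartile edges of a training sample
#'
#' First, second and third quartiles under the same linear-interpolation
#' convention as [median_cutoff()]; the second edge always equals the median
#' cut-off of the same data. Edges are estimated on training data and then
#' frozen inside a fitted scorecard, so new patients are binned exactly as
#' the training cohort was.
#'
#' @param x numeric vector with at least 4 finite values.
#' @return numeric vector `c(q1, q2, q3)` with attribute `source_n`, the
#'   number of values used.
#' @export
#' @examples
#' quartile_edges(1:8) # 2.75 4.50 6.25
quartile_edges <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4L) stop_data("quartile_edges: need at least 4 finite values")
  e <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(e, names = c("q1", "q2", "q3"), source_n = length(x))
}

#' Assign quartile-interval bins
#'
#' Maps values to the four quartile intervals defined by three edges, using
#' half-open intervals `(lo, hi]`: bin 1 is `x <= q1`, bin 2 is
#' `q1 < x <= q2`, bin 3 is `q2 < x <= q3`, bin 4 is `x > q3`. Values equal
#' to an edge therefore fall in the lower bin, matching [dichotomize()].
#'
#' @param x numeric vector (finite values).
#' @param edges numeric vector of 3 non-decreasing edges, e.g. from
#'   [quartile_edges()].
#' @return integer vector of bins in 1..4.
#' @export
assign_bin <- function(x, edges) {
  if (length(edges) != 3L || any(!is.finite(edges))) {
    stop_data("assign_bin: edges must be 3 finite numbers")
  }
  if (is.unsorted(edges)) stop_data("assign_bin: edges must be non-decreasing")
  if (any(!is.finite(x))) stop_data("assign_bin: non-finite value in input")
  if (edges[1] == edges[3]) {
    warning("assign_bin: degenerate edges (all equal); values map to bin 1 or 4")
  }
  1L + (x > edges[1]) + (x > edges[2]) + (x > edges[3])
}
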