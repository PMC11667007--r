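#' Wilcoxon signed-rank test for paired metrics
#'
#' Zero differences are discarded (classical Wilcoxon convention). The exact
#' signed-rank null distribution is used when `n <= 25` after zero removal
#' and the differences are tie-free; otherwise the normal approximation with
#' tie correction (no continuity correction). Two-sided throughout.
#'
#' @param x,y paired numeric vectors of equal length (e.g. per-case DSC
#'   under two conditions).
#' @return list with `W` (the smaller of the two signed-rank sums), `V`
#'   (positive-rank sum), `p` (two-sided), `n` (pairs after zero removal),
#'   and `exact` (logical).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate: all zero differences")
  if (n < 2) stop("need n >= 2 nonzero differences")
  ties <- any(duplicated(abs(d)))
  exact <- n <= 25 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = "two.sided",
                       exact = exact, correct = FALSE))
  V <- unname(ht$statistic)
  list(W = min(V, n * (n + 1) / 2 - V), V = V, p = unname(ht$p.value),
       n = n, exact = exact)
}

#' Bonferroni-adjusted significance threshold
#'
#' `alpha / m`, with a 2-significant-figure display string (so 0.05 over 27
#' comparisons prints as `1.9e-03`).
#'
#' @param alpha family-wise significance level.
#' @param m number of comparisons (>= 1).
#' @return list with `threshold` (numeric `alpha/m`) and `display`
#'   (2-significant-figure scientific string).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 1) {
  if (m < 1) stop("m must be >= 1")
  thr <- alpha / m
  list(threshold = thr, display = format(signif(thr, 2), scientific = TRUE))
}

#' Per-case medians across repeated iterations
#'
#' Collapses repeated runs to one median value per case, so downstream tests
#' are computed over independent data points rather than pooled repeats.
#'
#' @param values_by_iteration list of named numeric vectors (one per
#'   iteration), all keyed by the same case ids.
#' @return named numeric vector of per-case medians.
#' @export
aggregate_repeats <- function(values_by_iteration) {
  if (length(values_by_iteration) == 0) stop("no iterations")
  ids <- names(values_by_iteration[[1]])
  if (is.null(ids)) stop("iteration values must be named by case id")
  for (v in values_by_iteration)
    if (!setequal(names(v), ids)) stop("misaligned case ids across iterations")
  mat <- vapply(values_by_iteration, function(v) v[ids], numeric(length(ids)))
  mat <- matrix(mat, nrow = length(ids))
  stats::setNames(apply(mat, 1, stats::median), ids)
}

#' Significance stars for a p-value
#'
#' `*`, `**`, `***`, `****` at thresholds 1e-3, 1e-6, 1e-9, 1e-12; `"ns"`
#' otherwise.
#'
#' @param p p-value.
#' @return character.
#' @export
significance_stars <- function(p) {
  if (p < 1e-12) "****" else if (p < 1e-9) "***" else if (p < 1e-6) "**"
  else if (p < 1e-3) "*" else "ns"
}
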