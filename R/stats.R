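# Cohort-level statistics: binomial proportion intervals, rank-sum and
# exact contingency tests, correlation.  Thin, auditable wrappers around
# the standard implementations, with the method used recorded in the
# return value.

#' Binomial proportion with confidence interval
#'
#' Point estimate k/n with an exact (Clopper-Pearson) interval from beta
#' quantiles.  Used for reverser-percentage bars, where day-to-day spread
#' is consistent with counting noise.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (> 0).
#' @param level confidence level (default 0.95).
#' @return list with `point`, `lower`, `upper`, `level`, `method`.
#' @export
binomial_proportion_ci <- function(k, n, level = 0.95) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (k < 0 || k > n) stop("k must lie in [0, n]", call. = FALSE)
  alpha <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  list(point = k / n, lower = lower, upper = upper, level = level,
       method = "clopper-pearson")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null distribution for small samples (combined n <= 25, no ties),
#' normal approximation with tie and continuity correction otherwise.
#'
#' @param sample_a,sample_b numeric samples (nonempty).
#' @return list with `p_value`, `statistic` (rank-sum W of sample_a),
#'   `method`.
#' @export
rank_sum_test <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    stop("both samples must be nonempty", call. = FALSE)
  n <- length(sample_a) + length(sample_b)
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  exact <- n <= 25 && !ties
  ht <- suppressWarnings(stats::wilcox.test(sample_a, sample_b,
                                            exact = exact, correct = TRUE))
  list(p_value = ht$p.value, statistic = unname(ht$statistic),
       method = if (exact) "exact" else "normal-approximation")
}

#' Two-sided Fisher's exact test for R x C class-count tables
#'
#' Exact (network-algorithm) p-value for 2 x 2 tables and for larger tables
#' with total count <= `exact_limit`; otherwise a seeded Monte-Carlo
#' p-value with its standard error.
#'
#' @param table matrix of nonnegative integer counts (conditions x classes).
#' @param exact_limit largest total count for which the exact computation
#'   is attempted on R x C tables (default 200).
#' @param mc_draws Monte-Carlo replicates when sampling is needed.
#' @param seed seed for the Monte-Carlo path (reproducible).
#' @return list with `p_value`, `method`, and `mc_se` (NA when exact).
#' @export
fisher_exact <- function(table, exact_limit = 200, mc_draws = 1e5, seed = 1) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("table must hold nonnegative integer counts", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("table has an all-zero margin", call. = FALSE)
  total <- sum(table)
  if (all(dim(table) == 2) || total <= exact_limit) {
    ht <- stats::fisher.test(table)
    return(list(p_value = ht$p.value, method = "exact", mc_se = NA_real_))
  }
  ht <- with_seed(seed, stats::fisher.test(table, simulate.p.value = TRUE,
                                           B = mc_draws))
  p <- ht$p.value
  list(p_value = p, method = sprintf("monte-carlo (B = %g)", mc_draws),
       mc_se = sqrt(p * (1 - p) / mc_draws))
}

#' Pearson correlation with p-value
#'
#' Product-moment correlation and the two-sided p-value from the t
#' transform, as used to relate pre-stimulus front/rear polarity to
#' migration speed.
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y", call. = FALSE)
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}
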