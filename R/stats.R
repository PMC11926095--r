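#' Nonparametric hypothesis-testing toolkit
#'
#' The analysis pipeline gates every dependent variable through a
#' Shapiro-Wilk normality test (none of the study variables pass) and then
#' uses distribution-free procedures: two-sided Mann-Whitney U tests for
#' categorical predictors, Spearman correlation for continuous ones, and the
#' Hodges-Lehmann estimator (median of all pairwise differences) with a
#' distribution-free 95% confidence interval for effect sizes. The type I
#' error level is 0.05 throughout and no multiple-testing correction is
#' applied: p-values are per-comparison.
#'
#' @name stats_toolkit
NULL

#' Hodges-Lehmann shift estimate with distribution-free confidence interval
#'
#' The estimate is the median of all n1 x n2 pairwise differences x_i - y_j.
#' The confidence interval takes the order statistics of the sorted pairwise
#' differences at the ranks given by the Mann-Whitney critical value for the
#' two-sided level `1 - conf_level`.
#'
#' @param x,y non-empty numeric samples.
#' @param conf_level confidence level (default 0.95).
#' @return List with `estimate`, `ci_low`, `ci_high`, `conf_level`.
#' @export
hodges_lehmann <- function(x, y, conf_level = 0.95) {
  if (!length(x) || !length(y)) stopf("empty sample")
  d <- sort(as.vector(outer(x, y, "-")))
  m <- length(x); n <- length(y)
  alpha <- 1 - conf_level
  k <- qwilcox(alpha / 2, m, n)  # largest w with P(W <= w) <= alpha/2
  lo <- if (k >= 1) d[k] else -Inf
  hi <- if (k >= 1) d[m * n + 1 - k] else Inf
  list(estimate = median(d), ci_low = lo, ci_high = hi, conf_level = conf_level)
}

#' Two-sided Mann-Whitney U test with Hodges-Lehmann effect size
#'
#' Exact enumeration for small tie-free samples, tie-corrected normal
#' approximation otherwise (the default behavior of [stats::wilcox.test()]).
#' The reported U counts pairs where x exceeds y.
#'
#' @param x,y non-empty numeric samples.
#' @param conf_level level of the Hodges-Lehmann confidence interval.
#' @return List with `statistic` (U), `p_value`, `effect_size`
#'   (Hodges-Lehmann), `ci_low`, `ci_high`, `n1`, `n2`.
#' @export
mann_whitney_two_sided <- function(x, y, conf_level = 0.95) {
  if (!length(x) || !length(y)) stopf("empty sample")
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  hl <- hodges_lehmann(x, y, conf_level)
  list(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    effect_size = hl$estimate,
    ci_low = hl$ci_low,
    ci_high = hl$ci_high,
    n1 = length(x), n2 = length(y)
  )
}

#' Spearman rank correlation with average ranks for ties
#'
#' @param a,b equal-length numeric vectors, n >= 3.
#' @return List with `rho`, `p_value`, `n`; `flagged = TRUE` with NA rho
#'   when either input is constant.
#' @export
spearman_correlation <- function(a, b) {
  if (length(a) != length(b)) stopf("length mismatch")
  if (length(a) < 3) stopf("need at least 3 observations")
  if (sd(a) == 0 || sd(b) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = length(a), flagged = TRUE))
  }
  ct <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(a),
       flagged = FALSE)
}

#' Shapiro-Wilk normality gate
#'
#' Returns TRUE (treat as normal) when Shapiro-Wilk does not reject at
#' `alpha`; constant samples are non-normal by convention and flagged.
#'
#' @param sample numeric vector with 3 <= n <= 5000.
#' @param alpha significance level.
#' @return Logical verdict with attributes `p_value` and `flagged`.
#' @export
normality_gate <- function(sample, alpha = 0.05) {
  n <- length(sample)
  if (n < 3 || n > 5000) stopf("Shapiro-Wilk requires 3 <= n <= 5000")
  if (sd(sample) == 0) {
    return(structure(FALSE, p_value = NA_real_, flagged = TRUE))
  }
  sw <- shapiro.test(sample)
  structure(sw$p.value >= alpha, p_value = sw$p.value, flagged = FALSE)
}
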