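# Two-database sensitivity analysis: chi-squared homogeneity test on the
# 2x2 case/non-case table, 99% normal-approximation confidence interval for
# the rate difference, and a proportion effect size (Cohen's h by default).

#' Chi-squared homogeneity test for two samples
#'
#' Pearson chi-squared (no continuity correction, df = 1) on the 2x2 table
#' of cases/non-cases by sample. When any expected cell is below 5 the test
#' is still computed but flagged.
#'
#' @param x1,n1 cases and denominator in sample 1.
#' @param x2,n2 cases and denominator in sample 2.
#' @return list: `chi2`, `df`, `p_value`, `small_expected` flag.
#' @export
chi2_homogeneity <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 <= n1, x2 <= n2)
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (x1 + x2 == 0 || (n1 - x1) + (n2 - x2) == 0) {
    # degenerate margin: identical proportions by construction
    return(list(chi2 = 0, df = 1L, p_value = 1,
                small_expected = any(expected < 5)))
  }
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), small_expected = any(expected < 5))
}

#' Normal-approximation confidence interval for a rate difference
#'
#' Difference of the two sample proportions with a Wald interval,
#' \eqn{\hat p_1 - \hat p_2 \pm z_{1-\alpha/2}
#' \sqrt{p_1(1-p_1)/n_1 + p_2(1-p_2)/n_2}}, reported per 100,000. The
#' default level is 99% (\eqn{z = 2.5758}).
#'
#' @inheritParams chi2_homogeneity
#' @param conf_level confidence level, default 0.99.
#' @return list: `diff`, `lcl`, `ucl`, per 100,000.
#' @export
rate_diff_ci <- function(x1, n1, x2, n2, conf_level = 0.99) {
  stopifnot(n1 > 0, n2 > 0)
  p1 <- x1 / n1
  p2 <- x2 / n2
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  list(diff = 1e5 * (p1 - p2),
       lcl = 1e5 * (p1 - p2 - z * se),
       ucl = 1e5 * (p1 - p2 + z * se))
}

#' Effect size for the difference of two proportions
#'
#' The default is Cohen's h, \eqn{h = |2\arcsin\sqrt{p_1} -
#' 2\arcsin\sqrt{p_2}|}, the standard effect size for a difference of
#' proportions. `method = "d"` gives a pooled-SD standardized difference
#' (d-on-proportions) as an alternative convention. Both are symmetric,
#' zero iff the proportions are equal, and dimensionless; values below 0.2
#' are conventionally negligible.
#'
#' @inheritParams chi2_homogeneity
#' @param method `"h"` (default) or `"d"`.
#' @return nonnegative effect size.
#' @export
effect_size <- function(x1, n1, x2, n2, method = c("h", "d")) {
  method <- match.arg(method)
  stopifnot(n1 > 0, n2 > 0)
  p1 <- x1 / n1
  p2 <- x2 / n2
  if (method == "h") {
    abs(2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2)))
  } else {
    s2 <- ((n1 - 1) * p1 * (1 - p1) + (n2 - 1) * p2 * (1 - p2)) / (n1 + n2 - 2)
    if (s2 == 0) 0 else abs(p1 - p2) / sqrt(s2)
  }
}

#' Heterogeneity comparison row for two samples
#'
#' Combines [chi2_homogeneity()], [rate_diff_ci()] and [effect_size()] into
#' one tidy row, the tabular form of the study's forest-plot comparison.
#'
#' @inheritParams chi2_homogeneity
#' @param conf_level level for the rate-difference interval, default 0.99.
#' @return one-row data.table: `x1,n1,x2,n2,chi2,df,p,diff_per_100k,lcl99,
#'   ucl99,effect_size,small_expected_flag`.
#' @export
heterogeneity_row <- function(x1, n1, x2, n2, conf_level = 0.99) {
  ht <- chi2_homogeneity(x1, n1, x2, n2)
  ci <- rate_diff_ci(x1, n1, x2, n2, conf_level)
  data.table(x1 = x1, n1 = n1, x2 = x2, n2 = n2,
             chi2 = ht$chi2, df = ht$df, p = ht$p_value,
             diff_per_100k = ci$diff, lcl99 = ci$lcl, ucl99 = ci$ucl,
             effect_size = effect_size(x1, n1, x2, n2),
             small_expected_flag = ht$small_expected)
}
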