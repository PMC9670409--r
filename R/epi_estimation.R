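# Crude and stratified rates, direct standardization against a reference
# population, extrapolated counts, and Fay-Feuer gamma confidence intervals
# for directly standardized rates under a Poisson model.

#' Read or construct a reference population
#'
#' A reference population is a table with columns `age_group` (the three
#' study bands), `sex` and `count`, exhaustively covering ages 2-15 by sex
#' with positive counts. Stratum weights for direct standardization are the
#' normalized counts.
#'
#' `default_reference_population()` returns the stand-in reference shipped
#' with the package (`reference_population_synthetic.csv`): a synthetic
#' approximation of the German population aged 2-15 (10.48 million in
#' total), constructed because official stratum counts are not distributed
#' with the package. Supply your own table for real analyses.
#'
#' @param path CSV file with columns `age_group,sex,count`.
#' @return data.table with `age_group`, `sex`, `count`.
#' @export
read_reference_population <- function(path) {
  ref <- fread(path)
  miss <- setdiff(c("age_group", "sex", "count"), names(ref))
  if (length(miss)) {
    stop(sprintf("schema error in reference population: missing column(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  validate_reference(ref)
  ref
}

#' @rdname read_reference_population
#' @export
default_reference_population <- function() {
  read_reference_population(
    system.file("extdata", "reference_population_synthetic.csv",
                package = "jiaclaims", mustWork = TRUE))
}

validate_reference <- function(ref) {
  full <- CJ(age_group = AGE_GROUPS, sex = SEX_LEVELS)
  if (nrow(ref) != nrow(full) ||
      nrow(merge(ref, full, by = c("age_group", "sex"))) != nrow(full)) {
    stop("reference population must contain exactly the six (age group, sex) strata",
         call. = FALSE)
  }
  if (any(ref$count <= 0)) stop("reference counts must be positive", call. = FALSE)
  invisible(ref)
}

#' Crude rate per 100,000
#'
#' @param x total case count.
#' @param n total denominator (person count, > 0).
#' @return rate per 100,000.
#' @export
crude_rate <- function(x, n) {
  if (any(n <= 0)) stop("undefined rate: denominator is zero", call. = FALSE)
  1e5 * x / n
}

# Align a stratified count table (age_group, sex, x, n) with a reference
# population; returns per-stratum x, n and normalized weights w.
align_strata <- function(counts, ref) {
  counts <- as.data.table(counts)
  m <- merge(counts, ref, by = c("age_group", "sex"))
  if (nrow(m) != nrow(counts)) {
    missing <- counts[!ref, on = c("age_group", "sex")]
    stop(sprintf("stratum absent from reference population: %s",
                 paste(missing$age_group, missing$sex, collapse = "; ")),
         call. = FALSE)
  }
  zero <- m[n == 0]
  if (nrow(zero)) {
    stop(sprintf("undefined rate: empty denominator in stratum %s",
                 paste(zero$age_group, zero$sex, collapse = "; ")),
         call. = FALSE)
  }
  m[, w := count / sum(count)]
  m
}

#' Directly standardized rate per 100,000
#'
#' \deqn{R = 10^5 \sum_s w_s x_s / n_s,\qquad w_s = N_s / \sum_t N_t}
#' where \eqn{x_s, n_s} are the sample's stratum case counts and
#' denominators and \eqn{N_s} the reference population counts. Weights are
#' normalized within whichever stratum set is supplied.
#'
#' @param counts data.frame with columns `age_group`, `sex`, `x`, `n`
#'   (one row per stratum present in the sample).
#' @param ref reference population, see [read_reference_population()].
#' @return standardized rate per 100,000.
#' @export
standardized_rate <- function(counts, ref) {
  m <- align_strata(counts, ref)
  1e5 * m[, sum(w * x / n)]
}

#' Fay-Feuer gamma confidence interval for a standardized rate
#'
#' With per-person weights \eqn{c_s = w_s / n_s}, the standardized rate is
#' \eqn{R = \sum_s c_s x_s} with variance estimate \eqn{v = \sum_s c_s^2 x_s}
#' under independent Poisson stratum counts. The lower limit is the
#' \eqn{\alpha/2} quantile of a gamma distribution with shape \eqn{R^2/v}
#' and scale \eqn{v/R} (0 when \eqn{R = 0}); the upper limit is the
#' \eqn{1-\alpha/2} quantile with shape \eqn{(R+c^*)^2/(v+c^{*2})} and scale
#' \eqn{(v+c^{*2})/(R+c^*)}, where \eqn{c^*} is the largest per-person
#' weight over all strata (including zero-count strata — the conservative
#' choice). With a single stratum of weight one the interval reduces to the
#' exact Poisson gamma interval.
#'
#' @inheritParams standardized_rate
#' @param alpha two-sided error level, default 0.05.
#' @return list with `rate`, `lcl`, `ucl` (per 100,000) and `variance`
#'   (per-person scale).
#' @export
fay_feuer_ci <- function(counts, ref, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  m <- align_strata(counts, ref)
  cs <- m$w / m$n
  R <- sum(cs * m$x)
  v <- sum(cs^2 * m$x)
  cstar <- max(cs)
  lcl <- if (R > 0) qgamma(alpha / 2, shape = R^2 / v, scale = v / R) else 0
  ucl <- qgamma(1 - alpha / 2,
                shape = (R + cstar)^2 / (v + cstar^2),
                scale = (v + cstar^2) / (R + cstar))
  list(rate = 1e5 * R, lcl = 1e5 * lcl, ucl = 1e5 * ucl, variance = v)
}

#' Extrapolate a standardized rate to reference-population counts
#'
#' Each of rate/lcl/ucl (per 100,000) is multiplied by the total reference
#' population over 100,000 and rounded to whole persons.
#'
#' @param rate,lcl,ucl standardized rate and confidence bounds per 100,000.
#' @param ref reference population.
#' @return list with `extrapolated_n`, `extrapolated_lcl`,
#'   `extrapolated_ucl` (integer counts).
#' @export
extrapolate <- function(rate, lcl, ucl, ref) {
  f <- sum(ref$count) / 1e5
  list(extrapolated_n = round(rate * f),
       extrapolated_lcl = round(lcl * f),
       extrapolated_ucl = round(ucl * f))
}

#' Standardized estimate with Fay-Feuer interval and extrapolation
#'
#' Convenience wrapper combining [standardized_rate()], [fay_feuer_ci()] and
#' [extrapolate()] for one stratified count table.
#'
#' @inheritParams fay_feuer_ci
#' @return a one-row data.table: `x`, `n`, `rate`, `lcl`, `ucl`,
#'   `extrapolated_n`, `extrapolated_lcl`, `extrapolated_ucl`.
#' @export
standardized_estimate <- function(counts, ref, alpha = 0.05) {
  ci <- fay_feuer_ci(counts, ref, alpha)
  ex <- extrapolate(ci$rate, ci$lcl, ci$ucl, ref)
  data.table(x = sum(counts$x), n = sum(counts$n),
             rate = ci$rate, lcl = ci$lcl, ucl = ci$ucl,
             extrapolated_n = ex$extrapolated_n,
             extrapolated_lcl = ex$extrapolated_lcl,
             extrapolated_ucl = ex$extrapolated_ucl)
}
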