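# Rates, direct standardization, Fay-Feuer intervals, extrapolation.

equal_ref <- function(count = 1e6) {
  data.frame(age_group = rep(c("2-5", "6-11", "12-15"), each = 2),
             sex = rep(c("female", "male"), 3), count = count)
}

strat_counts <- function(x, n) {
  data.frame(age_group = rep(c("2-5", "6-11", "12-15"), each = 2),
             sex = rep(c("female", "male"), 3), x = x, n = n)
}

test_that("crude rate is cases per 100,000 denominator", {
  expect_equal(crude_rate(546, 401531), 100000 * 546 / 401531)
  expect_equal(round(crude_rate(546, 401531), 2), 135.98)
  expect_equal(crude_rate(0, 1000), 0)
  expect_equal(crude_rate(1000, 1000), 1e5)
  expect_error(crude_rate(1, 0), "denominator")
})

test_that("standardized rate is the reference-weighted stratum mean", {
  # equal weights, stratum rates 100 and 300 -> 200
  counts <- strat_counts(x = c(10, 10, 10, 30, 30, 30), n = 1e4)
  r <- standardized_rate(counts, equal_ref())
  expect_equal(r, 200)
  # single stratum reduces to the crude rate
  one <- data.frame(age_group = "6-11", sex = "female", x = 7, n = 3500)
  expect_equal(standardized_rate(one, equal_ref()[3, ]), crude_rate(7, 3500))
  # hand-computed weighted sum with unequal weights
  ref <- equal_ref()
  ref$count <- c(100, 200, 300, 400, 500, 600)
  counts <- strat_counts(x = c(1, 2, 3, 4, 5, 6), n = c(1, 2, 4, 8, 16, 32) * 1000)
  w <- ref$count / sum(ref$count)
  expected <- 1e5 * sum(w * counts$x / counts$n)
  expect_equal(standardized_rate(counts, ref), expected)
  # convexity: between min and max stratum rates
  sr <- 1e5 * counts$x / counts$n
  expect_gte(standardized_rate(counts, ref), min(sr))
  expect_lte(standardized_rate(counts, ref), max(sr))
})

test_that("standardization errors on empty or unmatched strata", {
  counts <- strat_counts(x = 0, n = c(100, 0, 100, 100, 100, 100))
  expect_error(standardized_rate(counts, equal_ref()), "empty denominator")
  bad <- data.frame(age_group = "16-18", sex = "female", x = 1, n = 100)
  expect_error(standardized_rate(bad, equal_ref()), "absent from reference")
})

test_that("crude and standardized rates agree when sample matches reference", {
  ref <- equal_ref(c(100, 200, 300, 400, 500, 600) * 1000)
  counts <- strat_counts(x = c(3, 5, 8, 13, 21, 34),
                         n = c(100, 200, 300, 400, 500, 600) * 10)
  expect_equal(standardized_rate(counts, ref),
               crude_rate(sum(counts$x), sum(counts$n)), tolerance = 1e-9)
})

test_that("Fay-Feuer single-stratum interval equals the exact Poisson gamma interval", {
  ref <- equal_ref()[1, ]
  for (x in c(0, 1, 10, 50)) {
    counts <- data.frame(age_group = "2-5", sex = "female", x = x, n = 1e5)
    ci <- fay_feuer_ci(counts, ref, alpha = 0.05)
    expect_equal(ci$rate, x)
    if (x == 0) {
      expect_equal(ci$lcl, 0)
    } else {
      expect_equal(ci$lcl, qgamma(0.025, shape = x), tolerance = 1e-12)
    }
    expect_equal(ci$ucl, qgamma(0.975, shape = x + 1), tolerance = 1e-12)
  }
  # the worked single-stratum example: x = 10 per 100,000; bounds equal the
  # textbook chi-squared form of the exact Poisson interval
  counts <- data.frame(age_group = "2-5", sex = "female", x = 10, n = 1e5)
  ci <- fay_feuer_ci(counts, ref)
  expect_equal(round(ci$lcl, 3), 4.795)
  expect_equal(round(ci$ucl, 3), 18.390)
  expect_equal(ci$lcl, 0.5 * qchisq(0.025, 2 * 10), tolerance = 1e-12)
  expect_equal(ci$ucl, 0.5 * qchisq(0.975, 2 * (10 + 1)), tolerance = 1e-12)
})

test_that("Fay-Feuer intervals contain the rate and nest across levels", {
  set.seed(21)
  ref <- equal_ref(sample(1e5:1e6, 6))
  for (rep in 1:20) {
    counts <- strat_counts(x = rpois(6, 20), n = sample(1e4:1e5, 6))
    ci95 <- fay_feuer_ci(counts, ref, 0.05)
    ci99 <- fay_feuer_ci(counts, ref, 0.01)
    expect_lte(ci95$lcl, ci95$rate)
    expect_gte(ci95$ucl, ci95$rate)
    expect_lte(ci99$lcl, ci95$lcl)
    expect_gte(ci99$ucl, ci95$ucl)
  }
})

test_that("extrapolation scales rate and bounds by the reference total", {
  ref <- equal_ref()  # total 6e6
  ex <- extrapolate(133, 122, 145, ref)
  expect_equal(ex$extrapolated_n, round(133 * 60))
  expect_lte(ex$extrapolated_lcl, ex$extrapolated_n)
  expect_gte(ex$extrapolated_ucl, ex$extrapolated_n)
  expect_equal(extrapolate(0, 0, 0, ref)$extrapolated_n, 0)
  # internal consistency of the rate/count pairing at the package reference
  ref0 <- default_reference_population()
  ex0 <- extrapolate(133, 122, 145, ref0)
  expect_equal(ex0$extrapolated_n, round(133 * sum(ref0$count) / 1e5))
})
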