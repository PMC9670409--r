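# Generator: seeded determinism, truth alignment, load-bearing filters,
# binomial behaviour of the true-case count.

test_that("generator config validation rejects inconsistent settings", {
  expect_error(generator_config(category_mix = c(sJIA = 0.5, oligoJIA = 0.4)),
               "sum to 1")
  expect_error(generator_config(inpatient_fraction = 1.5), "0, 1")
  expect_error(generator_config(
    stratum_rates = uniform_rates(50, 100)), "prevalence must be >= incidence")
  expect_error(generator_config(years = 2015:2018, anchor_year = 2020),
               "anchor_year")
})

test_that("same config and seed reproduce the database exactly", {
  cfg <- test_config()
  a <- simulate_claims(cfg)
  b <- simulate_claims(cfg)
  expect_equal(a$db$patients, b$db$patients)
  expect_equal(a$db$coverage, b$db$coverage)
  expect_equal(a$db$diagnoses, b$db$diagnoses)
  expect_equal(a$truth, b$truth)
  # a different seed gives different data
  c <- simulate_claims(test_config(seed = 99))
  expect_false(identical(a$db$diagnoses, c$db$diagnoses))
})

test_that("zero prevalence and zero noise yield no JIA-coded records", {
  sim <- simulate_claims(test_config(
    stratum_rates = uniform_rates(0, 0), noise_dx_rate = 0))
  expect_equal(nrow(sim$truth), 0L)
  jia <- sim$db$diagnoses[icd_match(icd_code,
                                    jia_case_definition()$code_prefixes)]
  expect_equal(nrow(jia), 0L)
})

test_that("the outpatient qualifier filter is load-bearing", {
  # every case event outpatient and non-confirmed: nothing is ascertained
  sim <- simulate_claims(test_config(
    stratum_rates = uniform_rates(2000, 500),
    nonconfirmed_fraction = 1, inpatient_fraction = 0, noise_dx_rate = 0))
  expect_gt(nrow(sim$truth), 0L)
  prev <- prevalent_cohort(sim$db, year = 2018)
  expect_equal(length(prev$case_ids), 0L)
})

test_that("every generated record passes claims_db validation round-trip", {
  sim <- simulate_claims(test_config(death_rate = 0.01))
  rebuilt <- claims_db(sim$db$patients, sim$db$coverage, sim$db$diagnoses,
                       label = sim$db$label)
  expect_equal(rebuilt$diagnoses, sim$db$diagnoses)
})

test_that("true-case count at the anchor year behaves binomially", {
  # n = 50,000 at uniform prevalence 150/100,000: expectation 75; the count
  # must fall in the central 99% binomial interval
  sim <- simulate_claims(generator_config(
    n_patients = 50000, years = 2018, anchor_year = 2018,
    stratum_rates = uniform_rates(150), background_dx_rate = 0, seed = 11))
  n_true <- nrow(sim$truth[year == 2018])
  bounds <- qbinom(c(0.005, 0.995), 50000, 150 / 1e5)
  expect_gte(n_true, bounds[1])
  expect_lte(n_true, bounds[2])
})

test_that("truth invariants hold: incident implies case, one category per case", {
  sim <- simulate_claims(test_config(stratum_rates = uniform_rates(600, 300)))
  expect_true(all(sim$truth$true_case))
  expect_true(all(sim$truth$true_incident <= sim$truth$true_case))
  expect_false(anyNA(sim$truth$true_category))
  # a patient's category is constant over years
  ncat <- sim$truth[, data.table::uniqueN(true_category), by = patient_id]$V1
  expect_true(all(ncat == 1L))
  # incident truth only at the anchor year
  expect_true(all(sim$truth[true_incident == TRUE, year] == 2018))
})

test_that("simulate_claims_pair yields disjoint patient populations", {
  pair <- simulate_claims_pair(test_config(n_patients = 1000),
                               second_seed = 7, labels = c("A", "B"))
  ids1 <- pair[[1]]$db$patients$patient_id
  ids2 <- pair[[2]]$db$patients$patient_id
  expect_length(intersect(ids1, ids2), 0L)
  expect_equal(pair[[1]]$db$label, "A")
  expect_equal(pair[[2]]$db$label, "B")
  # same config apart from label: identical truth summary
  pair2 <- simulate_claims_pair(test_config(n_patients = 1000),
                                second_seed = 42, labels = c("A", "B"))
  expect_equal(nrow(pair2[[1]]$truth), nrow(pair[[1]]$truth))
})

test_that("realized true-case fraction tracks configured prevalence (LLN)", {
  # high prevalence so the relative Monte-Carlo error is well below the
  # +/-5% acceptance band at n = 200,000
  n <- 200000
  p <- 2000
  sim <- simulate_claims(generator_config(
    n_patients = n, years = 2018, anchor_year = 2018,
    stratum_rates = uniform_rates(p), background_dx_rate = 0,
    noise_dx_rate = 0, seed = 5))
  frac <- nrow(sim$truth[year == 2018]) / n * 1e5
  expect_lt(abs(frac - p) / p, 0.05)
})
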