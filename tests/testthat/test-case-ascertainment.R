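# Phenotyping: M2Q rule, qualifying-event filter, cohorts, washout, ILAR.

test_that("qualifying_events keeps only matching, confirmed-or-inpatient events", {
  db <- one_patient_db(list(
    odx("p1", "M08.4", quarter = 1, qualifier = "suspected"),
    odx("p1", "M08.4", quarter = 2),
    odx("p1", "M99.1", quarter = 3),
    idx("p1", "M08.4", quarter = 3, main = TRUE)))
  evs <- qualifying_events(db, "p1", jia_case_definition(), 2018)
  expect_equal(nrow(evs), 2L)
  expect_setequal(evs$setting, c("outpatient", "inpatient_main"))
  # suspected-only patient yields no qualifying events
  db2 <- one_patient_db(odx("p1", "M08.4", qualifier = "suspected"))
  expect_equal(nrow(qualifying_events(db2, "p1", jia_case_definition(), 2018)), 0L)
  expect_error(qualifying_events(db, "nope", jia_case_definition(), 2018),
               "unknown patient")
})

test_that("meets_m2q follows the written rule on the canonical examples", {
  expect_true(meets_m2q(ev(3, "inpatient_main")))
  expect_false(meets_m2q(ev(c(2, 2), c("outpatient", "outpatient"))))
  expect_true(meets_m2q(ev(c(1, 3), c("outpatient", "inpatient_secondary"))))
  expect_false(meets_m2q(ev(1, "outpatient")))
  expect_false(meets_m2q(ev(c(1, 3), c("outpatient", "outpatient"),
                            c("confirmed", "suspected"))))
  expect_false(meets_m2q(ev(integer(), character())))
})

test_that("meets_m2q is order-invariant and idempotent under duplication", {
  base <- ev(c(1, 3, 2), c("outpatient", "inpatient_secondary", "outpatient"),
             c("confirmed", "confirmed", "suspected"))
  r <- meets_m2q(base)
  for (perm in list(c(3, 1, 2), c(2, 3, 1), 3:1)) {
    expect_equal(meets_m2q(base[perm, ]), r)
  }
  expect_equal(meets_m2q(rbind(base, base, base)), r)
  # duplicated identical events beyond the second never flip a negative
  one <- ev(2, "outpatient")
  expect_false(meets_m2q(rbind(one, one, one, one)))
})

test_that("prevalent cohort applies age, insurance and M2Q filters", {
  patients <- mk_patients(c("case", "gap", "old"),
                          birth_year = c(2010, 2010, 2002))
  coverage <- rbind(mk_cov(c("case", "old")),
                    mk_cov("gap", from = "2016-01-01", to = "2018-02-10"),
                    mk_cov("gap", from = "2018-03-01", to = "2019-12-31"))
  dxs <- list(idx("case", "M08.4"), idx("gap", "M08.4"), idx("old", "M08.4"))
  db <- mk_db(patients, coverage, dxs)
  coh <- prevalent_cohort(db, year = 2018)
  expect_equal(coh$case_ids, "case")
  # the gap patient is excluded from cases AND the denominator
  expect_equal(sum(coh$strata$n), 1L)
  expect_equal(sum(coh$strata$x), 1L)
  # strata counts sum to the case total
  expect_equal(sum(coh$strata$x), length(coh$case_ids))
})

test_that("incident cohort enforces prior-year insurance and the washout window", {
  mk <- function(extra_dx, from = "2016-01-01") {
    mk_db(mk_patients("p1"), mk_cov("p1", from = from),
          c(list(odx("p1", "M08.4", 2018, 1), odx("p1", "M08.4", 2018, 3)),
            extra_dx))
  }
  # clean history: incident
  db <- mk(list())
  expect_equal(incident_cohort(db, year = 2018)$case_ids, "p1")
  # qualifying code two quarters before the index quarter: washed out
  db <- mk(list(odx("p1", "M06.9", 2017, 2)))
  expect_equal(length(incident_cohort(db, year = 2018)$case_ids), 0L)
  # index quarter Q3: an event in Q2-2017 falls outside the 4-quarter window
  db <- mk_db(mk_patients("p1"), mk_cov("p1"),
              list(odx("p1", "M08.4", 2018, 3), odx("p1", "M08.4", 2018, 4),
                   odx("p1", "M06.9", 2017, 2)))
  expect_equal(incident_cohort(db, year = 2018)$case_ids, "p1")
  # no coverage in the prior year: excluded from cases and denominator
  db <- mk(list(), from = "2018-01-01")
  inc <- incident_cohort(db, year = 2018)
  expect_equal(length(inc$case_ids), 0L)
  expect_equal(sum(inc$strata$n), 0L)
})

test_that("incident cases are a subset of prevalent cases, washout monotone", {
  sim <- simulate_claims(test_config(stratum_rates = uniform_rates(800, 400)))
  prev <- prevalent_cohort(sim$db, year = 2018)
  inc4 <- incident_cohort(sim$db, year = 2018, washout_quarters = 4L)
  inc0 <- incident_cohort(sim$db, year = 2018, washout_quarters = 0L)
  expect_true(all(inc4$case_ids %in% prev$case_ids))
  # shrinking the washout never decreases the incident count
  expect_true(all(inc4$case_ids %in% inc0$case_ids))
  expect_gte(length(inc0$case_ids), length(inc4$case_ids))
})

test_that("polyJIA flag is the M2Q rule restricted to M08.0/M08.3", {
  expect_true(polyjia_flag(one_patient_db(idx("p1", "M08.0")), "p1", 2018))
  # confirmed outpatient + secondary inpatient in different quarters
  db <- one_patient_db(list(odx("p1", "M08.0", quarter = 1),
                            idx("p1", "M08.3", quarter = 4, main = FALSE)))
  expect_true(polyjia_flag(db, "p1", 2018))
  # codes outside the polyJIA set do not count
  db <- one_patient_db(list(odx("p1", "M08.4", quarter = 1),
                            odx("p1", "M08.4", quarter = 3)))
  expect_false(polyjia_flag(db, "p1", 2018))
  expect_true(meets_m2q(qualifying_events(db, "p1", jia_case_definition(), 2018)))
})

test_that("ILAR classification assigns unique categories and falls back to UA", {
  oligo <- one_patient_db(list(odx("p1", "M08.4", quarter = 1),
                               odx("p1", "M08.4", quarter = 3)))
  expect_equal(unname(classify_ilar(oligo, "p1", year = 2018)), "oligoJIA")
  # satisfying two category lists -> UA
  two <- one_patient_db(list(idx("p1", "M08.2"), idx("p1", "M45.0")))
  expect_equal(unname(classify_ilar(two, "p1", year = 2018)), "UA")
  # generic codes only -> case but no category -> UA
  generic <- one_patient_db(list(odx("p1", "M13.0", quarter = 1),
                                 odx("p1", "M13.0", quarter = 2)))
  expect_equal(unname(classify_ilar(generic, "p1", year = 2018)), "UA")
  # calling on a non-case errors
  noncase <- one_patient_db(odx("p1", "M08.4", quarter = 1))
  expect_error(classify_ilar(noncase, "p1", year = 2018), "non-case")
})

test_that("category counts partition every synthetic prevalent cohort", {
  sim <- simulate_claims(test_config(stratum_rates = uniform_rates(600, 150)))
  prev <- prevalent_cohort(sim$db, year = 2018)
  cats <- classify_ilar(sim$db, prev$case_ids, year = 2018)
  expect_equal(length(cats), length(prev$case_ids))
  expect_true(all(cats %in% c("sJIA", "oligoJIA", "RF- polyJIA", "RF+ polyJIA",
                              "jPsA", "ERA-JIA", "UA")))
  expect_equal(sum(table(cats)), length(prev$case_ids))
})
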