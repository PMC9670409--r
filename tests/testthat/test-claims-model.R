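# Domain model: validation, coverage merging, calendar utilities, round-trip IO.

test_that("claims_db validates schema and referential integrity", {
  p <- mk_patients("p1")
  expect_error(claims_db(p[, c("patient_id", "sex")], mk_cov("p1"), no_dx()),
               "missing column.*birth_year")
  expect_error(mk_db(p, diagnoses = odx("ghost", "M08.4")),
               "referential-integrity.*ghost")
  expect_error(mk_db(p, diagnoses = odx("p1", "M08.4", quarter = 5)),
               "quarter")
  expect_error(mk_db(p, diagnoses = odx("p1", "not-a-code")), "ICD")
  expect_error(mk_db(p, diagnoses = odx("p1", "M08.4", year = 2005)),
               "precedes birth year")
  expect_error(mk_db(mk_patients(c("p1", "p1"))), "duplicate")
  # minimal valid database round numbers
  db <- mk_db(p, mk_cov("p1"), odx("p1", "M08.4"))
  expect_s3_class(db, "claims_db")
  expect_equal(nrow(db$patients), 1L)
  expect_equal(nrow(db$coverage), 1L)
  expect_equal(nrow(db$diagnoses), 1L)
})

test_that("inpatient rows are forced to qualifier confirmed", {
  d <- idx("p1", "M08.4")
  d$qualifier <- "suspected"
  db <- mk_db(mk_patients("p1"), diagnoses = d)
  expect_equal(db$diagnoses$qualifier, "confirmed")
})

test_that("abutting and overlapping coverage intervals merge, order-invariantly", {
  rows <- data.frame(
    patient_id = "p1",
    start_date = as.Date(c("2018-01-01", "2018-07-01", "2018-05-01")),
    end_date = as.Date(c("2018-06-30", "2018-12-31", "2018-08-15")))
  merged <- merge_coverage(rows)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start_date, as.Date("2018-01-01"))
  expect_equal(merged$end_date, as.Date("2018-12-31"))
  # permutation invariance
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(merge_coverage(rows[perm, ]), merged)
  }
  # a one-day gap does not merge
  gap <- data.frame(patient_id = "p1",
                    start_date = as.Date(c("2018-01-01", "2018-07-02")),
                    end_date = as.Date(c("2018-06-30", "2018-12-31")))
  expect_equal(nrow(merge_coverage(gap)), 2L)
})

test_that("age_in_year is year minus birth year and monotone", {
  expect_equal(age_in_year(2010, 2018), 8L)
  expect_equal(age_in_year(2018, 2018), 0L)
  expect_equal(age_in_year(2003, 2018), 15L)
  expect_error(age_in_year(2010, 2005), "precedes")
  ages <- age_in_year(2007, 2010:2019)
  expect_true(all(diff(ages) == 1L))
})

test_that("assign_age_group maps the study bands and rejects other ages", {
  expect_equal(assign_age_group(c(2, 5, 6, 11, 12, 15)),
               c("2-5", "2-5", "6-11", "6-11", "12-15", "12-15"))
  expect_error(assign_age_group(1), "range")
  expect_error(assign_age_group(16), "range")
})

test_that("continuous insurance requires every day of the year, except after death", {
  full <- one_patient_db(from = "2018-01-01", to = "2018-12-31")
  expect_true(unname(continuously_insured(full, "p1", 2018)))
  late <- one_patient_db(from = "2018-02-01", to = "2018-12-31")
  expect_false(unname(continuously_insured(late, "p1", 2018)))
  # death in the observation year does not exclude
  died <- one_patient_db(from = "2018-01-01", to = "2018-05-10",
                         death_date = "2018-05-10")
  expect_true(unname(continuously_insured(died, "p1", 2018)))
  # but coverage stopping before death does
  short <- one_patient_db(from = "2018-01-01", to = "2018-05-01",
                          death_date = "2018-05-10")
  expect_false(unname(continuously_insured(short, "p1", 2018)))
  # dead before the year: not insured in it
  expect_false(unname(continuously_insured(died, "p1", 2019)))
  # absent coverage is simply FALSE
  none <- mk_db(mk_patients("p1"), mk_cov(character()))
  expect_false(unname(continuously_insured(none, "p1", 2018)))
})

test_that("icd prefix matching: a rule code matches itself and extensions", {
  expect_true(icd_match("M08.0", "M08.0"))
  expect_true(icd_match("M08.07", "M08.0"))
  expect_true(icd_match("M08.4", "M08"))
  expect_false(icd_match("M08.4", "M08.0"))
  expect_false(icd_match("M99.1", c("M05", "M08")))
  expect_equal(icd_normalize(" m08.4 "), "M084")
})

test_that("write/read round-trip is lossless", {
  dir <- withr::local_tempdir()
  sim <- simulate_claims(generator_config(
    n_patients = 100, years = 2017:2018, anchor_year = 2018, seed = 3,
    stratum_rates = within(default_stratum_rates_for_test(), {
      prevalence <- prevalence * 50
      incidence <- incidence * 50
    }),
    death_rate = 0.05, background_dx_rate = 1))
  db <- sim$db
  write_claims(db, dir)
  back <- read_claims(dir, label = db$label)
  expect_equal(back$patients, db$patients, ignore_attr = TRUE)
  expect_equal(back$coverage, db$coverage, ignore_attr = TRUE)
  ord <- function(d) {
    dd <- d$diagnoses[order(patient_id, icd_code, year, quarter, setting,
                            qualifier)]
    data.frame(dd)
  }
  expect_equal(ord(back), ord(db), ignore_attr = TRUE)
  # a set death_date survives the round trip
  expect_true(any(!is.na(back$patients$death_date)))
})

test_that("an empty database writes four header-only tables", {
  dir <- withr::local_tempdir()
  db <- mk_db(mk_patients(character()), mk_cov(character()))
  write_claims(db, dir)
  for (f in list.files(dir, pattern = "csv$", full.names = TRUE)) {
    expect_equal(nrow(data.table::fread(f)), 0L)
  }
  back <- read_claims(dir)
  expect_equal(nrow(back$patients), 0L)
})
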