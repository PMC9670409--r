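# Compact builders for hand-constructed claims fixtures. All fixtures are
# generated in code; no data files are read.

mk_patients <- function(ids, sex = "female", birth_year = 2010,
                        death_date = NA) {
  if (!length(ids)) {
    return(data.frame(patient_id = character(), sex = character(),
                      birth_year = integer(),
                      death_date = as.Date(character())))
  }
  data.frame(patient_id = ids, sex = sex, birth_year = birth_year,
             death_date = as.Date(death_date))
}

mk_cov <- function(ids, from = "2016-01-01", to = "2019-12-31") {
  if (!length(ids)) {
    return(data.frame(patient_id = character(),
                      start_date = as.Date(character()),
                      end_date = as.Date(character())))
  }
  data.frame(patient_id = ids, start_date = as.Date(from),
             end_date = as.Date(to))
}

# outpatient diagnosis rows
odx <- function(id, code, year = 2018, quarter = 1, qualifier = "confirmed") {
  data.frame(patient_id = id, icd_code = code, year = year, quarter = quarter,
             setting = "outpatient", qualifier = qualifier)
}

# inpatient diagnosis rows; date set to the first day of the quarter
idx <- function(id, code, year = 2018, quarter = 1, main = TRUE) {
  data.frame(patient_id = id, icd_code = code, year = year, quarter = quarter,
             setting = ifelse(main, "inpatient_main", "inpatient_secondary"),
             qualifier = "confirmed",
             date = as.Date(sprintf("%d-%02d-01", year, (quarter - 1) * 3 + 1)))
}

no_dx <- function() {
  data.frame(patient_id = character(), icd_code = character(),
             year = integer(), quarter = integer(), setting = character(),
             qualifier = character())
}

mk_db <- function(patients, coverage = mk_cov(patients$patient_id),
                  diagnoses = no_dx(), label = "test") {
  claims_db(patients, coverage, data.table::rbindlist(
    if (is.data.frame(diagnoses)) list(diagnoses) else diagnoses,
    fill = TRUE), label = label)
}

# one-patient database: handy wrapper used across tests
one_patient_db <- function(diagnoses = no_dx(), birth_year = 2010,
                           sex = "female", from = "2016-01-01",
                           to = "2019-12-31", death_date = NA) {
  mk_db(mk_patients("p1", sex, birth_year, death_date),
        mk_cov("p1", from, to), diagnoses)
}

# events table for meets_m2q checks
ev <- function(quarter, setting, qualifier = "confirmed") {
  if (!length(quarter)) {
    return(data.frame(quarter = integer(), setting = character(),
                      qualifier = character()))
  }
  data.frame(quarter = quarter, setting = setting, qualifier = qualifier)
}

# uniform stratum-rate table (per 100,000)
uniform_rates <- function(prevalence, incidence = prevalence / 4) {
  data.frame(age_group = rep(c("2-5", "6-11", "12-15"), each = 2),
             sex = rep(c("female", "male"), 3),
             prevalence = prevalence, incidence = incidence)
}

default_stratum_rates_for_test <- function() uniform_rates(150, 40)

# copy of a generator config with a different seed
within_seed <- function(cfg, seed) {
  cfg$seed <- as.integer(seed)
  cfg
}

# small generator config for fast tests; ... overrides the fast defaults
test_config <- function(...) {
  args <- utils::modifyList(
    list(n_patients = 5000, years = 2017:2018, anchor_year = 2018,
         background_dx_rate = 0.1, seed = 42),
    list(...))
  do.call(generator_config, args)
}
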