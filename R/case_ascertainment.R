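# Phenotyping algorithms: the M2Q case definition for overall JIA and
# polyJIA, prevalent/incident cohort construction with washout, and ILAR
# category classification with the undifferentiated-arthritis fallback.

#' Case definitions
#'
#' A case definition names an ICD-10-GM code-prefix set evaluated under the
#' M2Q rule: a patient-year is a case when it has at least one main inpatient
#' diagnosis with a matching code, or at least two matching diagnoses from
#' {secondary inpatient, confirmed outpatient} in two different quarters of
#' the calendar year.
#'
#' `jia_case_definition()` is the broad overall-JIA definition (codes M05,
#' M06, M07, M08, M09, M13, M45, L40.5 — adult rheumatoid-arthritis codes are
#' deliberately included because children occasionally receive them).
#' `polyjia_case_definition()` restricts the same rule to M08.0/M08.3
#' (RF-positive/RF-negative polyarthritis codes), the study's polyJIA proxy.
#'
#' @param name definition label.
#' @param code_prefixes character vector of ICD-10-GM code prefixes.
#' @return a `case_definition` object.
#' @export
case_definition <- function(name, code_prefixes) {
  code_prefixes <- unique(as.character(code_prefixes))
  if (!length(code_prefixes)) stop("empty code list", call. = FALSE)
  if (!all(icd_valid(code_prefixes))) {
    stop("syntactically invalid code prefix in definition", call. = FALSE)
  }
  structure(list(name = name, code_prefixes = code_prefixes),
            class = "case_definition")
}

#' @rdname case_definition
#' @export
jia_case_definition <- function() {
  case_definition("JIA", c("M05", "M06", "M07", "M08", "M09",
                           "M13", "M45", "L40.5"))
}

#' @rdname case_definition
#' @export
polyjia_case_definition <- function() {
  case_definition("polyJIA", c("M08.0", "M08.3"))
}

#' Default ILAR category code map
#'
#' Ordered mapping from the six named ILAR categories to ICD-10-GM code
#' prefixes. Undifferentiated arthritis (UA) is never mapped: it is the
#' fallback for cases matching no category or more than one. The paper's
#' supplementary code lists are not publicly included, so this map is a
#' reconstruction from standard ICD-10-GM juvenile-arthritis coding
#' conventions; every list is configurable, none is hard-coded logic.
#'
#' @return named list of code-prefix vectors.
#' @export
default_category_map <- function() {
  list(
    "sJIA"        = "M08.2",
    "oligoJIA"    = "M08.4",
    "RF- polyJIA" = "M08.3",
    "RF+ polyJIA" = "M08.0",
    "jPsA"        = c("L40.5", "M07.0", "M07.1", "M07.2", "M07.3"),
    "ERA-JIA"     = c("M08.1", "M45")
  )
}

ILAR_CATEGORIES <- c("sJIA", "oligoJIA", "RF- polyJIA", "RF+ polyJIA",
                     "jPsA", "ERA-JIA", "UA")

#' Diagnosis events qualifying under a case definition
#'
#' All diagnosis events of one patient in one calendar year whose code
#' matches the definition's prefixes, excluding outpatient events whose
#' qualifier is not `confirmed` (suspected/excluded/status-post outpatient
#' diagnoses never count).
#'
#' @param db a `claims_db`.
#' @param patient_id one patient identifier.
#' @param definition a `case_definition`.
#' @param year calendar year.
#' @return data.table with columns `quarter`, `setting`, `qualifier`,
#'   `icd_code`.
#' @export
qualifying_events <- function(db, patient_id, definition, year) {
  stopifnot(inherits(db, "claims_db"), inherits(definition, "case_definition"))
  pid <- patient_id
  yr <- year
  if (!pid %in% db$patients$patient_id) {
    stop(sprintf("unknown patient_id '%s'", pid), call. = FALSE)
  }
  dx <- db$diagnoses[patient_id == pid & year == yr]
  dx <- dx[icd_match(icd_code, definition$code_prefixes)]
  dx <- dx[setting != "outpatient" | qualifier == "confirmed"]
  dx[, .(quarter, setting, qualifier, icd_code)]
}

#' The M2Q rule on a patient-year's qualifying events
#'
#' TRUE when there is at least one main inpatient event, or at least two
#' events from {secondary inpatient, confirmed outpatient} falling in at
#' least two different quarters. Non-confirmed outpatient events are ignored
#' defensively, so the function can be applied to unfiltered event lists.
#' The result is invariant to event order and to duplicates beyond the
#' second.
#'
#' @param events data.frame with columns `quarter`, `setting`, `qualifier`
#'   (events of one patient-year).
#' @return logical scalar.
#' @export
meets_m2q <- function(events) {
  if (!nrow(events)) return(FALSE)
  if (any(events$setting == "inpatient_main")) return(TRUE)
  keep <- events$setting == "inpatient_secondary" |
    (events$setting == "outpatient" & events$qualifier == "confirmed")
  q <- events$quarter[keep]
  length(q) >= 2L && length(unique(q)) >= 2L
}

# Vectorized case ascertainment over every patient in the database.
# Returns the character vector of patient_ids whose year's qualifying
# events satisfy M2Q for the given definition.
m2q_case_ids <- function(db, definition, year) {
  yr <- year
  dx <- db$diagnoses[year == yr]
  dx <- dx[icd_match(icd_code, definition$code_prefixes)]
  dx <- dx[setting != "outpatient" | qualifier == "confirmed"]
  if (!nrow(dx)) return(character())
  main_ids <- unique(dx[setting == "inpatient_main", patient_id])
  two <- dx[setting != "inpatient_main",
            .(ok = .N >= 2L && uniqueN(quarter) >= 2L), by = patient_id]
  union(main_ids, two[ok == TRUE, patient_id])
}

#' polyJIA flag for one patient-year
#'
#' The M2Q rule restricted to codes M08.0/M08.3: one main inpatient
#' discharge diagnosis, or two confirmed outpatient diagnoses in different
#' quarters, with secondary inpatient diagnoses counted as confirmed
#' outpatient diagnoses.
#'
#' @inheritParams qualifying_events
#' @return logical scalar.
#' @export
polyjia_flag <- function(db, patient_id, year) {
  meets_m2q(qualifying_events(db, patient_id, polyjia_case_definition(), year))
}

# ---------------------------------------------------------------------------
# Cohorts

# Eligibility backbone shared by the cohort builders: age-eligible patients
# with the insurance condition, with their stratum labels.
eligible_patients <- function(db, year, age_range) {
  pat <- db$patients[year - birth_year >= age_range[1] &
                       year - birth_year <= age_range[2]]
  if (!nrow(pat)) return(pat[, .(patient_id, sex, birth_year)])
  ins <- continuously_insured(db, pat$patient_id, year)
  pat <- pat[ins]
  pat[, age := age_in_year(birth_year, year)]
  pat[, age_group := assign_age_group(age)]
  pat[, .(patient_id, sex, age_group)]
}

new_cohort_result <- function(year, case_ids, elig, measure) {
  strat <- CJ(age_group = AGE_GROUPS, sex = SEX_LEVELS)
  den <- elig[, .(n = .N), by = .(age_group, sex)]
  cas <- elig[patient_id %in% case_ids, .(x = .N), by = .(age_group, sex)]
  strat <- den[strat, on = c("age_group", "sex")]
  strat <- cas[strat, on = c("age_group", "sex")]
  strat[is.na(x), x := 0L]
  strat[is.na(n), n := 0L]
  setcolorder(strat, c("age_group", "sex", "x", "n"))
  strat <- strat[order(match(age_group, AGE_GROUPS), sex)]
  structure(list(year = year, measure = measure, case_ids = sort(case_ids),
                 strata = strat[]),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result %s %d>: %d cases / %d eligible\n",
              x$measure, x$year, length(x$case_ids), sum(x$strata$n)))
  print(x$strata)
  invisible(x)
}

#' Prevalent cohort for one observation year
#'
#' Cases are patients aged within `age_range` (age attained on Dec 31),
#' continuously insured throughout the year, satisfying the M2Q rule for the
#' definition. The stratum denominators count all age-eligible continuously
#' insured patients regardless of case status.
#'
#' @param db a `claims_db`.
#' @param definition a `case_definition` (default overall JIA).
#' @param year observation year.
#' @param age_range inclusive age bounds, default `c(2, 15)`.
#' @return a `cohort_result`: `year`, `measure`, sorted `case_ids`, and a
#'   `strata` table with per-(age group, sex) case counts `x` and
#'   denominators `n`.
#' @export
prevalent_cohort <- function(db, definition = jia_case_definition(), year,
                             age_range = c(2L, 15L)) {
  elig <- eligible_patients(db, year, age_range)
  cases <- intersect(m2q_case_ids(db, definition, year), elig$patient_id)
  new_cohort_result(year, cases, elig, "prevalence")
}

#' Incident cohort for one observation year
#'
#' The subset of the prevalent cohort that additionally has continuous
#' insurance in the year before the index year and no qualifying diagnosis
#' in the washout window: the `washout_quarters` (default 4) quarters
#' immediately preceding the index quarter, the earliest quarter of the
#' index year containing a qualifying event. The washout screens the full
#' `washout_definition` code set (default overall JIA, regardless of the
#' cohort's own definition) in any setting; outpatient washout diagnoses
#' must be confirmed unless `washout_any_qualifier = TRUE`. Denominators are
#' restricted to patients continuously insured in both years.
#'
#' @inheritParams prevalent_cohort
#' @param washout_quarters length of the diagnosis-free look-back window.
#' @param washout_definition code set screened during washout.
#' @param washout_any_qualifier if TRUE, any outpatient qualifier counts as
#'   a documented diagnosis during washout.
#' @return a `cohort_result` with measure `"incidence"`.
#' @export
incident_cohort <- function(db, definition = jia_case_definition(), year,
                            age_range = c(2L, 15L), washout_quarters = 4L,
                            washout_definition = jia_case_definition(),
                            washout_any_qualifier = FALSE) {
  elig <- eligible_patients(db, year, age_range)
  if (nrow(elig)) {
    prior <- continuously_insured(db, elig$patient_id, year - 1L)
    elig <- elig[prior]
  }
  cases <- intersect(m2q_case_ids(db, definition, year), elig$patient_id)
  if (length(cases)) {
    yr <- year
    # index quarter: earliest quarter with a qualifying event of the
    # cohort's own definition in the index year
    dx <- db$diagnoses[patient_id %in% cases & year == yr]
    dx <- dx[icd_match(icd_code, definition$code_prefixes)]
    dx <- dx[setting != "outpatient" | qualifier == "confirmed"]
    idx <- dx[, .(index_q = min(quarter)), by = patient_id]
    # washout: any documented diagnosis from the washout code set in the
    # window of absolute quarters [index - washout_quarters, index - 1]
    wdx <- db$diagnoses[patient_id %in% cases & year %in% c(yr - 1L, yr)]
    wdx <- wdx[icd_match(icd_code, washout_definition$code_prefixes)]
    if (!washout_any_qualifier) {
      wdx <- wdx[setting != "outpatient" | qualifier == "confirmed"]
    }
    wdx[, absq := year * 4L + quarter]
    idx[, absq0 := yr * 4L + index_q]
    hits <- wdx[idx, on = "patient_id"][
      absq >= absq0 - washout_quarters & absq <= absq0 - 1L,
      unique(patient_id)]
    cases <- setdiff(cases, hits)
  }
  new_cohort_result(year, cases, elig, "incidence")
}

# ---------------------------------------------------------------------------
# ILAR classification

#' Classify cases into ILAR categories by ICD-10-GM code
#'
#' Evaluates the case rule (M2Q) separately on each category's code list for
#' the given year. A case satisfying exactly one category is assigned it;
#' cases satisfying none (e.g. ascertained only via generic codes such as
#' M13) or more than one fall back to `"UA"` (undifferentiated arthritis),
#' so the seven categories always partition the cohort.
#'
#' @param db a `claims_db`.
#' @param patient_ids identifiers of ascertained cases for `year`.
#' @param category_map named list of code-prefix vectors, see
#'   [default_category_map()].
#' @param year observation year.
#' @param verify_cases check that every patient is an overall-JIA M2Q case
#'   for the year and error otherwise (contract guard, default TRUE).
#' @return named character vector: patient_id -> category.
#' @export
classify_ilar <- function(db, patient_ids, category_map = default_category_map(),
                          year, verify_cases = TRUE) {
  stopifnot(inherits(db, "claims_db"))
  if (!length(patient_ids)) return(setNames(character(), character()))
  if (verify_cases) {
    ok <- m2q_case_ids(db, jia_case_definition(), year)
    bad <- setdiff(patient_ids, ok)
    if (length(bad)) {
      stop(sprintf("classify_ilar called on non-case patient(s): %s",
                   paste(head(bad, 5), collapse = ", ")), call. = FALSE)
    }
  }
  sat <- matrix(FALSE, nrow = length(patient_ids), ncol = length(category_map),
                dimnames = list(patient_ids, names(category_map)))
  for (cat_name in names(category_map)) {
    def <- case_definition(cat_name, category_map[[cat_name]])
    ids <- m2q_case_ids(db, def, year)
    sat[, cat_name] <- patient_ids %in% ids
  }
  n_sat <- rowSums(sat)
  res <- rep("UA", length(patient_ids))
  one <- which(n_sat == 1)
  if (length(one)) {
    res[one] <- colnames(sat)[apply(sat[one, , drop = FALSE], 1, which)]
  }
  setNames(res, patient_ids)
}
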