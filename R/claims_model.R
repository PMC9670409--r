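# Domain model for SHI-style claims: patients, coverage intervals, diagnosis
# records, plus the calendar and coverage utilities every downstream stage
# shares. Diagnoses are stored in one unified table; outpatient records are
# located by (year, quarter) only, inpatient records carry a discharge date
# from which year/quarter are derived.

SEX_LEVELS       <- c("male", "female")
SETTING_LEVELS   <- c("inpatient_main", "inpatient_secondary", "outpatient")
QUALIFIER_LEVELS <- c("confirmed", "suspected", "excluded", "status_post")
AGE_GROUPS       <- c("2-5", "6-11", "12-15")

#' Normalize ICD-10-GM codes for prefix comparison
#'
#' Upper-cases and strips the dot, so `"m08.4"` becomes `"M084"`. All code
#' matching in the package is prefix matching on this normalized form: a rule
#' code `M08.0` matches `M08.0` and any extension, a three-character rule
#' code `M08` matches all of `M08.x`.
#'
#' @param x character vector of ICD-10-GM codes or code prefixes.
#' @return character vector of normalized codes.
#' @export
icd_normalize <- function(x) {
  gsub(".", "", toupper(trimws(as.character(x))), fixed = TRUE)
}

#' @rdname icd_normalize
#' @param codes character vector of diagnosis codes.
#' @param prefixes character vector of rule code prefixes.
#' @return `icd_match()`: logical vector, `TRUE` where a code matches at
#'   least one prefix.
#' @export
icd_match <- function(codes, prefixes) {
  nc <- icd_normalize(codes)
  out <- rep(FALSE, length(nc))
  for (p in icd_normalize(prefixes)) {
    out <- out | startsWith(nc, p)
  }
  out
}

icd_valid <- function(x) {
  grepl("^[A-Z][0-9]{2}[0-9A-Z]{0,3}$", icd_normalize(x))
}

# ---------------------------------------------------------------------------
# Construction and validation

#' Assemble and validate a claims database
#'
#' Bundles the three claims tables into a validated `claims_db` object.
#' Overlapping or abutting coverage intervals per patient are merged on
#' construction; rows violating the schema or referential integrity abort
#' with row-level diagnostics.
#'
#' @param patients data.frame with columns `patient_id`, `sex`
#'   (`"male"`/`"female"`), `birth_year`, and optionally `death_date`
#'   (`Date` or ISO-8601 string, `NA` if alive).
#' @param coverage data.frame with columns `patient_id`, `start_date`,
#'   `end_date` (inclusive calendar dates).
#' @param diagnoses data.frame with columns `patient_id`, `icd_code`,
#'   `year`, `quarter` (1-4), `setting` (one of `inpatient_main`,
#'   `inpatient_secondary`, `outpatient`), `qualifier` (one of `confirmed`,
#'   `suspected`, `excluded`, `status_post`; inpatient rows are forced to
#'   `confirmed`), and optionally `date` (inpatient discharge date).
#' @param label free-text sample name, e.g. the insurer sample the database
#'   emulates.
#' @return an object of class `claims_db`: a list with elements `patients`,
#'   `coverage`, `diagnoses` (data.tables) and `label`.
#' @export
claims_db <- function(patients, coverage, diagnoses, label = "sample") {
  patients <- as.data.table(patients)
  coverage <- as.data.table(coverage)
  diagnoses <- as.data.table(diagnoses)

  need <- function(dt, cols, tab) {
    miss <- setdiff(cols, names(dt))
    if (length(miss)) {
      stop(sprintf("schema error in '%s' table: missing column(s) %s",
                   tab, paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  need(patients, c("patient_id", "sex", "birth_year"), "patients")
  need(coverage, c("patient_id", "start_date", "end_date"), "coverage")
  need(diagnoses, c("patient_id", "icd_code", "year", "quarter",
                    "setting", "qualifier"), "diagnoses")

  patients[, patient_id := as.character(patient_id)]
  patients[, birth_year := as.integer(birth_year)]
  if (!"death_date" %in% names(patients)) patients[, death_date := as.Date(NA)]
  patients[, death_date := as.Date(death_date)]
  if (anyDuplicated(patients$patient_id)) {
    dup <- unique(patients$patient_id[duplicated(patients$patient_id)])
    stop(sprintf("duplicate patient_id(s): %s",
                 paste(head(dup, 5), collapse = ", ")), call. = FALSE)
  }
  if (!all(patients$sex %in% SEX_LEVELS)) {
    stop("patients$sex must be 'male' or 'female'", call. = FALSE)
  }

  coverage[, patient_id := as.character(patient_id)]
  coverage[, start_date := as.Date(start_date)]
  coverage[, end_date := as.Date(end_date)]
  if (any(coverage$start_date > coverage$end_date)) {
    stop("coverage intervals with start_date > end_date", call. = FALSE)
  }

  diagnoses[, patient_id := as.character(patient_id)]
  diagnoses[, icd_code := as.character(icd_code)]
  diagnoses[, year := as.integer(year)]
  diagnoses[, quarter := as.integer(quarter)]
  if (!"date" %in% names(diagnoses)) diagnoses[, date := as.Date(NA)]
  diagnoses[, date := as.Date(date)]
  bad <- which(!diagnoses$quarter %in% 1:4)
  if (length(bad)) {
    stop(sprintf("diagnosis rows with quarter outside 1..4: rows %s",
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  bad <- which(!icd_valid(diagnoses$icd_code))
  if (length(bad)) {
    stop(sprintf("malformed ICD-10-GM code(s): %s",
                 paste(head(unique(diagnoses$icd_code[bad]), 5),
                       collapse = ", ")), call. = FALSE)
  }
  if (!all(diagnoses$setting %in% SETTING_LEVELS)) {
    stop("diagnoses$setting must be inpatient_main, inpatient_secondary or outpatient",
         call. = FALSE)
  }
  if (!all(diagnoses$qualifier %in% QUALIFIER_LEVELS)) {
    stop("diagnoses$qualifier outside {confirmed, suspected, excluded, status_post}",
         call. = FALSE)
  }
  # inpatient diagnoses are confirmed by convention
  diagnoses[setting != "outpatient", qualifier := "confirmed"]

  # referential integrity
  ids <- patients$patient_id
  dangling <- setdiff(unique(c(coverage$patient_id, diagnoses$patient_id)), ids)
  if (length(dangling)) {
    stop(sprintf("referential-integrity error: unknown patient_id(s) %s",
                 paste(head(dangling, 5), collapse = ", ")), call. = FALSE)
  }

  # birth year cannot postdate a diagnosis year
  chk <- diagnoses[patients, on = "patient_id",
                   nomatch = NULL][year < birth_year]
  if (nrow(chk)) {
    stop(sprintf("diagnosis year precedes birth year for patient(s) %s",
                 paste(head(unique(chk$patient_id), 5), collapse = ", ")),
         call. = FALSE)
  }

  coverage <- merge_coverage(coverage)
  setkey(coverage, patient_id, start_date)
  setkey(diagnoses, patient_id, year, quarter)

  structure(
    list(patients = patients, coverage = coverage, diagnoses = diagnoses,
         label = label),
    class = "claims_db"
  )
}

#' @export
print.claims_db <- function(x, ...) {
  cat(sprintf("<claims_db '%s'>: %d patients, %d coverage intervals, %d diagnoses\n",
              x$label, nrow(x$patients), nrow(x$coverage), nrow(x$diagnoses)))
  invisible(x)
}

#' Merge overlapping or abutting coverage intervals
#'
#' Inclusive daily intervals per patient are merged whenever one starts on or
#' before the day after another ends, so `2018-01-01..2018-06-30` and
#' `2018-07-01..2018-12-31` collapse to one interval spanning the year. The
#' result is independent of input row order.
#'
#' @param coverage data.frame/data.table with `patient_id`, `start_date`,
#'   `end_date`.
#' @return data.table of disjoint, non-abutting intervals.
#' @export
merge_coverage <- function(coverage) {
  cov <- as.data.table(coverage)
  if (!nrow(cov)) return(cov)
  cov <- cov[order(patient_id, start_date, end_date)]
  # vectorized per-patient running max of interval ends: offset each
  # patient's days so a global cummax never bleeds across patients
  k <- rleid(cov$patient_id)
  s <- as.numeric(cov$start_date)
  e <- as.numeric(cov$end_date)
  span <- max(e) - min(s) + 2
  off <- k * span
  run_end <- cummax(e + off) - off
  m <- nrow(cov)
  new_grp <- c(TRUE, k[-1] != k[-m] | s[-1] > run_end[-m] + 1)
  cov[, grp := cumsum(new_grp)]
  out <- cov[, .(patient_id = patient_id[1L], start_date = min(start_date),
                 end_date = max(end_date)), by = grp]
  out[, grp := NULL]
  out[]
}

# ---------------------------------------------------------------------------
# Readers / writers: four delimited UTF-8 tables (see README)

claims_files <- c(patients = "patients.csv", coverage = "coverage.csv",
                  outpatient = "outpatient_dx.csv", inpatient = "inpatient_dx.csv")

#' Read a claims database from its four delimited tables
#'
#' Expects `patients.csv` (`patient_id,sex,birth_year,death_date`),
#' `coverage.csv` (`patient_id,start_date,end_date`), `outpatient_dx.csv`
#' (`patient_id,icd_code,year,quarter,qualifier`) and `inpatient_dx.csv`
#' (`patient_id,icd_code,date,position` with position `main`/`secondary`).
#' Dates are ISO-8601. The inpatient quarter is derived from the discharge
#' date; validation and coverage merging happen via [claims_db()].
#'
#' @param dir directory containing the four tables.
#' @param label sample name attached to the database.
#' @return a `claims_db`.
#' @export
read_claims <- function(dir, label = basename(dir)) {
  paths <- file.path(dir, claims_files)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop(sprintf("claims table(s) not found: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  pat <- fread(paths[[1]], colClasses = list(character = "patient_id"))
  cov <- fread(paths[[2]], colClasses = list(character = "patient_id"))
  out <- fread(paths[[3]], colClasses = list(character = c("patient_id", "icd_code")))
  inp <- fread(paths[[4]], colClasses = list(character = c("patient_id", "icd_code")))

  need <- function(dt, cols, tab) {
    miss <- setdiff(cols, names(dt))
    if (length(miss)) {
      stop(sprintf("schema error in '%s' table: missing column(s) %s",
                   tab, paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  need(out, c("patient_id", "icd_code", "year", "quarter", "qualifier"),
       "outpatient_dx")
  need(inp, c("patient_id", "icd_code", "date", "position"), "inpatient_dx")

  if (nrow(pat) && "death_date" %in% names(pat)) {
    pat[, death_date := as.Date(as.character(death_date))]
  }
  out_dx <- if (nrow(out)) {
    data.table(patient_id = out$patient_id, icd_code = out$icd_code,
               year = as.integer(out$year), quarter = as.integer(out$quarter),
               setting = "outpatient", qualifier = as.character(out$qualifier),
               date = as.Date(NA))
  } else empty_dx()
  inp_dx <- if (nrow(inp)) {
    if (!all(inp$position %in% c("main", "secondary"))) {
      stop("inpatient_dx$position must be 'main' or 'secondary'", call. = FALSE)
    }
    d <- as.Date(as.character(inp$date))
    data.table(patient_id = inp$patient_id, icd_code = inp$icd_code,
               year = as.integer(format(d, "%Y")),
               quarter = (as.integer(format(d, "%m")) - 1L) %/% 3L + 1L,
               setting = fifelse(inp$position == "main",
                                 "inpatient_main", "inpatient_secondary"),
               qualifier = "confirmed", date = d)
  } else empty_dx()

  claims_db(pat, cov, rbind(out_dx, inp_dx), label = label)
}

empty_dx <- function() {
  data.table(patient_id = character(), icd_code = character(),
             year = integer(), quarter = integer(), setting = character(),
             qualifier = character(), date = as.Date(character()))
}

#' Write a claims database as its four delimited tables
#'
#' Inverse of [read_claims()]: `read_claims(write_claims(db, dir))`
#' reproduces the database record for record (coverage already merged).
#'
#' @param db a `claims_db`.
#' @param dir destination directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_claims <- function(db, dir) {
  stopifnot(inherits(db, "claims_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pat <- copy(db$patients)
  pat[, death_date := format(death_date, "%Y-%m-%d")]
  fwrite(pat, file.path(dir, claims_files[["patients"]]))
  fwrite(db$coverage, file.path(dir, claims_files[["coverage"]]))
  out <- db$diagnoses[setting == "outpatient",
                      .(patient_id, icd_code, year, quarter, qualifier)]
  fwrite(out, file.path(dir, claims_files[["outpatient"]]))
  inp <- db$diagnoses[setting != "outpatient"]
  if (nrow(inp) && anyNA(inp$date)) {
    stop("inpatient diagnosis rows without a date cannot be written", call. = FALSE)
  }
  inp <- inp[, .(patient_id, icd_code, date,
                 position = fifelse(setting == "inpatient_main",
                                    "main", "secondary"))]
  fwrite(inp, file.path(dir, claims_files[["inpatient"]]))
  invisible(dir)
}

# ---------------------------------------------------------------------------
# Calendar / coverage utilities

#' Age attained in a calendar year
#'
#' Age on December 31 of the observation year, i.e. `year - birth_year`.
#' This is the reference date used throughout for age eligibility and
#' stratification; it is deterministic from the birth year alone.
#'
#' @param birth_year integer vector of birth years.
#' @param year observation year (scalar or vector).
#' @return integer ages.
#' @export
age_in_year <- function(birth_year, year) {
  if (any(year < birth_year)) {
    stop("observation year precedes birth year", call. = FALSE)
  }
  as.integer(year - birth_year)
}

#' Assign the study age group
#'
#' Maps ages 2-15 to the three study bands `"2-5"`, `"6-11"`, `"12-15"`.
#'
#' @param age integer vector, each in 2..15.
#' @return character vector of age-group labels.
#' @export
assign_age_group <- function(age) {
  if (any(age < 2L | age > 15L)) {
    stop("age outside the study range 2-15", call. = FALSE)
  }
  AGE_GROUPS[findInterval(age, c(2L, 6L, 12L))]
}

#' Continuous insurance throughout a calendar year
#'
#' A patient counts as continuously insured in a year when the merged
#' coverage contains every day of that year, or covers January 1 through the
#' patient's death date when the death falls inside the year (death in the
#' observation year does not exclude). A patient who died before the year
#' is not insured in it.
#'
#' @param db a `claims_db`.
#' @param patient_ids patient identifiers to evaluate (default: all).
#' @param year calendar year.
#' @return named logical vector along `patient_ids`.
#' @export
continuously_insured <- function(db, patient_ids = db$patients$patient_id, year) {
  stopifnot(inherits(db, "claims_db"))
  jan1 <- as.Date(sprintf("%d-01-01", year))
  dec31 <- as.Date(sprintf("%d-12-31", year))
  pat <- db$patients[.(patient_ids), on = "patient_id",
                     .(patient_id, death_date)]
  # required coverage end: Dec 31, or the death date when death is in-year
  pat[, target_end := dec31]
  pat[!is.na(death_date) & death_date >= jan1 & death_date <= dec31,
      target_end := death_date]
  dead_before <- !is.na(pat$death_date) & pat$death_date < jan1

  cov <- db$coverage[.(patient_ids), on = "patient_id", nomatch = NULL]
  ok_ids <- unique(cov[pat, on = "patient_id"][
    start_date <= jan1 & end_date >= target_end, patient_id])
  res <- patient_ids %in% ok_ids & !dead_before
  names(res) <- patient_ids
  res
}
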