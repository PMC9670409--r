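# Comorbidity panel frequencies and top-k most common diagnoses among
# ascertained cases, reported under the small-cell (n >= 5) suppression rule
# of German claims-data protection. Suppression happens at output time only,
# so internal invariant checks always see exact counts.

#' Default comorbidity panel
#'
#' Ordered mapping of the 25 pre-defined comorbidities to ICD-10-GM code
#' prefixes. The study's exact supplementary code lists are not publicly
#' available; these lists are reconstructions from standard ICD-10-GM coding
#' and are fully configurable.
#'
#' @return named list of ICD-10-GM prefix vectors.
#' @export
default_comorbidity_panel <- function() {
  list(
    "allergic rhinitis"                 = c("J30.1", "J30.2", "J30.3", "J30.4"),
    "predominantly allergic asthma"     = "J45.0",
    "amyloidosis"                       = "E85",
    "anaemia"                           = c("D50", "D51", "D52", "D53",
                                            "D55", "D56", "D57", "D58",
                                            "D59", "D60", "D61", "D62",
                                            "D63", "D64"),
    "anxiety disorders"                 = c("F40", "F41"),
    "primary hypertension"              = "I10",
    "atopic dermatitis"                 = "L20",
    "persistent somatoform pain disorder" = "F45.4",
    "ulcerative colitis"                = "K51",
    "depression"                        = c("F32", "F33"),
    "diabetes mellitus"                 = c("E10", "E11", "E12", "E13", "E14"),
    "iron deficiency"                   = "E61.1",
    "fatigue"                           = "R53",
    "fibromyalgia"                      = "M79.7",
    "autoimmune thyroiditis"            = "E06.3",
    "thyrotoxicosis"                    = "E05",
    "hypothyroidism"                    = "E03",
    "lack of expected normal physiological development" = "R62",
    "Crohn's disease"                   = "K50",
    "migraine"                          = "G43",
    "chronic kidney disease"            = "N18",
    "osteoporosis"                      = c("M80", "M81"),
    "psoriasis"                         = "L40",
    "sicca syndrome"                    = "M35.0",
    "uveitis"                           = c("H20", "H30")
  )
}

#' Small-cell suppression of a count column
#'
#' Counts in `1..threshold-1` are replaced by the sentinel `"<5"` (or
#' `"<threshold"`) and the associated rate is blanked; zero and counts of at
#' least the threshold pass through. Used by every table writer so no
#' published output contains a patient-level count between 1 and 4.
#'
#' @param n integer vector of patient-level counts.
#' @param threshold minimum reportable count, default 5.
#' @return character vector: the count as text, or the sentinel.
#' @export
suppress_small_counts <- function(n, threshold = 5L) {
  fifelse(n > 0L & n < threshold, sprintf("<%d", threshold),
          as.character(n))
}

# qualifying comorbidity/diagnosis events: confirmed outpatient or any
# inpatient diagnosis in the year
reportable_dx <- function(db, case_ids, year) {
  yr <- year
  dx <- db$diagnoses[patient_id %in% case_ids & year == yr]
  dx[setting != "outpatient" | qualifier == "confirmed"]
}

#' Comorbidity frequencies among ascertained cases
#'
#' For each panel condition, the number of distinct case patients with at
#' least one qualifying diagnosis (confirmed outpatient or any inpatient) in
#' the year, and the percentage of the case population. Ascertainment by a
#' single diagnosis is the default (the weakest assumption); set
#' `require_m2q = TRUE` to demand the M2Q rule instead. Counts are exact in
#' the `n` column; `n_reported` carries the suppressed form and `rate_pct`
#' is `NA` where suppressed.
#'
#' @param db a `claims_db`.
#' @param case_ids case patient identifiers (non-empty).
#' @param panel named list of ICD prefix vectors, see
#'   [default_comorbidity_panel()].
#' @param year observation year.
#' @param threshold suppression threshold, default 5.
#' @param require_m2q ascertain comorbidities with the M2Q rule rather than
#'   a single diagnosis.
#' @return data.table: `name`, `n`, `n_reported`, `rate_pct`.
#' @export
comorbidity_rates <- function(db, case_ids, panel = default_comorbidity_panel(),
                              year, threshold = 5L, require_m2q = FALSE) {
  if (!length(case_ids)) stop("empty case set", call. = FALSE)
  dx <- reportable_dx(db, case_ids, year)
  res <- rbindlist(lapply(names(panel), function(nm) {
    if (require_m2q) {
      def <- case_definition(nm, panel[[nm]])
      ids <- intersect(m2q_case_ids(db, def, year), case_ids)
      cnt <- length(ids)
    } else {
      cnt <- uniqueN(dx[icd_match(icd_code, panel[[nm]]), patient_id])
    }
    data.table(name = nm, n = cnt)
  }))
  res[, n_reported := suppress_small_counts(n, threshold)]
  res[, rate_pct := fifelse(n > 0L & n < threshold, NA_real_,
                            100 * n / length(case_ids))]
  res[]
}

#' Top-k most common diagnosis blocks among cases
#'
#' Distinct-patient counts per three-character ICD-10-GM block (configurable
#' granularity) over the cases' confirmed-outpatient/inpatient diagnoses in
#' the year, sorted by descending count with lexicographic tie-break,
#' truncated to `k`, suppression applied at output.
#'
#' @inheritParams comorbidity_rates
#' @param k number of blocks to report.
#' @param exclusions ICD prefixes to drop before ranking (e.g. the JIA
#'   definition codes themselves).
#' @param block_chars grouping granularity in normalized code characters.
#' @return data.table: `code`, `n`, `n_reported`, `rate_pct`, ordered.
#' @export
top_k_diagnoses <- function(db, case_ids, year, k = 10L,
                            exclusions = character(), threshold = 5L,
                            block_chars = 3L) {
  stopifnot(k >= 1L)
  if (!length(case_ids)) stop("empty case set", call. = FALSE)
  dx <- reportable_dx(db, case_ids, year)
  if (length(exclusions)) dx <- dx[!icd_match(icd_code, exclusions)]
  if (!nrow(dx)) {
    return(data.table(code = character(), n = integer(),
                      n_reported = character(), rate_pct = numeric()))
  }
  dx[, block := substr(icd_normalize(icd_code), 1L, block_chars)]
  res <- dx[, .(n = uniqueN(patient_id)), by = .(code = block)]
  res <- res[order(-n, code)]
  res <- head(res, k)
  res[, n_reported := suppress_small_counts(n, threshold)]
  res[, rate_pct := fifelse(n > 0L & n < threshold, NA_real_,
                            100 * n / length(case_ids))]
  res[]
}

#' Audit tables for small-cell violations
#'
#' Scans count-bearing columns of emitted tables for integer values in
#' `1..threshold-1`. Used as a global publication audit: every table the
#' pipeline writes must pass.
#'
#' @param tab data.frame to audit.
#' @param count_cols columns holding patient-level counts (character columns
#'   are parsed; sentinels pass).
#' @param threshold suppression threshold.
#' @return TRUE if clean, FALSE otherwise.
#' @export
passes_suppression_audit <- function(tab, count_cols, threshold = 5L) {
  for (col in intersect(count_cols, names(tab))) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    v <- v[!is.na(v)]
    if (any(v >= 1 & v < threshold)) return(FALSE)
  }
  TRUE
}
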