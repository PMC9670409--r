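# Synthetic SHI-style claims generator with known ground truth. Emulates the
# features the case-ascertainment pipeline is sensitive to: stratum-specific
# true prevalence/incidence, per-case diagnosis-event streams spread over
# quarters and care settings, non-case noise diagnoses (single-quarter or
# non-confirmed, so they fail M2Q by construction), continuous vs.
# interrupted coverage, and death during the observation year.

JIA_NOISE_CODES <- c("M05.8", "M06.9", "M07.2", "M08.0", "M08.4", "M08.9",
                     "M09.0", "M13.8", "M45.0", "L40.5")
GENERIC_JIA_CODES <- c("M05.8", "M06.9", "M09.0", "M13.0", "M08.8", "M08.9")
BACKGROUND_CODES <- c("J06.9", "H52.0", "R10.4", "B34.9", "Z00.1", "Z27.8",
                      "H50.9", "Q66.8", "J03.9", "S93.4")

default_stratum_rates <- function() {
  # per-100,000 true prevalence: the printed stratified 2018 rates of the
  # smaller sample; the 6-11 band (not printed) interpolated between its
  # neighbours. Incidence scaled to roughly a quarter of prevalence, the
  # overall ratio of the two headline 2018 estimates.
  prev <- data.table(
    age_group = rep(AGE_GROUPS, each = 2L),
    sex = rep(c("female", "male"), 3L),
    prevalence = c(87.39, 40.38, 160, 95, 290.61, 170.31))
  prev[, incidence := round(prevalence * 0.26, 2)]
  prev[]
}

default_category_mix <- function() {
  c("sJIA" = 0.05, "oligoJIA" = 0.40, "RF- polyJIA" = 0.18,
    "RF+ polyJIA" = 0.025, "jPsA" = 0.015, "ERA-JIA" = 0.05, "UA" = 0.28)
}

default_comorbidity_prevalence <- function() {
  panel <- names(default_comorbidity_panel())
  p <- setNames(rep(0.01, length(panel)), panel)
  p[c("atopic dermatitis", "allergic rhinitis", "uveitis")] <- c(0.147, 0.12, 0.11)
  p[c("predominantly allergic asthma", "psoriasis")] <- 0.05
  p[c("depression", "migraine")] <- 0.04
  p[c("anaemia", "fatigue", "anxiety disorders")] <- 0.03
  p[c("ulcerative colitis", "diabetes mellitus", "thyrotoxicosis",
      "chronic kidney disease", "osteoporosis", "amyloidosis")] <- 0.002
  p
}

#' Configuration of the synthetic claims generator
#'
#' Defaults emulate the study conditions: two observation spans of years
#' 2013-2019 with ages 2-15, stratum prevalences matching the printed 2018
#' stratified rates, incidence at about a quarter of prevalence, and an
#' ILAR category mix proportional to the printed category rates. All
#' probabilities are per patient-year unless stated.
#'
#' @param n_patients number of patients to simulate.
#' @param years inclusive span of calendar years covered by the data.
#' @param anchor_year year at which stratum prevalence/incidence are
#'   calibrated (ages are drawn uniform 2-15 at this year); defaults to the
#'   penultimate data year so a washout year precedes it.
#' @param stratum_rates data.frame with `age_group`, `sex`, `prevalence`,
#'   `incidence` (per 100,000 true rates at the anchor year).
#' @param category_mix named probability vector over the seven ILAR
#'   categories (must sum to 1; the UA share is generated via generic codes
#'   mapping to no single category).
#' @param events_per_case_mean mean diagnosis events per case-year (shifted
#'   Poisson, at least one event).
#' @param inpatient_fraction probability a case event is inpatient.
#' @param main_fraction probability an inpatient event is a main diagnosis.
#' @param noise_dx_rate expected JIA-code noise events per non-case
#'   patient-year; noise events land in a single quarter or carry
#'   non-confirmed qualifiers, so they fail M2Q.
#' @param nonconfirmed_fraction probability an outpatient case event carries
#'   a non-confirmed qualifier.
#' @param generic_code_prob probability a case event uses a generic JIA code
#'   (e.g. M13) mapping to no single ILAR category, exercising the UA
#'   fallback.
#' @param coverage_gap_prob probability a patient-year has a coverage gap
#'   (March uncovered).
#' @param background_dx_rate expected non-JIA background diagnoses per
#'   patient-year (feeds the top-k diagnosis ranking).
#' @param comorbidity_prevalence named probability vector (per case-year)
#'   over the comorbidity panel names.
#' @param death_rate probability a patient dies during the data span.
#' @param label sample label.
#' @param seed integer seed; per-stage substreams are derived from it.
#' @return validated `generator_config` list.
#' @export
generator_config <- function(n_patients = 200000L,
                             years = 2013:2019,
                             anchor_year = max(years) - 1L,
                             stratum_rates = default_stratum_rates(),
                             category_mix = default_category_mix(),
                             events_per_case_mean = 5,
                             inpatient_fraction = 0.15,
                             main_fraction = 0.4,
                             noise_dx_rate = 0.02,
                             nonconfirmed_fraction = 0.1,
                             generic_code_prob = 0.1,
                             coverage_gap_prob = 0.05,
                             background_dx_rate = 0.5,
                             comorbidity_prevalence = default_comorbidity_prevalence(),
                             death_rate = 2e-4,
                             label = "S1",
                             seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), years = as.integer(years),
              anchor_year = as.integer(anchor_year),
              stratum_rates = as.data.table(stratum_rates),
              category_mix = category_mix,
              events_per_case_mean = events_per_case_mean,
              inpatient_fraction = inpatient_fraction,
              main_fraction = main_fraction,
              noise_dx_rate = noise_dx_rate,
              nonconfirmed_fraction = nonconfirmed_fraction,
              generic_code_prob = generic_code_prob,
              coverage_gap_prob = coverage_gap_prob,
              background_dx_rate = background_dx_rate,
              comorbidity_prevalence = comorbidity_prevalence,
              death_rate = death_rate, label = label, seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  probs <- c(cfg$inpatient_fraction, cfg$main_fraction,
             cfg$nonconfirmed_fraction, cfg$generic_code_prob,
             cfg$coverage_gap_prob, cfg$death_rate, cfg$comorbidity_prevalence)
  if (any(probs < 0 | probs > 1)) {
    stop("config error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(cfg$category_mix) - 1) > 1e-9) {
    stop("config error: category_mix must sum to 1", call. = FALSE)
  }
  if (!all(names(cfg$category_mix) %in% ILAR_CATEGORIES)) {
    stop("config error: unknown ILAR category in category_mix", call. = FALSE)
  }
  sr <- cfg$stratum_rates
  miss <- setdiff(c("age_group", "sex", "prevalence", "incidence"), names(sr))
  if (length(miss)) {
    stop(sprintf("config error: stratum_rates missing column(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (any(sr$prevalence < sr$incidence)) {
    stop("config error: stratum prevalence must be >= incidence", call. = FALSE)
  }
  if (!cfg$anchor_year %in% cfg$years) {
    stop("config error: anchor_year outside the data years", call. = FALSE)
  }
  if (cfg$events_per_case_mean < 1) {
    stop("config error: events_per_case_mean must be >= 1", call. = FALSE)
  }
  invisible(cfg)
}

# random day within (year, quarter), as Date
random_day_in_quarter <- function(year, quarter) {
  q_start <- as.Date(sprintf("%d-%02d-01", year, (quarter - 1L) * 3L + 1L))
  q_end <- as.Date(sprintf("%d-%02d-01", year + (quarter == 4L),
                           ((quarter %% 4L) * 3L + 1L))) - 1L
  q_start + floor(runif(length(year)) * (as.numeric(q_end - q_start) + 1))
}

#' Simulate a claims database with ground truth
#'
#' Deterministic for a fixed seed (per-stage substreams are derived from the
#' config seed). True cases are chronic from an onset year onward; cases
#' whose onset falls in the anchor year are the true incident cases, and
#' stratum prevalence/incidence are calibrated at the anchor year. Case
#' patient-years emit at least one JIA-coded diagnosis event with quarters
#' drawn uniformly, so a small, tunable fraction of true cases fails M2Q;
#' non-case noise events are single-quarter or non-confirmed and never
#' create cases.
#'
#' @param config a [generator_config()].
#' @return list with `db` (a `claims_db`), `truth` (data.table of case
#'   patient-years: `patient_id`, `year`, `true_incident`, `true_category`,
#'   `true_comorbidities`; patient-years absent from the table are true
#'   non-cases), and `config`.
#' @export
simulate_claims <- function(config) {
  validate_generator_config(config)
  cfg <- config
  n <- cfg$n_patients
  years <- cfg$years
  anchor <- cfg$anchor_year

  # -- stage 1: patients ----------------------------------------------------
  set.seed(cfg$seed)
  patient_id <- sprintf("%s-%07d", cfg$label, seq_len(n))
  sex <- sample(SEX_LEVELS, n, replace = TRUE)
  # birth cohorts wide enough that every data year contains the full 2-15
  # age span; stratum rates are assigned at the anchor-year age (clamped to
  # the study bands for patients outside 2-15 at the anchor, who only enter
  # cohorts of other years)
  amin <- 2L - (anchor - min(years))
  amax <- 15L + (max(years) - anchor)
  age_anchor <- sample(amin:amax, n, replace = TRUE)
  birth_year <- anchor - age_anchor
  span_start <- as.Date(sprintf("%d-01-01", min(years)))
  span_end <- as.Date(sprintf("%d-12-31", max(years)))
  dies <- runif(n) < cfg$death_rate
  death_date <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  if (any(dies)) {
    death_date[dies] <- span_start +
      floor(runif(sum(dies)) * as.numeric(span_end - span_start + 1))
  }
  patients <- data.table(patient_id, sex, birth_year, death_date)

  # -- stage 2: true case status, onset, category ---------------------------
  set.seed(cfg$seed + 1L)
  strat <- data.table(age_group = assign_age_group(pmin(pmax(age_anchor, 2L),
                                                        15L)),
                      sex = sex)
  strat <- cfg$stratum_rates[strat, on = c("age_group", "sex")]
  if (anyNA(strat$prevalence)) {
    stop("config error: stratum_rates must cover all six strata", call. = FALSE)
  }
  is_case <- runif(n) < strat$prevalence / 1e5
  # given case: incident at anchor with prob incidence/prevalence, else
  # onset uniform over earlier data years
  p_inc <- fifelse(strat$prevalence > 0, strat$incidence / strat$prevalence, 0)
  incident_at_anchor <- is_case & runif(n) < p_inc
  onset_year <- rep(NA_integer_, n)
  onset_year[incident_at_anchor] <- anchor
  prior_years <- years[years < anchor]
  idx_prev <- which(is_case & !incident_at_anchor)
  if (length(idx_prev)) {
    onset_year[idx_prev] <- if (length(prior_years)) {
      prior_years[1L + floor(runif(length(idx_prev)) * length(prior_years))]
    } else anchor
  }
  mix <- cfg$category_mix / sum(cfg$category_mix)
  category_vec <- rep(NA_character_, n)
  n_case <- sum(is_case)
  if (n_case) {
    category_vec[is_case] <- sample(names(mix), n_case, replace = TRUE,
                                    prob = mix)
  }

  # -- stage 3: coverage ----------------------------------------------------
  # one row per patient-year (two when the year has a gap: March uncovered);
  # abutting rows merge back into long intervals on claims_db construction
  set.seed(cfg$seed + 2L)
  death_year <- rep(.Machine$integer.max, n)
  death_year[dies] <- as.integer(format(death_date[dies], "%Y"))
  py <- CJ(i = seq_len(n), year = years)[year >= birth_year[i] + 1L &
                                           year <= death_year[i]]
  py[, gap := runif(.N) < cfg$coverage_gap_prob]
  # per-year date lookups (avoids per-row date parsing)
  jan1 <- setNames(as.Date(sprintf("%d-01-01", years)), years)
  dec31 <- setNames(as.Date(sprintf("%d-12-31", years)), years)
  feb28 <- setNames(as.Date(sprintf("%d-02-28", years)), years)
  apr1 <- setNames(as.Date(sprintf("%d-04-01", years)), years)
  yi <- function(y) match(y, years)
  cov1 <- py[gap == FALSE,
             .(patient_id = patient_id[i],
               start_date = jan1[yi(year)], end_date = dec31[yi(year)])]
  gap_y <- py[gap == TRUE]
  cov2 <- rbind(
    gap_y[, .(patient_id = patient_id[i],
              start_date = jan1[yi(year)], end_date = feb28[yi(year)])],
    gap_y[, .(patient_id = patient_id[i],
              start_date = apr1[yi(year)], end_date = dec31[yi(year)])])
  coverage <- rbind(cov1, cov2)
  # truncate at death
  all_ids <- patient_id
  coverage[, dd := death_date[match(patient_id, all_ids)]]
  coverage <- coverage[is.na(dd) | start_date <= dd]
  coverage[!is.na(dd) & end_date > dd, end_date := dd]
  coverage <- coverage[, .(patient_id, start_date, end_date)]

  # -- stage 4: case diagnosis streams --------------------------------------
  set.seed(cfg$seed + 3L)
  case_idx <- which(is_case)
  case_py <- py[i %in% case_idx & year >= onset_year[i], .(i, year)]
  dx_case <- empty_dx()
  if (nrow(case_py)) {
    case_py[, n_ev := 1L + rpois(.N, cfg$events_per_case_mean - 1)]
    ev <- case_py[rep(seq_len(.N), n_ev), .(i, year)]
    m <- nrow(ev)
    ev[, quarter := sample(4L, m, replace = TRUE)]
    inp <- runif(m) < cfg$inpatient_fraction
    main <- inp & runif(m) < cfg$main_fraction
    ev[, setting := fifelse(main, "inpatient_main",
                            fifelse(inp, "inpatient_secondary", "outpatient"))]
    nonconf <- !inp & runif(m) < cfg$nonconfirmed_fraction
    qualifier_pool <- c("suspected", "excluded", "status_post")
    ev[, qualifier := "confirmed"]
    if (any(nonconf)) {
      ev[nonconf, qualifier := sample(qualifier_pool, sum(nonconf),
                                      replace = TRUE)]
    }
    # code: the patient's true category's codes, or a generic JIA code
    ev[, category := category_vec[i]]
    generic <- runif(m) < cfg$generic_code_prob | ev$category == "UA"
    code_of <- function(cat_names) {
      cmap <- default_category_map()
      vapply(cat_names, function(cn) {
        codes <- cmap[[cn]]
        codes[1L + floor(runif(1) * length(codes))]
      }, character(1))
    }
    ev[, icd_code := NA_character_]
    if (any(generic)) {
      ev[generic, icd_code := sample(GENERIC_JIA_CODES, sum(generic),
                                     replace = TRUE)]
    }
    if (any(!generic)) {
      ev[!generic, icd_code := code_of(category)]
    }
    ev[, date := as.Date(NA)]
    ev[setting != "outpatient", date := random_day_in_quarter(year, quarter)]
    dx_case <- ev[, .(patient_id = patient_id[i], icd_code, year, quarter,
                      setting, qualifier, date)]
  }

  # -- stage 5: non-case noise ----------------------------------------------
  set.seed(cfg$seed + 4L)
  dx_noise <- empty_dx()
  if (cfg$noise_dx_rate > 0) {
    noise_py <- py[!(i %in% case_idx), .(i, year)]
    noise_py[, n_ev := rpois(.N, cfg$noise_dx_rate)]
    noise_py <- noise_py[n_ev > 0L]
    if (nrow(noise_py)) {
      # all of a patient-year's noise lands in one quarter, outpatient;
      # about half non-confirmed — either way it cannot satisfy M2Q
      noise_py[, quarter := sample(4L, .N, replace = TRUE)]
      ev <- noise_py[rep(seq_len(.N), n_ev), .(i, year, quarter)]
      m <- nrow(ev)
      ev[, icd_code := sample(JIA_NOISE_CODES, m, replace = TRUE)]
      ev[, qualifier := fifelse(runif(m) < 0.5, "confirmed", "suspected")]
      dx_noise <- ev[, .(patient_id = patient_id[i], icd_code, year, quarter,
                         setting = "outpatient", qualifier, date = as.Date(NA))]
    }
  }

  # -- stage 6: background (non-JIA) diagnoses ------------------------------
  set.seed(cfg$seed + 5L)
  dx_bg <- empty_dx()
  if (cfg$background_dx_rate > 0) {
    bg <- py[, .(i, year, n_ev = rpois(.N, cfg$background_dx_rate))][n_ev > 0L]
    if (nrow(bg)) {
      ev <- bg[rep(seq_len(.N), n_ev), .(i, year)]
      m <- nrow(ev)
      dx_bg <- ev[, .(patient_id = patient_id[i],
                      icd_code = sample(BACKGROUND_CODES, m, replace = TRUE),
                      year, quarter = sample(4L, m, replace = TRUE),
                      setting = "outpatient", qualifier = "confirmed",
                      date = as.Date(NA))]
    }
  }

  # -- stage 7: comorbidities among case patient-years ----------------------
  set.seed(cfg$seed + 6L)
  dx_com <- empty_dx()
  com_truth <- NULL
  if (nrow(case_py)) {
    panel <- default_comorbidity_panel()
    pcom <- cfg$comorbidity_prevalence
    for (nm in intersect(names(pcom)[pcom > 0], names(panel))) {
      hit <- runif(nrow(case_py)) < pcom[[nm]]
      if (!any(hit)) next
      h <- case_py[hit, .(i, year)]
      dx_com <- rbind(dx_com,
                      h[, .(patient_id = patient_id[i],
                            icd_code = panel[[nm]][1],
                            year, quarter = sample(4L, .N, replace = TRUE),
                            setting = "outpatient", qualifier = "confirmed",
                            date = as.Date(NA))])
      com_truth <- rbind(com_truth, h[, .(i, year, name = nm)])
    }
  }

  diagnoses <- rbind(dx_case, dx_noise, dx_bg, dx_com)
  db <- claims_db(patients, coverage, diagnoses, label = cfg$label)

  truth <- if (nrow(case_py)) {
    t <- case_py[, .(patient_id = patient_id[i], i, year)]
    t[, true_case := TRUE]
    t[, true_incident := year == onset_year[i] & year == anchor &
        incident_at_anchor[i]]
    t[, true_category := category_vec[i]]
    t[, true_comorbidities := ""]
    if (!is.null(com_truth)) {
      agg <- com_truth[, .(cm = paste(sort(name), collapse = ";")),
                       by = .(i, year)]
      t[agg, on = c("i", "year"), true_comorbidities := cm]
    }
    t[, i := NULL]
    setkey(t, patient_id, year)
    t[]
  } else {
    data.table(patient_id = character(), year = integer(),
               true_case = logical(), true_incident = logical(),
               true_category = character(), true_comorbidities = character())
  }

  list(db = db, truth = truth, config = cfg)
}

#' Simulate two disjoint samples for heterogeneity testing
#'
#' Two databases drawn from the same configuration but different seeds and
#' labels, with disjoint patient identifiers — emulating two insurer samples
#' with non-overlapping populations.
#'
#' @param config a [generator_config()] (used for sample 1).
#' @param second_seed seed for sample 2.
#' @param labels two sample labels.
#' @return list of two `simulate_claims()` results.
#' @export
simulate_claims_pair <- function(config, second_seed = config$seed + 1000L,
                                 labels = c("S1", "S2")) {
  cfg1 <- config
  cfg1$label <- labels[1]
  cfg2 <- config
  cfg2$label <- labels[2]
  cfg2$seed <- as.integer(second_seed)
  list(simulate_claims(cfg1), simulate_claims(cfg2))
}
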