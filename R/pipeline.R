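# Study orchestration: simulate or load claims, ascertain cohorts per year,
# estimate standardized rates, report comorbidities and two-sample
# heterogeneity, all from a single configuration. Every output table goes
# through the small-cell suppression writer.

#' Study configuration
#'
#' Bundles the analysis choices: observation years, age range, case
#' definitions, category map, comorbidity panel, reference population,
#' error levels and suppression threshold.
#'
#' @param observation_years years for which cohorts are formed.
#' @param age_range inclusive age bounds.
#' @param definition overall case definition.
#' @param polyjia_definition polyarthritis case definition.
#' @param category_map ILAR category -> code-prefix map.
#' @param comorbidity_panel comorbidity name -> code-prefix map.
#' @param reference reference population table.
#' @param alpha level for rate confidence intervals (default 0.05).
#' @param het_conf_level confidence level for the heterogeneity
#'   rate-difference interval (default 0.99).
#' @param suppression_threshold minimum reportable count (default 5).
#' @param washout_quarters incident washout length in quarters.
#' @param top_k number of diagnosis blocks to report.
#' @param comorbidity_year year for the comorbidity/top-k report (default:
#'   last observation year).
#' @return a `study_config` list.
#' @export
study_config <- function(observation_years = 2014:2018,
                         age_range = c(2L, 15L),
                         definition = jia_case_definition(),
                         polyjia_definition = polyjia_case_definition(),
                         category_map = default_category_map(),
                         comorbidity_panel = default_comorbidity_panel(),
                         reference = default_reference_population(),
                         alpha = 0.05,
                         het_conf_level = 0.99,
                         suppression_threshold = 5L,
                         washout_quarters = 4L,
                         top_k = 10L,
                         comorbidity_year = max(observation_years)) {
  stopifnot(!is.unsorted(observation_years),
            age_range[1] >= 0, age_range[1] <= age_range[2],
            suppression_threshold >= 1)
  validate_reference(as.data.table(reference))
  structure(list(observation_years = as.integer(observation_years),
                 age_range = as.integer(age_range),
                 definition = definition,
                 polyjia_definition = polyjia_definition,
                 category_map = category_map,
                 comorbidity_panel = comorbidity_panel,
                 reference = as.data.table(reference),
                 alpha = alpha, het_conf_level = het_conf_level,
                 suppression_threshold = as.integer(suppression_threshold),
                 washout_quarters = as.integer(washout_quarters),
                 top_k = as.integer(top_k),
                 comorbidity_year = as.integer(comorbidity_year)),
            class = "study_config")
}

#' Share of a selection step, as a printed percentage
#'
#' Percentage `100 x / n` rounded to one decimal, the form used in the
#' patient-selection funnel (e.g. the age-2-15 share of a sample).
#'
#' @param x numerator count.
#' @param n denominator count.
#' @return percentage rounded to one decimal.
#' @export
funnel_percentage <- function(x, n) {
  round(100 * x / n, 1)
}

# Per-year patient-selection funnel for one database.
study_funnel <- function(db, config, year) {
  total <- nrow(db$patients)
  age_ok <- db$patients[year - birth_year >= config$age_range[1] &
                          year - birth_year <= config$age_range[2]]
  n_age <- nrow(age_ok)
  ins <- if (n_age) sum(continuously_insured(db, age_ok$patient_id, year)) else 0L
  prev <- prevalent_cohort(db, config$definition, year, config$age_range)
  n_cases <- length(prev$case_ids)
  prior_ins <- if (n_cases) {
    sum(continuously_insured(db, prev$case_ids, year - 1L))
  } else 0L
  inc <- incident_cohort(db, config$definition, year, config$age_range,
                         washout_quarters = config$washout_quarters)
  data.table(
    year = year,
    step = c("total", "age_eligible", "continuously_insured", "jia_cases",
             "prior_year_insured", "incident_cases"),
    count = c(total, n_age, ins, n_cases, prior_ins,
              length(inc$case_ids)),
    pct_of_previous = c(NA, funnel_percentage(n_age, total),
                        funnel_percentage(ins, n_age),
                        funnel_percentage(n_cases, ins),
                        funnel_percentage(prior_ins, n_cases),
                        funnel_percentage(length(inc$case_ids), prior_ins))
  )
}

# One estimates block (stratum rows + standardized "all" row) for a cohort.
estimate_block <- function(cohort, group, ref, alpha) {
  st <- copy(cohort$strata)
  strat_rows <- st[, .(
    year = cohort$year, measure = cohort$measure, group = group,
    stratum = paste(age_group, sex, sep = "/"), x, n,
    rate = fifelse(n > 0, 1e5 * x / n, NA_real_),
    lcl = NA_real_, ucl = NA_real_, extrapolated_n = NA_real_,
    extrapolated_lcl = NA_real_, extrapolated_ucl = NA_real_)]
  all_row <- cbind(
    data.table(year = cohort$year, measure = cohort$measure, group = group,
               stratum = "all"),
    standardized_estimate(st, ref, alpha))
  rbind(strat_rows, all_row, use.names = TRUE)
}

#' Run the full study on one or two claims databases
#'
#' For every observation year: the patient-selection funnel, prevalent and
#' incident overall-JIA cohorts, the polyJIA cohorts, ILAR category
#' classification, and directly standardized rate estimates with Fay-Feuer
#' intervals per group. For the comorbidity year: panel frequencies and the
#' top-k diagnosis blocks among prevalent JIA and polyJIA cases. With a
#' second database, a heterogeneity comparison per measure and year. All
#' tables are written as CSV under `out_dir` with small-cell suppression
#' applied to every patient-level count column, plus a `manifest.json`
#' echoing the configuration. The run is deterministic for fixed inputs.
#'
#' @param config a [study_config()].
#' @param db a `claims_db`.
#' @param db2 optional second `claims_db` for the sensitivity analysis.
#' @param out_dir output directory (created).
#' @return invisibly, a named list of the unsuppressed result tables
#'   (`funnel`, `cohort`, `estimates`, `comorbidities`, `topk`,
#'   `heterogeneity`).
#' @export
run_study <- function(config, db, db2 = NULL, out_dir) {
  stopifnot(inherits(config, "study_config"), inherits(db, "claims_db"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dbs <- if (is.null(db2)) list(db) else list(db, db2)

  funnel <- list()
  cohort_rows <- list()
  est <- list()
  het <- list()
  counts2 <- list()  # per (label, measure, year): x, n for heterogeneity

  for (d in dbs) {
    lab <- d$label
    for (yr in config$observation_years) {
      step_name <- sprintf("funnel %s %d", lab, yr)
      res <- tryCatch({
        funnel[[paste(lab, yr)]] <- cbind(sample = lab,
                                          study_funnel(d, config, yr))
        prev <- prevalent_cohort(d, config$definition, yr, config$age_range)
        inc <- incident_cohort(d, config$definition, yr, config$age_range,
                               washout_quarters = config$washout_quarters)
        prev_poly <- prevalent_cohort(d, config$polyjia_definition, yr,
                                      config$age_range)
        inc_poly <- incident_cohort(d, config$polyjia_definition, yr,
                                    config$age_range,
                                    washout_quarters = config$washout_quarters)
        ilar <- classify_ilar(d, prev$case_ids, config$category_map, yr,
                              verify_cases = FALSE)

        if (length(prev$case_ids)) {
          pat <- d$patients[.(prev$case_ids), on = "patient_id"]
          cohort_rows[[paste(lab, yr)]] <- data.table(
            sample = lab, patient_id = prev$case_ids, year = yr,
            stratum = paste(assign_age_group(age_in_year(pat$birth_year, yr)),
                            pat$sex, sep = "/"),
            incident_flag = prev$case_ids %in% inc$case_ids,
            ilar_category = unname(ilar[prev$case_ids]),
            polyjia_flag = prev$case_ids %in% prev_poly$case_ids)
        }

        blocks <- list(
          estimate_block(prev, "overall", config$reference, config$alpha),
          estimate_block(inc, "overall", config$reference, config$alpha),
          estimate_block(prev_poly, "polyJIA", config$reference, config$alpha),
          estimate_block(inc_poly, "polyJIA", config$reference, config$alpha))
        # per-ILAR-category standardized estimates on the prevalent and
        # incident cohorts (categories classified on the prevalent cohort)
        for (cohort in list(prev, inc)) {
          for (cat_name in ILAR_CATEGORIES) {
            ids <- names(ilar)[ilar == cat_name]
            ids <- intersect(ids, cohort$case_ids)
            sub <- subset_cohort(cohort, ids, d)
            blocks[[length(blocks) + 1L]] <-
              estimate_block(sub, cat_name, config$reference, config$alpha)
          }
        }
        est[[paste(lab, yr)]] <- cbind(sample = lab,
                                       rbindlist(blocks, use.names = TRUE))

        counts2[[paste(lab, "prevalence", yr)]] <-
          list(x = length(prev$case_ids), n = sum(prev$strata$n))
        counts2[[paste(lab, "incidence", yr)]] <-
          list(x = length(inc$case_ids), n = sum(inc$strata$n))
        TRUE
      }, error = function(e) e)
      if (inherits(res, "error")) {
        stop(sprintf("stage '%s' failed for year %d: %s",
                     step_name, yr, conditionMessage(res)), call. = FALSE)
      }
    }
  }

  funnel <- rbindlist(funnel)
  cohort_tab <- if (length(cohort_rows)) rbindlist(cohort_rows) else
    data.table(sample = character(), patient_id = character(),
               year = integer(), stratum = character(),
               incident_flag = logical(), ilar_category = character(),
               polyjia_flag = logical())
  estimates <- rbindlist(est)

  # comorbidities & top-k on the comorbidity year, per database
  com <- list()
  topk <- list()
  for (d in dbs) {
    yr <- config$comorbidity_year
    prev <- prevalent_cohort(d, config$definition, yr, config$age_range)
    poly <- prevalent_cohort(d, config$polyjia_definition, yr, config$age_range)
    for (pop in c("JIA", "polyJIA")) {
      ids <- if (pop == "JIA") prev$case_ids else poly$case_ids
      if (!length(ids)) next
      com[[paste(d$label, pop)]] <- cbind(
        sample = d$label, population = pop, year = yr,
        comorbidity_rates(d, ids, config$comorbidity_panel, yr,
                          threshold = config$suppression_threshold))
      topk[[paste(d$label, pop)]] <- cbind(
        sample = d$label, population = pop, year = yr,
        top_k_diagnoses(d, ids, yr, k = config$top_k,
                        threshold = config$suppression_threshold))
    }
  }
  com <- if (length(com)) rbindlist(com) else
    data.table(sample = character(), population = character(),
               year = integer(), name = character(), n = integer(),
               n_reported = character(), rate_pct = numeric())
  topk <- if (length(topk)) rbindlist(topk) else
    data.table(sample = character(), population = character(),
               year = integer(), code = character(), n = integer(),
               n_reported = character(), rate_pct = numeric())

  # heterogeneity between the two samples
  if (!is.null(db2)) {
    for (yr in config$observation_years) {
      for (ms in c("prevalence", "incidence")) {
        a <- counts2[[paste(db$label, ms, yr)]]
        b <- counts2[[paste(db2$label, ms, yr)]]
        het[[paste(ms, yr)]] <- cbind(
          data.table(measure = ms, year = yr, stratum = "all"),
          heterogeneity_row(a$x, a$n, b$x, b$n, config$het_conf_level))
      }
    }
  }
  het <- if (length(het)) rbindlist(het) else
    data.table(measure = character(), year = integer(), stratum = character(),
               x1 = integer(), n1 = integer(), x2 = integer(), n2 = integer(),
               chi2 = numeric(), df = integer(), p = numeric(),
               diff_per_100k = numeric(), lcl99 = numeric(),
               ucl99 = numeric(), effect_size = numeric(),
               small_expected_flag = logical())

  tables <- list(funnel = funnel, cohort = cohort_tab, estimates = estimates,
                 comorbidities = com, topk = topk, heterogeneity = het)
  write_study_tables(tables, out_dir, config)
  invisible(tables)
}

# Sub-cohort restricted to a case subset: same year, measure and stratum
# denominators as the parent cohort, case counts recomputed for the subset.
subset_cohort <- function(cohort, ids, db) {
  strat <- copy(cohort$strata)
  strat[, x := 0L]
  if (length(ids)) {
    pat <- db$patients[.(ids), on = "patient_id"]
    sub <- data.table(
      age_group = assign_age_group(age_in_year(pat$birth_year, cohort$year)),
      sex = pat$sex)[, .(x_new = .N), by = .(age_group, sex)]
    strat[sub, on = c("age_group", "sex"), x := x_new]
  }
  structure(list(year = cohort$year, measure = cohort$measure,
                 case_ids = sort(ids), strata = strat[]),
            class = "cohort_result")
}

#' Write the study tables with suppression applied
#'
#' Serializes the result tables as CSV under `dir`, replacing every
#' patient-level count in `1..threshold-1` by the `"<threshold"` sentinel
#' and blanking the associated rates, and writes `manifest.json` with the
#' configuration echo.
#'
#' @param tables named list as returned by [run_study()].
#' @param dir output directory.
#' @param config the `study_config` used.
#' @return invisibly, the directory.
#' @export
write_study_tables <- function(tables, dir, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  thr <- config$suppression_threshold
  supp <- function(dt, count_cols, rate_cols = character()) {
    dt <- copy(as.data.table(dt))
    for (cc in intersect(count_cols, names(dt))) {
      hide <- !is.na(dt[[cc]]) & dt[[cc]] >= 1 & dt[[cc]] < thr
      for (rc in intersect(rate_cols, names(dt))) {
        set(dt, which(hide), rc, NA)
      }
      set(dt, NULL, cc, suppress_small_counts(as.integer(dt[[cc]]), thr))
    }
    dt
  }
  out <- list()
  out$funnel <- supp(tables$funnel, "count", "pct_of_previous")
  out$estimates <- supp(tables$estimates, c("x", "extrapolated_n",
                                            "extrapolated_lcl",
                                            "extrapolated_ucl"),
                        c("rate", "lcl", "ucl"))
  out$comorbidities <- if (nrow(tables$comorbidities)) {
    tables$comorbidities[, .(sample, population, year, name,
                             n = n_reported, rate_pct)]
  } else data.table()
  out$topk <- if (nrow(tables$topk)) {
    tables$topk[, .(sample, population, year, code,
                    n = n_reported, rate_pct)]
  } else data.table()
  out$heterogeneity <- supp(tables$heterogeneity, c("x1", "x2"))
  out$cohort <- tables$cohort  # patient-level working file, no counts

  for (nm in names(out)) {
    fwrite(out[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("jiaclaims")),
    observation_years = config$observation_years,
    age_range = config$age_range,
    definition = config$definition$code_prefixes,
    polyjia_definition = config$polyjia_definition$code_prefixes,
    alpha = config$alpha,
    het_conf_level = config$het_conf_level,
    suppression_threshold = config$suppression_threshold,
    washout_quarters = config$washout_quarters)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
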