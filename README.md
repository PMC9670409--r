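# jiaclaims

Prevalence and incidence of juvenile idiopathic arthritis (JIA) from
German statutory health insurance (SHI) style claims data — a tested,
reusable implementation of the full analysis chain, plus a synthetic
claims generator with known ground truth so the chain can be validated
without access to proprietary insurer databases.

Intended for epidemiologists and biostatisticians working with
administrative claims who need a transparent, testable reference
implementation of claims-based case ascertainment and standardized-rate
estimation for a rare paediatric disease.

## What it implements

* **M2Q case ascertainment** — a patient-year is a JIA case given at least
  one main inpatient diagnosis, or ≥ 2 diagnoses from {secondary
  inpatient, confirmed outpatient} in two different calendar quarters,
  over a configurable ICD-10-GM code set (default: M05, M06, M07, M08,
  M09, M13, M45, L40.5). A restriction to M08.0/M08.3 gives the polyJIA
  proxy.
* **Cohort construction** — prevalent cohorts (ages 2–15, continuous
  insurance, death in-year not excluding) and incident cohorts
  (prior-year insurance plus a diagnosis-free 4-quarter washout before the
  index quarter).
* **ILAR category classification** by per-category M2Q evaluation with the
  undifferentiated-arthritis (UA) fallback for cases matching zero or
  several categories; categories always partition the cohort.
* **Direct standardization** of stratum rates (age band × sex) to a
  reference population, with **Fay–Feuer gamma confidence intervals**

  $R = 10^5 \sum_s w_s x_s/n_s$, $\ \mathrm{LCL} = G_{\alpha/2}(R^2/v,\, v/R)$,
  $\ \mathrm{UCL} = G_{1-\alpha/2}\big((R+c^*)^2/(v+c^{*2}),\, (v+c^{*2})/(R+c^*)\big)$

  and extrapolated case counts for the reference total.
* **Comorbidity and top-10 diagnosis reporting** under the n ≥ 5
  small-cell suppression rule, applied to every published table.
* **Two-sample heterogeneity** — Pearson chi-squared homogeneity test, 99%
  Wald interval for the rate difference, and Cohen's h effect size.
* **Synthetic SHI claims generator** — seeded, stratum-calibrated, with
  per-case diagnosis streams, noise diagnoses that fail M2Q by
  construction, coverage gaps, deaths, and a per-patient-year truth table.

See `vignettes/jia-claims-methods.Rmd` for the model, assumptions and
design choices, including why the shipped category/comorbidity code lists
and reference population are labelled reconstructions.

## Worked example

```r
library(jiaclaims)

cfg <- generator_config(n_patients = 30000, years = 2017:2018,
                        anchor_year = 2018, seed = 7,
                        background_dx_rate = 0.2)
sim <- simulate_claims(cfg)
sim$db
#> <claims_db 'S1'>: 30000 patients, 32901 coverage intervals, 13241 diagnoses

prev <- prevalent_cohort(sim$db, year = 2018)
prev
#> <cohort_result prevalence 2018>: 39 cases / 26560 eligible

standardized_estimate(prev$strata, default_reference_population())
#>        x     n     rate      lcl      ucl extrapolated_n extrapolated_lcl extrapolated_ucl
#> 1:    39 26560 146.6101 104.2273 200.7093          15363            10922            21032
```

39 ascertained cases among 26,560 eligible children give a directly
standardized prevalence of 146.6 per 100,000 (95% CI 104.2–200.7),
i.e. an extrapolated 15,363 affected children in the 10.48-million
reference population; the interval comfortably covers the generator's
configured standardized truth of 137.8 per 100,000.

The full study — both samples, all years, funnel, estimates,
comorbidities, heterogeneity — is a numbered workflow:

```sh
Rscript analysis/01_simulate.R    # two synthetic samples -> results/claims_S*/
Rscript analysis/02_run_study.R   # cohorts, rates, reports -> results/study/
Rscript analysis/03_summarise.R   # narrative summary -> results/summary.txt
Rscript analysis/04_recovery.R    # parameter-recovery experiment
```

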