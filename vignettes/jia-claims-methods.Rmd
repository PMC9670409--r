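---
title: "Estimating JIA prevalence and incidence from SHI-style claims data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating JIA prevalence and incidence from SHI-style claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Juvenile idiopathic arthritis (JIA) is the most common chronic inflammatory
rheumatic disease of childhood, yet population-based estimates of its
prevalence and incidence are scarce: the disease is rare, diagnosis requires
symptoms persisting at least six weeks, and registry studies capture only
patients who reach specialist care. Administrative claims from German
statutory health insurance (SHI) funds offer large, unselected samples, but
a claims record is not a diagnosis: outpatient codes are only located in
time by calendar quarter, carry qualifiers (confirmed, suspected, excluded,
status post), and single stray codes are common. This package implements
the full analysis chain for estimating JIA epidemiology from such data, and
— because real SHI claims cannot be redistributed — a synthetic claims
generator with known ground truth so every stage can be tested end to end.

## Case ascertainment: the M2Q rule

A patient-year is an overall-JIA case when, within the calendar year, the
patient has

* at least one **main inpatient** discharge diagnosis with a qualifying
  code, or
* at least two diagnoses from {**secondary inpatient**, **confirmed
  outpatient**} with qualifying codes in **two different quarters**
  ("M2Q").

The quarter condition is a proxy for diagnostic persistence: since
outpatient diagnoses are dated only to the quarter, two different quarters
are the coarsest available guarantee that the diagnoses are at least six
weeks apart. Non-confirmed outpatient qualifiers never count. The
qualifying code set for overall JIA is M05, M06, M07, M08, M09, M13, M45
and L40.5 — deliberately broad, including adult rheumatoid-arthritis codes,
because children (particularly adolescents moving to adult practitioners)
occasionally receive them. Codes are matched by prefix: a rule code `M08`
covers every `M08.x`, and `M08.0` covers itself and any extension.

polyJIA (the polyarthritis proxy) is the same rule restricted to
M08.0/M08.3, with secondary inpatient diagnoses counted as confirmed
outpatient diagnoses — which is already how the general rule treats them.

### Cohorts

For each observation year, the **prevalent cohort** is: patients aged 2–15
(age attained on December 31, i.e. year − birth year), continuously insured
through the year (death during the year does not exclude, provided coverage
ran to the death date), and satisfying M2Q. The denominator counts all
age-eligible continuously insured patients. The **incident cohort**
additionally requires continuous insurance in the preceding year and a
clean washout: no qualifying-code diagnosis in the four quarters before the
index quarter (the earliest quarter of the year containing a qualifying
event). The washout screens the *full* overall-JIA code set regardless of
which definition the cohort uses, because a documented related diagnosis of
any kind marks the disease as pre-existing. The washout length and its
outpatient-qualifier filter are configurable (`washout_quarters`,
`washout_any_qualifier`); four quarters with the confirmed-only filter is
the default, mirroring the case rule.

The age reference date deserves a note: claims tables carry birth years,
not birth dates, so "aged 2–15" is evaluated as the age attained on
December 31. This is deterministic, standard in German claims studies, and
the only convention computable from a birth year alone.

### ILAR categories

Each case is classified by evaluating the same M2Q rule per ILAR category
code list; a case satisfying exactly one category is assigned to it, and
cases satisfying none (e.g. ascertained only via generic codes such as M13)
or more than one fall back to undifferentiated arthritis (UA). The seven
categories therefore always partition the cohort — a property the test
suite asserts on every synthetic run. The default map (sJIA ← M08.2,
oligoJIA ← M08.4, RF− polyJIA ← M08.3, RF+ polyJIA ← M08.0, jPsA ← L40.5
and M07.0–M07.3, ERA-JIA ← M08.1 and M45, with M05/M06/M09/M13/M08.8/M08.9
counting toward overall JIA only) is a reconstruction from standard
ICD-10-GM coding conventions; the original study's exact supplementary code
lists are not publicly distributed, so every list here is configuration,
not logic, and should be replaced for serious use. The same applies to the
25-condition comorbidity panel in `default_comorbidity_panel()`.

## Estimation

Stratum-specific rates `x_s/n_s` over the six (age band × sex) strata are
combined by direct standardization against a reference population with
counts `N_s`:

$$R = 10^5 \sum_s w_s \frac{x_s}{n_s}, \qquad w_s = N_s / \textstyle\sum_t N_t.$$

Weights are normalized within whichever stratum set is being standardized.
Strata with empty denominators abort the estimate rather than being
silently dropped, since dropping them would change the standard population.

Confidence intervals use the Fay–Feuer gamma method for directly
standardized rates under Poisson stratum counts: with per-person weights
$c_s = w_s/n_s$, $R = \sum c_s x_s$, $v = \sum c_s^2 x_s$ and
$c^* = \max_s c_s$ (the maximum over *all* strata, including zero-count
ones — the conservative choice),

$$\mathrm{LCL} = G_{\alpha/2}\!\left(R^2/v,\; v/R\right), \qquad
\mathrm{UCL} = G_{1-\alpha/2}\!\left(\tfrac{(R+c^*)^2}{v+c^{*2}},\;
\tfrac{v+c^{*2}}{R+c^*}\right),$$

where $G_p(\text{shape}, \text{scale})$ is the gamma quantile and the lower
limit is 0 when $R = 0$. With a single stratum of weight one this reduces
exactly to the textbook Poisson gamma interval
$\tfrac12\chi^2_{\alpha/2}(2x) \,/\, \tfrac12\chi^2_{1-\alpha/2}(2x+2)$;
the tests assert this identity for $x = 0..50$ to $10^{-9}$ relative, and
a 2,000-replicate stratified-Poisson simulation confirms 93–97% coverage
at the 95% level. Extrapolated counts are the rate times the reference
total over 100,000, rounded to whole persons; full precision is kept
internally and rates are rounded only at output.

The reference population shipped with the package
(`reference_population_synthetic.csv`) is a synthetic stand-in: 10.48
million persons aged 2–15 split over the six strata with a 51.3% male
share. Official stratum counts are not redistributable here; the file is
clearly labelled synthetic and any real analysis should supply its own.

## The synthetic generator

`simulate_claims()` draws a population whose birth cohorts span the full
2–15 age range in every data year, assigns true case status per stratum at
a configurable **anchor year** (the year at which prevalence and incidence
are exactly calibrated; other years are approximate because cases are
chronic and age across strata), an onset year (onset at the anchor year
with probability incidence/prevalence — those are the true incident cases
— otherwise uniform over earlier data years), and one ILAR category per
case from the configured mix. Case patient-years emit a shifted-Poisson
number (≥ 1) of diagnosis events with uniform quarters, configurable
inpatient/main fractions, non-confirmed outpatient qualifiers, and codes
drawn from the case's category (or a generic JIA code with probability
`generic_code_prob`, exercising the UA fallback). Non-case noise events
all land in a single quarter per patient-year and are half non-confirmed,
so they can never satisfy M2Q — the generator produces no false-positive
cases by construction, which keeps recovery tests interpretable. Coverage
gaps (March uncovered) occur per patient-year with probability
`coverage_gap_prob`, and a small death rate exercises the
death-in-observation-year rule.

Default parameters are the study conditions: years 2013–2019 with anchor
2018; stratum prevalences at the printed 2018 stratified rates of the
smaller sample (87.4 and 40.4 per 100,000 for girls and boys aged 2–5,
290.6 and 170.3 at 12–15, with the unprinted 6–11 band interpolated at 160
and 95); incidence at 26% of prevalence (the ratio of the two printed
2018 headline estimates); a category mix proportional to the printed
category rates (oligoarthritis 40%, UA 28%, RF− polyarthritis 18%, …);
five diagnosis events per case-year; 15% inpatient, of which 40% main;
10% non-confirmed outpatient; 0.02 noise events per non-case year; 5%
coverage-gap years. Where the source material states no value (event
counts per case-year, gap and noise rates) the defaults are stated
assumptions chosen once as plausible for SHI data, not estimates.

What the generator does **not** emulate: regional structure, care-seeking
behaviour, treatment/ATC histories, correlated comorbidities (panel flags
are independent Bernoulli draws per case-year), or miscoded non-JIA
children. Passing recovery tests therefore show that the *pipeline* is
faithful to its definitions — not that the M2Q rule is sensitive or
specific on real claims, which can only be established against chart
review.

With the default five events per case-year, roughly 5% of true cases fail
M2Q (single-quarter streams with no main inpatient event), so ascertained
prevalence sits slightly below truth — deliberate, since real case
definitions also miss cases. The recovery experiments that require
near-deterministic ascertainment (`analysis/04_recovery.R`, the acceptance
suite) therefore switch to twelve events per case-year and zero noise, in
which configuration the failure probability is negligible; they use 100
runs of n = 200,000 patients over a single data year, sizes chosen to make
the Monte-Carlo error on coverage counts small while keeping the whole
suite fast on one CPU. The law-of-large-numbers check on the realized
case fraction uses a 2,000-per-100,000 prevalence so that its ±5% relative
band sits many standard errors from the mean at n = 200,000.

## Small-cell suppression

German data-protection rules for these databases forbid reporting
aggregated counts below five. Suppression is applied at output time only —
internal tables keep exact counts so invariants can be checked — and every
published CSV replaces counts 1–4 by the sentinel `"<5"` and blanks the
associated rate. A global audit (`passes_suppression_audit()`) scans every
emitted table; the test suite runs it on full pipeline output. Zero is
reported as zero: the rule protects small non-zero cells, not the absence
of cases.

## Two-sample heterogeneity

With two disjoint samples, `heterogeneity_row()` reports a Pearson
chi-squared homogeneity test on the 2×2 case/non-case table (df = 1, no
continuity correction — the simplest convention; expected cells below 5
are flagged, not fatal), a 99% Wald interval for the rate difference per
100,000, and an effect size. "Cohen's d" on two proportions is not a
well-defined quantity, so the default effect size is **Cohen's h**,
$|2\arcsin\sqrt{p_1} - 2\arcsin\sqrt{p_2}|$, the standard measure for a
difference of proportions; a pooled-SD d-on-proportions variant is
available via `effect_size(..., method = "d")`. On the published 2018
case/denominator pairs (546/401,531 vs 849/504,941) the chi-squared test
rejects decisively while h ≈ 0.008 — statistically significant but
negligible, the qualitative conclusion the comparison is designed to
reproduce: with samples this large, trivial differences reach
significance, and the effect size is the right lens.

Type-I calibration of the test is checked by simulating pairs of samples
from one configuration 1,000 times and confirming the α = 0.01 rejection
rate is compatible with 1%.

## Numerical and degenerate-case choices

* Coverage intervals are inclusive daily dates; intervals that abut
  (gap of zero days) merge, a one-day gap does not. Merging is
  order-invariant.
* `meets_m2q` on an empty event list is `FALSE`; duplicated identical
  events beyond the second never change the result.
* Index-quarter ties are impossible (quarters are totally ordered); the
  earliest qualifying quarter is the index.
* A rate with zero denominator is an error, never silently zero; a zero
  numerator is a true zero rate with a Fay–Feuer lower limit of 0.
* Top-k diagnosis ranking groups at the 3-character ICD block
  (configurable), sorts by descending distinct-patient count with
  lexicographic tie-break.
* Mid-year insurer switches are not distinguishable from coverage gaps in
  these tables; any gap breaks continuity.
* Comorbidity ascertainment uses a single qualifying diagnosis in the year
  (the weakest assumption, flagged here); `require_m2q = TRUE` applies the
  stricter rule.

## Known limitations

The category and comorbidity code lists are reconstructions (see above).
The generator's non-anchor years are only approximately calibrated. The
incident-washout interaction with noise diagnoses is simplified: noise is
only emitted for never-case patients, so washout failures among true
incident cases arise solely from their own pre-onset event streams. And
the package estimates administrative, not clinical, epidemiology: what is
recovered is the rate of patients *coded* consistently with JIA under the
M2Q rule.
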