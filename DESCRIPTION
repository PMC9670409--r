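Package: jiaclaims
Title: Juvenile Idiopathic Arthritis Epidemiology from Statutory Health
    Insurance Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for estimating the prevalence and incidence of
    juvenile idiopathic arthritis (JIA) from German statutory health insurance
    (SHI) style claims data. Implements the M2Q case-ascertainment algorithm
    (one main inpatient diagnosis, or two qualifying diagnoses in two
    different quarters of a calendar year), ILAR category classification by
    ICD-10-GM code with the undifferentiated-arthritis fallback, prevalent
    and incident cohort construction with a four-quarter washout, directly
    standardized rates with Fay-Feuer gamma confidence intervals and
    extrapolation to a reference population, comorbidity frequencies under
    small-cell (n >= 5) suppression, and a two-database heterogeneity
    analysis (chi-squared homogeneity test, 99% normal-approximation
    confidence interval for the rate difference, Cohen's h). A synthetic
    claims generator with known ground truth makes every stage testable
    without access to proprietary claims databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
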