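Package: ashmm
Title: Hidden Markov Models for Prostate Cancer Active Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits a discrete-time hidden Markov model of prostate cancer
    progression under active surveillance, with two transient risk states
    (favorable and non-favorable), three absorbing leaving states anchored
    to radical-prostatectomy pathology, annual PSA and biopsy emissions
    with non-informative missingness, and Baum-Welch estimation with
    random multi-restart. Provides patient-level nonparametric bootstrap
    standard errors, percentile confidence intervals and bootstrap-t
    positivity tests; a Monte-Carlo simulator for comparing published
    surveillance biopsy schedules by mean biopsy burden and mean delay to
    detection of non-favorable cancer; a synthetic longitudinal cohort
    generator with known ground truth; and internal-validation
    diagnostics (per-round biopsy positive rates against simulated bands,
    observed versus fitted PSA densities).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
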