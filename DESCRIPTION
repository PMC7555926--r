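Package: axotrace
Title: Axonal Excitability Modelling, Threshold Tracking and Metabolic
    Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates nerve excitability testing on a two-compartment
    (node and internode) biophysical model of a myelinated motor axon and
    analyses the resulting excitability measures alongside metabolic data
    from diet-induced prediabetes studies in rats.  Threshold-tracking
    protocols (strength-duration, threshold electrotonus, current-threshold
    and the recovery cycle) are reproduced in silico, scalar excitability
    indices are extracted, and membrane parameters are fitted to recorded
    group-mean data by a weighted least-squares discrepancy with
    single-parameter perturbation scans.  Companion tools compute the
    study's metabolic indices (HOMA-IR, TyG, Lee index, glucose-tolerance
    AUC), the up-down 50% paw-withdrawal threshold, normality-gated group
    comparisons and correlation tests, and generate seeded synthetic rat
    cohorts with a configurable correlation structure so that the whole
    pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    yaml,
    readr,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
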