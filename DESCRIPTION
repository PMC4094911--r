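Package: adindex
Title: MRI-Derived Severity Index for Alzheimer's Disease from Regional Morphometry
Version: 0.1.0
Authors@R:
    person("AddNeuroMed", "Reanalysis Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes a continuous per-subject Alzheimer's disease severity
    index from regional MRI morphometry (FreeSurfer-style cortical thickness
    and subcortical volumes) using a two-block hierarchical orthogonal partial
    least squares (OPLS) discriminant model trained on AD versus control
    subjects.  Provides a from-scratch single-response OPLS implementation
    with stratified k-fold cross-validation and Q2(Y) model significance,
    intracranial-volume normalisation and frozen autoscaling, confusion-count
    and empirical ROC/AUC evaluation, longitudinal annual-rate and
    average-index analyses with pattern-of-atrophy and APOE e4 stratification,
    and a seeded synthetic-cohort generator emulating the statistical
    structure of a multi-centre AD/MCI/control morphometry study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
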