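Package: preemietraj
Title: Longitudinal Serum Proteomics Trajectories in Preterm Infants
Version: 0.1.0
Authors@R:
    person("PRIDICT", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal label-free quantification
    (LFQ) serum proteomics of preterm infants sampled at postnatal days 0,
    3, 7, 14 and 28. Provides ingestion of DIA-NN-style protein-group
    reports, unique-precursor and completeness filtering, downshifted-normal
    imputation of intensity-dependent (MNAR) missing values, coefficient-of-
    variation quality control on repeated pool injections, classification of
    postnatal abundance trajectories by similarity score (squared Pearson
    correlation against theoretical shapes) and baseline-normalised area
    effect size, an empirical-Bayes moderated t-test with Benjamini-Hochberg
    correction for group contrasts at birth, and detection of proteins whose
    longitudinal behaviour deviates between small-for-gestational-age (SGA)
    and appropriate-for-gestational-age (AGA) infants. Includes a synthetic
    cohort generator that emulates the study design so that every stage is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
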