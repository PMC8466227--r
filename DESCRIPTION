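Package: pmredist
Title: Time-Dependent Postmortem Drug Redistribution Modeling and
    Endogenous Metabolite Correlation Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing time-dependent postmortem redistribution
    (PMR) of drugs measured in paired femoral-blood samples collected at
    mortuary admission and at autopsy. Provides cohort data structures with
    time-of-death imputation and interval arithmetic, an exponential
    mixed-effect concentration-change model with case-level random
    intercepts fitted on the natural-log scale, back-calculation of earlier
    concentrations, robustness assessment by repeated train/test
    resampling, a Spearman rank-correlation screen of endogenous metabolite
    features against drug concentration changes with false-discovery-rate
    control, Bland-Altman inter-method agreement analysis, and a seeded
    synthetic-data generator emulating the statistical structure of paired
    two-time-point postmortem cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
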