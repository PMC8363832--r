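Package: mlmgm
Title: Simulation Laboratory for Multilevel Multi-Growth Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying parameter recovery in longitudinal growth
    models when several monotone growth processes (chronological age,
    assessment experience, staggered interventions, pubertal maturation)
    jointly drive a single outcome. Generates observation designs for cohort,
    accelerated (planned-missingness), school-cohort and puberty studies;
    simulates outcomes from configurable multi-growth mixed-effects models,
    including sigmoid pubertal trajectories coarsened to Tanner stages and
    error-contaminated time-varying covariates; fits mis-specified (age-only)
    and properly specified multi-growth linear mixed-effects models by REML;
    and aggregates Monte-Carlo diagnostics across replicated ensembles:
    standardized bias, growth-predictor correlations, variance inflation
    factors, Bonferroni-corrected significance rates and implied trajectory
    vertices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    lmerTest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
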