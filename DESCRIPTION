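Package: pehgene
Title: Longitudinal Genetic Association Analysis of Post-Exercise Hypotension
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening genetic variants against ambulatory blood
    pressure responses to acute exercise (post-exercise hypotension). Converts
    reading-level ambulatory monitor data into hourly exercise-minus-control
    response series with device quality control, codes VCF genotypes as
    minor-allele dosages, fits generalized least squares models with AR(1),
    compound-symmetry or independent within-subject correlation by maximum
    likelihood or REML, screens variants with Bonferroni and
    Benjamini-Yekutieli correction over unique genotype profiles, builds
    AIC-selected multivariable final models with likelihood-based
    proportion-of-variance-explained measures, and estimates power by
    simulation. Includes a synthetic cohort generator for validation.
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
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    nlme
Config/testthat/edition: 3
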