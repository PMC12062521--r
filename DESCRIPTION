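Package: nflref
Title: Age- and Sex-Specific Reference Values for Serum Neurofilament
    Light Chain
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for establishing serum neurofilament light chain (sNfL)
    reference values in healthy adults. Implements CLSI-style nonparametric
    reference intervals (rank-interpolated 2.5th-97.5th percentiles) with
    bootstrap confidence intervals for medians and Mann-Whitney group
    comparisons; a log10-linear regression of sNfL on age and sex with a
    closed-form exponentiated upper-limit (97.5th percentile) formula; and
    age-normative centile curves from the Box-Cox Cole-Green (LMS)
    distribution fitted by a GAMLSS-type cyclic maximum-likelihood
    algorithm, with per-subject Z-scores. A seeded synthetic-cohort
    generator reproduces the demographic and distributional structure of a
    healthy adult reference population so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    splines,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
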