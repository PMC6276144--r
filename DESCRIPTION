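Package: certaudit
Title: Rule-Based Quality Auditing of Medical Cause-of-Death Certificates
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to audit the quality of medical certificates of cause of
    death. Provides deterministic, lexicon-driven detectors for the common
    certification errors (multiple causes on one line, missing disease time
    intervals, clinically implausible cause sequences, ill-defined underlying
    causes, blank lines within the causal chain, abbreviations, and
    under-specified diagnoses), a weighted composite error score, group-level
    quality tables with percentage-point improvement columns, Pearson
    chi-square and Welch t tests, and a maximum-likelihood proportional-odds
    (cumulative-logit) ordinal regression of the error score with odds-ratio
    reporting and reference-category switching. A seeded synthetic-certificate
    generator with planted error profiles supports end-to-end testing and
    calibration studies when individual-level registry data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
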