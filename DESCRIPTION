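Package: emadd
Title: Ecological Momentary Assessment of Delay Discounting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring delay discounting with short, continuous
    indifference-point items delivered by ecological momentary assessment
    (EMA). Implements hyperbolic-model (V = A/(1 + kD)) scoring of
    time-selection and monetary-selection slider items, Kirby-style
    consistency scoring of the binary Monetary Choice Questionnaire,
    participant-level quality control (straightliner and 3-SD outlier
    exclusion), the psychometric validation battery (item-total
    correlations, test-retest reliability, convergent validity, random-subset
    scale abbreviation), adjusted linear regressions of substance-use
    endorsement percentages on log discounting rates, and a synthetic
    two-phase EMA study simulator for end-to-end validation of the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
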