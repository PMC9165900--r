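Package: ringtrial
Title: Interlaboratory Precision Analysis for Quantitative Disinfectant
    Carrier Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analyses multi-laboratory (ring-trial) validation data for
    quantitative antimicrobial carrier tests such as the prEN 17658
    laboratory-scale laundering method. Converts raw agar-plate counts
    into per-carrier and wash-water loads with dilution-series weighting
    and detection-limit censoring, computes log-reduction endpoints,
    estimates repeatability and reproducibility variance components from
    the one-way random-effects model (ANOVA method-of-moments and REML),
    screens for outlying laboratories and observations with Cochran and
    Grubbs tests per ISO 5725-2, and renders per-endpoint precision
    reports with relative standard deviations and systematic-difference
    classifications. Includes a synthetic ring-trial generator, down to
    Poisson plate counts, so the full pipeline is testable without raw
    laboratory spreadsheets.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
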