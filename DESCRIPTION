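Package: btqr
Title: Presence-Only Threshold Selection for Species Distribution Models
    by Threshold Regression on the Boyce P/E Curve
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts continuous habitat-suitability predictions into binary
    presence/absence maps using only presence records. Builds the
    predicted-to-expected (P/E) frequency curve of Boyce and locates its
    mutation point -- the suitability value at which the curve's slope changes
    abruptly, interpreted under source-sink theory as the sink-to-source
    habitat transition -- by a two-region threshold regression with grid
    search over trimmed candidate thresholds. Also provides nine classical
    threshold rules (MaxSSS, equal sensitivity-specificity, maximum kappa,
    prevalence matching, mean probability, minimum ROC distance, and fixed
    sensitivities) for comparison, a virtual-species simulator with
    calibrated prevalence, and an evaluation framework based on Cohen's
    kappa, prevalence recovery, and one-way ANOVA F-tests of threshold
    consistency across validation sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
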