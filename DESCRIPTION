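Package: phagodrop
Title: Titration, Potency and Method-Agreement Statistics for Phage
    Drop-Off Plaque Assays
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying bacteriophage potency from direct spot
    ("drop-off") plaque assays performed manually or by a liquid-handling
    robot.  Converts spot-level plaque counts on ten-fold serial dilutions
    into titers (PFU/mL) with replicate statistics, resolves plate anomalies
    (merged adjacent drops, missed drops), applies countability and
    clearance-without-plaques exclusion rules, computes efficiency of
    plaquing (EOP) with virulence classification and assembles phagogram
    matrices across phage-strain panels.  Includes method-comparison
    statistics for validating an automated against a manual assay
    (Bland-Altman ratio analysis on log10-transformed titers, Lin's
    concordance correlation coefficient, normality-gated variability tests)
    and a stochastic simulator of the robotic assay (serial-dilution
    pipetting error, Poisson plaque counting, drop failures and spot
    coalescence) that provides ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
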