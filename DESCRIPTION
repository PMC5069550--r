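Package: silacturn
Title: Protein Turnover and Proteasome-Inhibition Kinetics from Dynamic SILAC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how proteasome inhibition affects protein
    degradation and synthesis from dynamic SILAC (stable isotope labeling with
    amino acids in cell culture) experiments. Implements peptide-to-protein
    ratio aggregation, normalization to long-lived reference proteins,
    pulsed-SILAC half-life estimation from fractional label incorporation, a
    first-order kinetic model predicting expected heavy/medium ratios under a
    given degree of proteasomal inhibition, detection-limit analysis,
    per-protein Welch tests with effect-size classification, joint inference of
    synthesis suppression from paired pulsed and multiplexed designs, and a
    synthetic-data generator with known per-protein ground truth for both
    labeling designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
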