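Package: interlab
Title: Interlaboratory Reproducibility Analysis for Cyanobacterial
    Promoter Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multi-laboratory plate-reader and
    spectrophotometer assays of reporter-gene expression in Synechocystis
    sp. PCC 6803. Implements internal-standard fluorescence normalization
    (blank correction, minimum-offset shift, RFU and nRFU computation),
    exponential growth-rate estimation by log-linear regression,
    intralaboratory and interlaboratory coefficient-of-variation
    decomposition, and inducible-promoter characterization (induction fold
    change, relative strength, leakiness) with cross-laboratory confidence
    intervals and Tukey compact-letter group comparison. Ships a
    hierarchical synthetic-data generator emulating the ring-trial design
    (laboratory-specific instruments and growth rates, biological and
    technical replication, induction kinetics) so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    multcomp,
    purrr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
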