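Package: pascalc
Title: Pairwise Agonist Scanning and an Ensemble Calcium Calculator for
    Platelet Signaling
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.com>
Description: Design, simulation and analysis tools for Pairwise Agonist
    Scanning (PAS) of platelet intracellular calcium mobilization.
    Enumerates combinatorial agonist stimulation designs (single, pairwise,
    trinary, higher-order and sequential-addition conditions over a dose
    grid expressed in EC50 multiples), generates synthetic donor calcium
    fluorescence time courses with configurable kinetics, crosstalk and
    saturation, preprocesses F/F0 traces (baseline normalization, replicate
    averaging, resampling, area under the curve), trains ensembles of
    lagged-feedback neural networks that predict calcium dynamics from
    agonist inputs, and quantifies signaling crosstalk with normalized
    synergy scores, percent inhibition and four-parameter Hill dose-response
    fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
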