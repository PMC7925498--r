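Package: sqmrm
Title: Targeted MRM Quantification of Sulfoquinovosyl Lipids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for targeted HPLC-ESI-MS/MS quantification of intact
    sulfoquinovosyl mono- and diacylglycerols (SQMG/SQDG) by multiple
    reaction monitoring (MRM). Provides an in-silico elemental-composition
    and mass model of sulfolipid species with isobaric acyl-pair
    enumeration, negative-mode fragment prediction (sulfoquinovose
    diagnostic ions and fatty-acid neutral losses), MRM transition-panel
    modelling with a bundled reference panel, chromatographic peak
    detection and trapezoidal integration on MRM traces,
    internal-standard calibration with LOD/LOQ estimation, concentration
    back-calculation and composition shares, method-validation statistics
    (intra-/inter-day precision, accuracy, recovery), and a seeded
    simulator of MRM runs, calibration series, and validation studies
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    zoo
Suggests:
    jsonlite,
    mzR,
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
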