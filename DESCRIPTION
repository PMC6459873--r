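Package: hdxstat
Title: Peptide-Level Statistics for Hydrogen-Deuterium Exchange Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for differential hydrogen-deuterium exchange
    mass spectrometry (HDX-MS) of membrane transporters: deuterium-uptake
    summarisation, back-exchange quantification against maximally labelled
    controls, normalized-uptake butterfly comparisons, a pooled-standard-
    deviation confidence-interval significance framework with a hybrid
    decision rule, residue-level consolidation of peptide calls, EX1
    bimodal isotope-envelope deconvolution, and equilibrium receptor-ligand
    occupancy with depletion plus one-site saturation binding fits. Includes
    a forward simulator of HDX studies (EX2 and EX1 regimes, replicate
    noise, back-exchange, isotope envelopes, saturation binding assays)
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    readr,
    purrr,
    ggplot2,
    minpack.lm,
    yaml,
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
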