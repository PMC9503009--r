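Package: scamcell
Title: Cell-Based Fluorometric Cysteine-Accessibility Analysis for
    Neurotransmitter Transporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses cell-based substituted-cysteine
    accessibility (SCAM) assays that read out transporter conformation with
    fluorescent substrates. Generates confocal-like image stacks under a
    mechanistic model of substrate uptake, membrane binding and
    methanethiosulfonate (MTS) modification kinetics; segments cells and
    quantifies per-cell fluorescence with a membrane-ring/interior
    decomposition; fits Michaelis-Menten transport kinetics with
    nonspecific-signal subtraction; converts MTS concentration-inhibition
    curves into pseudo-first-order modification rate constants; and
    classifies ligand- and ion-induced conformational changes from paired
    rate-constant comparisons between the extracellular and cytoplasmic
    permeation pathways.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
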