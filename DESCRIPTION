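Package: abrefine
Title: Structure-Guided Antibody Framework Refinement and Assay Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for structure-guided refinement of humanized antibody
    frameworks and model-based analysis of the validation assays.  Provides a
    simplified point-mutation folding-energy (ddG) scanner with van der Waals,
    Coulomb, Generalized-Born solvation, nonpolar surface-area and side-chain
    entropy terms evaluated in two structural contexts (parental murine
    structure and humanized homology model); the explicit back-mutation and
    humanizing-mutation selection rules used to assemble framework variants
    and their net mutation energies; T20-style humanness scoring against a
    human V-region sequence database; matrix-based MHC class II epitope
    scanning; a bivalent-analyte surface plasmon resonance kinetic model with
    global multi-concentration fitting; differential scanning fluorimetry
    melting-temperature analysis by the derivative method; and four-parameter
    logistic ADCC dose-response fitting with extra-sum-of-squares F tests.
    Synthetic-data generators emulate every input so the full pipeline runs at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    Biostrings,
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
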