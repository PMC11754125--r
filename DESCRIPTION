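Package: mirswitch
Title: Design and Thermodynamic Analysis of miRNA-Sensing CRISPR Guide RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for assembling single-guide RNAs whose Cas9 activity is
    gated by an endogenous microRNA. Guides are built from a modular grammar
    (shield, miRNA-binding site, spacer, scaffold) in which a self-complementary
    trigger hairpin sequesters the spacer until Argonaute-presented miRNA
    binding opens it. The package tunes trigger-hairpin stability by rule-based
    mismatch placement and evaluates candidates with an internal nearest-
    neighbour RNA secondary-structure engine: minimum-free-energy folding,
    ensemble base-pair probabilities via the partition function, constrained
    folding, a distance-scaled cotranscriptional folding check, and a two-state
    strand-displacement test. Includes a split AND-gate architecture sensing
    two miRNAs, a deterministic mismatch-pattern optimizer, synthetic fixture
    generation, and a frameshift-reporter simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    Biostrings,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    readr
Config/testthat/edition: 3
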