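Package: regevo
Title: Comparative Analysis of Cis-Regulatory Sequence Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying parallel evolution of transcription-factor
    binding sites in promoter regions across a phylogeny. Extracts upstream
    intergenic regions from annotated genomes, scans them on both strands with
    log-likelihood position weight matrices, tests gene sets for motif
    enrichment with exact hypergeometric tails, profiles the spacing between
    pairs of binding sites, fits two-state Mk models and samples stochastic
    character maps of motif gain and loss on a species tree, and quantifies
    allele-specific expression in interspecies hybrids with genomic-DNA
    normalization, per-gene t-tests under Benjamini-Hochberg FDR control and
    a group-level directional test. Includes simulators that generate every
    input with known ground truth: genomes with planted motif instances at
    controlled scores and spacings, binary characters evolved on trees with
    the true change history retained, and allelic count tables with planted
    log2 effects and a ploidy artifact.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    phangorn,
    phytools,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
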