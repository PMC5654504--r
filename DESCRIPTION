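Package: cftrace
Title: Somatic Variant Calling and Longitudinal Monitoring for Cell-Free DNA
    Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and tracks tumour-derived somatic single nucleotide
    variants in whole-genome sequencing of cell-free DNA. Implements a
    two-stage caller: candidate single nucleotide variants are scored under an
    empirical confusion-matrix sequencing-error model with exact binomial and
    Bayesian statistics, then verified against the germline by local de Bruijn
    assembly and k-mer haplotype support, guarding against reference-divergence
    artefacts. Adds 96-context mutational-signature spectra with
    transcriptional strand bias and Fisher-test spectrum comparisons,
    longitudinal variant-allele-frequency matrices with hierarchical subclone
    clustering and molecular-progression detection, and a depth-requirement
    planner. Ships a seeded cell-free DNA simulator (nucleosome-periodic
    fragment lengths, signature-weighted somatic variants, subclone
    trajectories) so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    generics,
    IRanges,
    jsonlite,
    purrr,
    rlang,
    Rsamtools,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    GenomicRanges,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
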