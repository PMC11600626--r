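Package: introntd
Title: Teleost Intron Size Distributions and PRDM9 Domain Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the bimodal 'teleost distribution' (TD) of
    intron sizes and its relationship to the domain architecture of PRDM9
    orthologues. Extracts introns from GFF3 genome annotation, builds
    log2-binned size distributions, detects antimodes and classifies species
    as TD or non-TD by a two-interval density rule; builds position-specific
    profile models from protein alignments, scans proteins and six-frame
    genome translations for aKRAB- and PR-SET-like domains and C2H2 zinc
    finger arrays; computes BLOSUM-rescaled pairwise sequence distances,
    neighbour-joining trees and PR-SET class assignments; and counts
    independent domain losses (or trait origins) as maximal monophyletic
    clades on a labelled phylogeny. A synthetic-data module generates
    annotations, protein families and labelled trees with planted truth so
    that every stage is testable without downloading genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
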