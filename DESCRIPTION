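Package: acrpoly
Title: Comparative Chromatin Accessibility Analysis for Allopolyploids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrative analysis of accessible chromatin regions (ACRs) in
    allopolyploids and their diploid progenitors. Implements an in silico
    'hybrid' built by mixing progenitor data 1:1 (genome-size-proportional for
    DNA methylation), ACR filtering and annotation, three-way common/specific
    overlap classes, differential ACR enrichment, histone-mark co-occurrence
    clustering (H3K4me3, H3K27ac, H3K27me3), weighted whole-genome bisulfite
    methylation levels with a minimum-coverage rule, meta-profiles around TSS
    and peak centers, negative-binomial differential expression, homeolog
    expression-bias classification, and subgenome asymmetry statistics. Ships
    a synthetic multi-omic data generator with known ground truth so the whole
    workflow is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
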