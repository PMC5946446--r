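Package: cocnet
Title: Gene Regulatory Crosstalk Between Oocytes and Cumulus Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects gene regulatory crosstalk between an oocyte and its
    surrounding cumulus-cell layers from per-compartment transcriptome
    profiles of cumulus-oocyte complexes (COCs). Implements robust
    cross-compartment co-expression via the biweight midcorrelation with
    a permutation empirical false discovery rate, within-compartment
    signed co-expression networks (topological overlap clustering), a
    ligand-receptor signaling road map built from merged protein-protein
    interaction sources with homology mapping and autocrine/paracrine
    classification, coefficient-of-variation statistics for highly
    variable genes, and length-bias-corrected gene-set enrichment by the
    Wallenius noncentral hypergeometric distribution. Includes a
    synthetic COC data generator with planted correlation structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
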