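Package: trapatools
Title: Chloroplast INDEL Markers, Plastid Typing and Seed Morphometrics for
    Water Chestnuts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A maternal-lineage analysis toolkit for water chestnuts (Trapa):
    simulation of quadripartite circular plastomes diverging along a known
    lineage tree, discovery and left-normalization of chloroplast INDELs from
    whole-genome pairwise alignments, repeat-motif classification
    (single-nucleotide repeat, tandem, SSR), primer design and in-silico PCR
    genotyping with size-coded alleles, collapsing of multi-locus genotypes
    into plastid types, maximum-composite-likelihood (TN93-family) pairwise
    distances with pairwise deletion and neighbor-joining trees, flow-cytometry
    genome-size and ploidy estimation against an internal standard, and seed /
    CT-volume morphometrics, orchestrated by a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phytools,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
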