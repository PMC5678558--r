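Package: methgrass
Title: Two-Genotype Plant Methylome Analysis from Bisulfite and MeDIP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative whole-genome bisulfite (WGBS) and MeDIP-seq
    methylome analysis in plants. Reads Bismark-style per-cytosine reports,
    GFF3 annotation and BED-family interval files; computes weighted
    methylation levels (genome-wide, per feature, per window, per region) in
    CG, CHG and CHH contexts; builds scaled gene/TE metaprofiles with fixed
    flanks; calls differentially methylated cytosines by per-site Fisher exact
    tests with Benjamini-Hochberg correction, clusters them into
    differentially methylated regions under distance/count/span/effect-size
    rules, and merges regions across contexts; assigns regions to genomic
    features with hypergeometric overrepresentation tests and nearest-TE
    association; summarises MeDIP peak densities and BS-seq/MeDIP concordance.
    A fully deterministic synthetic two-genotype methylome generator (genome,
    annotation, per-cytosine counts with planted DMRs, MeDIP-like peaks and
    coverage) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
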