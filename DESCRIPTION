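Package: aqpkit
Title: Annotation and Profiling of Plant Aquaporin (MIP) Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to annotate plant aquaporin (major intrinsic protein)
    gene families: proteome screening for dual NPA-like motifs and
    transmembrane topology, extraction of diagnostic residues (NPA loops,
    ar/R selectivity filter, Froger positions, substrate
    specificity-determining positions) from an annotated anchor alignment,
    neighbor-joining subfamily classification with bootstrap support,
    SDP-based substrate-specificity calling, genome context analyses
    (chromosome distribution, tandem duplication, exon skipping) and RPKM
    expression profiling. Ships curated residue and catalog tables for the
    sugar beet (Beta vulgaris) family and a deterministic synthetic-data
    generator with planted ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
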