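Package: fflnet
Title: Feed-Forward Loop Enrichment in TF-miRNA Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for transcription-factor-centred miRNA
    regulatory networks built from a loss-of-function contrast. Consolidates
    replicate ChIP-seq peaks into high-confidence binding sites and assigns
    candidate target genes via strand-oriented promoter windows; scans
    promoter sequences with position weight matrices or IUPAC patterns and
    tests positional and global over-representation; infers signed TF-to-gene
    regulatory edges from differential expression in the TF mutant; and
    enumerates TF-miRNA-target feed-forward loops, classifying them into the
    four types realizable with a repressive miRNA-target edge and testing
    per-type enrichment against an expression-shuffling permutation null.
    Includes a synthetic-data generator that plants ground-truth binding
    sites, motifs and coherent loops for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
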