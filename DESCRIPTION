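Package: creNet
Title: Cis-Regulatory Element Scanning and Co-Expression Community
    Networks for Transcription Factor Target Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate transcription factor target genes by
    combining genome-wide promoter scans for degenerate cis-regulatory
    elements (IUPAC consensus expansion, both-strand exact matching),
    positional-bias statistics in TSS-anchored bins, motif enrichment
    tests (hypergeometric presence test and a permutation test against
    base-composition-matched random promoters), mutual-rank co-expression
    neighborhoods around guide genes, and integration of co-expression
    support, promoter motif presence, and ortholog evidence into a
    community target network. Includes a synthetic-data generator with
    planted motifs and regulons for end-to-end validation, and a
    deterministic pipeline driver. Motivated by bZIP light-signalling
    regulators (HY5/HYH) whose binding sites are short ACGT-core boxes,
    but applicable to any consensus-defined motif catalog.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
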