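Package: sncpipe
Title: Profiling and Network Analysis of 5' tRNA Halves and YRNA Fragments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for small non-coding RNA sequencing studies
    of circulating and tissue 5' tRNA halves and 5' YRNA fragments. Counts
    5'-anchored 30-34 nt reads per gene locus, performs negative-binomial
    differential abundance analysis (TMM normalization, exact test for
    unpaired designs, patient-blocked likelihood-ratio test for paired
    designs, Benjamini-Hochberg FDR), discovers weighted coexpression modules
    over pooled miRNA/fragment expression (soft-threshold adjacency,
    topological overlap, dynamic branch cutting, module eigengenes, module
    membership and trait gene significance), scores miRNA overtargeting of
    validated target genes with a hypergeometric statistic and a random-set
    empirical null, and quantifies qPCR confirmations by the double-delta-Ct
    method. Ships a synthetic-data generator reproducing the statistical
    structure each stage assumes, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    Biostrings,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    mclust,
    Rsamtools,
    rtracklayer
Config/testthat/edition: 3
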