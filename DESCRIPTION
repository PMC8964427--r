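Package: ceRNAforge
Title: Staged lncRNA Identification, Differential Expression and ceRNA
    Network Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multi-stage long noncoding RNA (lncRNA) analysis in
    bulk RNA-seq designs: novel-lncRNA identification from assembled
    transcript annotations (structural filters, coding-potential
    intersection, positional classification), FPKM computation and staged
    differential expression, cis/trans target prediction, competing
    endogenous RNA (ceRNA) network inference via a hypergeometric
    shared-miRNA-sponge test, over-representation enrichment, and
    validation statistics (2^-ddCt qPCR quantification, trait correlations,
    Duncan's multiple range test, fatty-acid class ratios). Ships a
    synthetic-data generator that plants recoverable ceRNA triads,
    differential features and trait correlations so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
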