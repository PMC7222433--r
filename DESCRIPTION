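Package: genespan
Title: Gene Architecture, Tissue Enrichment and Neuronal Long-Gene
    Expression Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies gene architecture from genome annotations (gene
    span, exon unions, exonic and intronic content, intron lengths by
    ordinal position), normalizes multi-tissue expression matrices (TPM
    and group-aware smooth quantile normalization), scores per-gene
    tissue enrichment by fold-difference over the next-highest tissue,
    builds binned expression-versus-gene-length and intron-ordinal
    profiles, and aggregates per-species gene-length medians to clade
    statistics with rank-test comparisons. A synthetic-data generator
    produces annotations, expression matrices and multi-species length
    tables with planted length-by-tissue effects so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
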