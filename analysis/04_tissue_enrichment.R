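#!/usr/bin/env Rscript
# Score per-gene tissue specificity: maximal tissue, fold-difference over
# the next-highest tissue, fold classes and the 50x enrichment filter.

suppressMessages(library(genespan))

em <- read_expression_tsv("results/tpm.tsv", "results/data/metadata.tsv",
                          units = "TPM")
enr <- score_enrichment(tissue_means(em))
readr::write_tsv(enr, "results/enrichment.tsv")

defined <- !is.na(enr$fold_difference)
cat(sprintf("%d genes scored; %d with undefined fold-difference (all-zero)\n",
            nrow(enr), sum(!defined)))
print(table(fold_class = enr$fold_class[defined],
            passes_50x = enr$passes_50x[defined]))
cat(sprintf("neuronal-maximal genes: %d of %d (%.0f%%)\n",
            sum(enr$group_of_max == "neuronal", na.rm = TRUE), sum(defined),
            100 * mean(enr$group_of_max[defined] == "neuronal")))
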