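#!/usr/bin/env Rscript
# Normalize the raw counts: TPM against union exonic lengths, then smooth
# quantile normalization with tissues grouped as neuronal/non-neuronal.

suppressMessages(library(genespan))

em <- read_expression_tsv("results/data/counts.tsv",
                          "results/data/metadata.tsv")
arch <- readr::read_tsv("results/architecture.tsv", show_col_types = FALSE)
eff_len <- setNames(arch$exonic_bp, arch$gene_id)

tpm <- tpm_normalize(em, eff_len)
stopifnot(max(abs(colSums(tpm$values) - 1e6)) < 1e-3)
cat("TPM: every sample column sums to 1e6\n")

qs <- qsmooth_normalize(tpm, window_fraction = 0.05)
write_expression_tsv(qs, "results/tpm.tsv")

# how far did qsmooth move the values?
rel <- abs(qs$values - tpm$values) / (tpm$values + 1)
cat(sprintf("qsmooth: median |relative change| %.3f; units now %s\n",
            median(rel), qs$units))
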