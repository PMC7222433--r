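#!/usr/bin/env Rscript
# Quantify gene architecture from the annotation: gene lengths, exon
# unions, exonic/intronic content and intron lengths with strand-aware
# ordinal positions; illustrate the transcription-time cost of long genes.

suppressMessages(library(genespan))

models <- parse_annotation("results/data/genome.gff3", "gff3",
                           biotype_filter = "protein_coding")
arch <- architecture_table(models, length_method = "exon_span")
introns <- infer_introns(models)
readr::write_tsv(arch, "results/architecture.tsv")
readr::write_tsv(introns, "results/introns.tsv")

stopifnot(all(arch$exonic_bp + arch$intronic_bp == arch$gene_length_bp))
cat(sprintf("architecture: %d genes; median length %.0f bp; %.0f%% of long-gene bp are intronic\n",
            nrow(arch), median(arch$gene_length_bp),
            100 * with(arch[arch$gene_length_bp >=
                              quantile(arch$gene_length_bp, 0.9), ],
                       sum(intronic_bp) / sum(gene_length_bp))))

# intron delay: how long does transcription take at ~1 kb/min?
longest <- arch[which.max(arch$gene_length_bp), ]
cat(sprintf("longest gene %s: %.0f bp -> %.1f min (%.2f h) at 1 kb/min\n",
            longest$gene_id, longest$gene_length_bp,
            transcription_time(longest$gene_length_bp, 1000),
            minutes_to_hours(transcription_time(longest$gene_length_bp, 1000))))
cat(sprintf("a typical 10 kb gene takes %.0f min at the same rate\n",
            transcription_time(10e3, 1000)))
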