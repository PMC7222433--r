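#!/usr/bin/env Rscript
# Generate the synthetic study inputs: an annotated genome with a
# neuronal-long gene subset (larger, 5'-biased introns), a multi-tissue
# expression experiment with a planted length-by-neuronal-group effect,
# and multi-species gene-length tables with clade-specific scale.

suppressMessages(library(genespan))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- synthetic_spec(seed = 1, n_genes = 1000)
genome <- generate_genome(spec)
write_gff3(genome$models, file.path(out, "genome.gff3"))
readr::write_tsv(genome$truth, file.path(out, "genome_truth.tsv"))
cat(sprintf("genome: %d genes, %d flagged neuronal-long (%.0f%%)\n",
            nrow(genome$truth), sum(genome$truth$is_neuronal_long),
            100 * mean(genome$truth$is_neuronal_long)))

expr <- generate_expression(spec, genome$truth)
write_expression_tsv(expr$counts, file.path(out, "counts.tsv"))
write_metadata_tsv(expr$counts, file.path(out, "metadata.tsv"))
cat(sprintf("expression: %d genes x %d samples over %d tissues\n",
            nrow(expr$counts$values), ncol(expr$counts$values),
            length(unique(expr$metadata$tissue))))

ms <- generate_multispecies(spec)
dir.create(file.path(out, "species"), showWarnings = FALSE)
for (sp in names(ms$tables)) {
  readr::write_tsv(ms$tables[[sp]],
                   file.path(out, "species", paste0(sp, ".tsv")))
}
readr::write_tsv(ms$clade_map, file.path(out, "clade_map.tsv"))
cat(sprintf("multispecies: %d species across %d clades\n",
            nrow(ms$clade_map), length(unique(ms$clade_map$clade))))
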