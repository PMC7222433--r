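#!/usr/bin/env Rscript
# Comparative gene-length statistics: per-species medians (all genes and
# the top 10% longest), clade mean +/- SD of those medians, and a rank
# test between the largest-gene clade and the rest.

suppressMessages(library(genespan))

map <- readr::read_tsv("results/data/clade_map.tsv", show_col_types = FALSE)
tables <- lapply(map$species, function(sp) {
  readr::read_tsv(file.path("results/data/species", paste0(sp, ".tsv")),
                  show_col_types = FALSE)
})
names(tables) <- map$species

summaries <- dplyr::bind_rows(lapply(map$species, function(sp) {
  species_summary(tables[[sp]], sp, map$clade[map$species == sp])
}))
readr::write_tsv(summaries, "results/species_summary.tsv")

clades <- dplyr::bind_rows(
  dplyr::mutate(clade_aggregate(summaries, "median_length_all"),
                statistic = "median_length_all"),
  dplyr::mutate(clade_aggregate(summaries, "median_length_top10"),
                statistic = "median_length_top10"))
readr::write_tsv(clades, "results/clade_summary.tsv")
for (st in unique(clades$statistic)) {
  cat(st, "\n")
  sub <- clades[clades$statistic == st, ]
  for (i in seq_len(nrow(sub))) {
    cat(sprintf("  %-10s x̄ = %6.2f ± %5.2f kb (n = %d species)\n",
                sub$clade[i], sub$mean_of_medians[i] / 1000,
                sub$sd_of_medians[i] / 1000, sub$n_species[i]))
  }
}

top_clade <- with(clades[clades$statistic == "median_length_all", ],
                  clade[which.max(mean_of_medians)])
len_top <- unlist(lapply(tables[map$species[map$clade == top_clade]],
                         `[[`, "gene_length_bp"), use.names = FALSE)
len_rest <- unlist(lapply(tables[map$species[map$clade != top_clade]],
                          `[[`, "gene_length_bp"), use.names = FALSE)
cmp <- compare_species_groups(len_top, len_rest)
cat(sprintf("%s vs rest: U = %.3g, z = %.1f, p %s\n", top_clade, cmp$U,
            cmp$z,
            if (cmp$p_value < 2.2e-16) "< 2.2e-16"
            else sprintf("= %.3g", cmp$p_value)))
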