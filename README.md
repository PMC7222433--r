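# genespan

Gene architecture, tissue enrichment and neuronal long-gene expression
profiling in R.

Long genes are expensive to transcribe: at typical eukaryotic elongation
rates of 1–4 kb/min, a ~10 kb gene takes about 10 minutes per transcript
while a multi-megabase gene takes many hours — a cost ("intron delay")
that plausibly confines the longest genes to long-lived post-mitotic
cells such as neurons. `genespan` is for genomicists who want to quantify
this: it measures gene architecture from annotations, scores which
tissues each gene is enriched in, profiles expression as a function of
gene length and intron length as a function of ordinal position, and
compares gene-length distributions across species and clades. A
synthetic-data generator with planted effects makes the whole pipeline
testable end to end without any downloads.

## What it computes

* **Architecture** (`parse_annotation`, `architecture_table`,
  `infer_introns`, `exon_union`, `transcription_time`): per gene, the
  exon-span length L = max(exon end) − min(exon start) across isoforms,
  exonic content |∪ exons|, intronic content L − |∪ exons| (an exact
  identity), exon counts, and per-transcript introns with 5′-anchored
  ordinal positions; transcription time t = L / r for elongation rate r.
* **Normalization** (`tpm_normalize`, `qsmooth_normalize`, `cube_root`):
  TPM_g = 10^6 (c_g/ℓ_g) / Σ_j (c_j/ℓ_j), followed by smooth quantile
  normalization — each sample's rank-k value becomes
  w_k F̄(k) + (1 − w_k) F̄_group(k), with w_k a smoothed 1 − SSB/SST —
  which reduces exactly to quantile normalization when all samples share
  one group.
* **Tissue enrichment** (`tissue_means`, `score_enrichment`): per gene
  the maximal tissue, fold-difference max/second-highest, classes
  `lt2` / `2to5` / `gt5`, and the 50× max/min enrichment filter.
* **Profiles** (`profile_expression_vs_length`, `percentile_profile`,
  `loess_smooth`, `ordinal_profile`, `first_intron_ratio`): mean
  cube-root TPM per tissue over 100 equal-count gene-length bins (±95%
  CI), and mean intron length ± SE by ordinal position, stratified by
  neuronal vs non-neuronal maximal tissue and fold class.
* **Clade statistics** (`species_summary`, `clade_aggregate`,
  `compare_species_groups`): per-species medians of gene length (all
  genes and the top 10% longest), clade mean ± SD of those medians, and
  Mann–Whitney rank tests with continuity correction.
* **Synthetic data** (`synthetic_spec`, `generate_genome`,
  `generate_expression`, `generate_multispecies`): seeded,
  byte-reproducible genomes/expression/species tables with planted
  length-by-neuronal-group and 5′-intron-bias effects.

## Worked example

The `analysis/` directory is a numbered workflow over the package. On the
default synthetic study (seed 1, 1,000 genes, six tissues of which two
neuronal, 40 species in five clades):

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_gene_architecture.R
...
Rscript analysis/06_clade_statistics.R
```

prints, among other things:

```
architecture: 1000 genes; median length 10903 bp; 93% of long-gene bp are intronic
longest gene g0777: 132271 bp -> 132.3 min (2.20 h) at 1 kb/min
TPM: every sample column sums to 1e6
length profile: decile contrast (neuronal - non-neuronal, top vs bottom) = 0.76 cube-root TPM
gt5 stratum: first-intron neuronal/non-neuronal ratio = 2.69
gt5 neuronal ordinal slope = -1024 bp/position (5' introns longer)
Chordata   x̄ =  13.31 ±  1.80 kb (n = 8 species)
Chordata vs rest: U = 2.29e+08, z = 109.5, p < 2.2e-16
```

Reading: the longest genes are overwhelmingly intronic; the positive
decile contrast means neuronal tissues overtake non-neuronal ones at the
long end of the length axis; genes strongly enriched (> 5-fold) in
neuronal tissues carry first introns ~3× longer than their non-neuronal
counterparts, decaying toward the 3′ end; and the planted clade scales
separate by orders of magnitude with a vanishing rank-test p. Tables land
under `results/`. `run_pipeline(pipeline_config(...))` runs the same
stages as one call with a YAML-configurable parameter set and a JSON
manifest of filter counts.

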