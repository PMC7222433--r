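---
title: "Methods: gene architecture, tissue enrichment and long-gene expression profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene architecture, tissue enrichment and long-gene expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genespan)
```

# The question and the quantities

Transcribing a gene takes time roughly proportional to its length: at the
commonly cited eukaryotic elongation rates of 1–4 kb per minute, a
typical ~10 kb gene takes about ten minutes, while a multi-megabase gene
takes many hours (`transcription_time()` is exactly this division). This
"intron delay" plausibly restricts the longest genes to long-lived
post-mitotic cells such as neurons. The package quantifies the
architecture side of that argument (how long are genes, where in the gene
do the long introns sit) and the expression side (are the longest genes
preferentially expressed in neuronal tissues), plus the comparative side
(how do per-species gene-length medians differ between clades).

The core quantities, per gene:

* **gene length** — by default the *exon span*: distance from the start
  of the first exon to the end of the last exon across all isoforms. A
  `genomic_span` alternative uses record-level gene start/end coordinates
  when the annotation provides them. Both are offered because annotation
  conventions differ in whether UTR-bearing record coordinates or exon
  extremes are the better-comparable measure across species; the default
  is the exon span, and the choice is recorded in the output's
  `length_method` attribute.
* **exonic content** — total bases covered by the union of all annotated
  exons across isoforms (touching intervals merged).
* **intronic content** — defined as exon-span length minus exonic
  content. A union-of-introns definition can double-cover bases that are
  exonic in one isoform and intronic in another; the complement
  definition is deterministic and makes
  `exonic_bp + intronic_bp == gene_length_bp` an exact integer identity,
  which the tests assert for every generated gene.
* **intron records** — for every transcript of every gene (no canonical
  transcript is selected), intron i spans the gap between consecutive
  exons, and the *ordinal position* counts introns from the transcript's
  5′ end, so on the minus strand the genomically last intron is ordinal 1.

Coordinates are 0-based half-open internally; GFF3/GTF/BioMart input
(1-based inclusive) is converted on read. Only lengths are ever reported,
so the convention cannot leak into results. Touching exons within a
transcript (a zero-length intron) are an error under `strict = TRUE`, or
merged with a warning under `strict = FALSE`; transcripts spanning
multiple chromosomes or strands are always rejected.

# Expression normalization

Counts are converted to TPM per sample: each gene's count is divided by
its effective length (by default the union exonic content, the portion of
the gene actually present in mature transcripts), and rates are rescaled
to sum to 10^6. Column sums of 10^6 are asserted at relative tolerance
1e-9.

Across tissues the package applies **smooth quantile normalization**:
ordinary quantile normalization assumes every sample shares one
distribution, which is too strong when tissues genuinely differ. Instead,
each sample's rank-k value is replaced by

w_k · F̄(k) + (1 − w_k) · F̄_group(k)

where F̄(k) is the cross-sample mean at rank k, F̄_group(k) the mean
within the sample's biological group (here: neuronal vs non-neuronal
tissues), and w_k is `1 − SSB_k/SST_k` (between-group over total sum of
squares at rank k), clipped to [0, 1], smoothed by a running median over
`ceil(window_fraction · n)` ranks (default `window_fraction = 0.05`, the
conventional choice; ranks with SST = 0 get weight 1). With a single
group every w_k is 1 and the procedure reduces *exactly* to quantile
normalization — the test suite checks this to 1e-10. Tied values receive
the mean of their ranks' normalized values, so within-sample ordering is
preserved up to ties. Samples are normalized individually; tissue-level
expression is the mean over a tissue's samples, taken downstream.

Displayed expression uses the cube-root transform, a strictly monotone
variance-compressing map that keeps zero at zero.

# Tissue enrichment

Tissue specificity is deliberately descriptive, not model-based: each
gene is assigned to the tissue of maximal mean expression, and its
**fold-difference** is that maximum over the next-highest tissue. Classes
use strict boundaries — `lt2` below 2, `gt5` above 5, `2to5` for the
closed interval in between (a fold of exactly 5 is `2to5`); a relaxed
`gt2` selector (fold > 2) is also available. A gene counts as
tissue-enriched (`passes_50x`) only when its maximal value exceeds 50
times its lowest cross-tissue value; the "lowest value" is read per gene
across tissues, the only reading that yields a per-gene filter. A
second-highest value of zero with a positive maximum gives an infinite
fold (class `gt5`, the limit of the ratio); all-zero genes have no
defined fold and are carried as `NA` with a reported count rather than
silently dropped. Ties for the maximal tissue break by column order.

# Profiles

**Expression vs length.** Genes are segregated into `n_bins = 100`
equal-count bins by ascending length (ties broken by gene id, so the
partition is stable); per tissue and bin the mean of cube-root
tissue-mean expression is reported with a normal-approximation 95%
interval (1.96·sd/√n) and the bin's average gene length. Equal-count
bins were chosen over equal-width because gene lengths span orders of
magnitude (an equal-width variant exists behind `bin_method`); the
percentile profile is the same partition with the bin index read as a
length percentile, hence invariant to monotone transforms of length. The
`profile_decile_contrast()` summary — the neuronal-minus-non-neuronal
difference averaged over the top decile of bins minus the same over the
bottom decile — is the scalar used for planted-effect recovery.

**Smoothing.** `loess_smooth()` implements local polynomial regression
directly: at each target point the `ceil(span · n)` nearest observations
get tricube weights `(1 − (d/dmax)^3)^3` and a weighted least-squares
polynomial (default degree 2, default span 0.1) is evaluated at the
target. Degenerate neighbourhoods (all neighbours at one x, or all
weights zero) fall back to a weighted mean with a message. With span 1
and degree d the smoother reproduces any polynomial of degree ≤ d to
machine precision, and equals a closed-form weighted least-squares fit —
both are asserted in the tests. Generalized additive model smoothing is
deliberately left to plotting layers and nothing downstream depends on
it.

**Intron ordinal profiles.** Intron records join to enrichment records;
only genes passing the 50× filter enter, strata are (group of maximal
tissue) × (fold class), and every transcript contributes its introns
independently (a `collapse_gene` mode averages within gene first, for
sensitivity analysis). Rows are emitted per ordinal up to `max_ordinal`
(default 20) with at least `min_n` introns (default 25); both caps are
exposed because figure-level choices like these are rarely stated and
should be the analyst's. `first_intron_ratio()` and `ordinal_slope()`
summarize the 5′ bias.

# Clade statistics

Per species: medians of gene length over all genes and over the **top
10% longest** genes. The top-10% subset is the `ceil(n/10)` longest genes
(ties at the threshold included) — with 10 genes of 1..10 kb the subset
is the single 10 kb gene. Clades aggregate species medians to mean ± SD
(n − 1 denominator; a single-species clade reports sd 0 with a warning).
Group comparisons use the unpaired two-sample rank test (Mann–Whitney U)
via `stats::wilcox.test`: the exact null distribution for small tie-free
samples, otherwise the normal approximation with continuity correction;
the reported z is always the tie- and continuity-corrected deviate. The
exact small-sample route matches full permutation enumeration, which the
tests verify for every partition with at most 10 observations. (A paired
signed-rank mode would be inappropriate for unpaired species groups and
is not used.)

# The synthetic-data generator

The generator exists so that every stage is testable without downloads,
with known planted truth:

* **Genome.** Exon counts are 1 + Geometric (mean `exon_count_mean = 8`);
  exon lengths lognormal (median 150 bp, sdlog 0.5) and base intron
  lengths lognormal (median 1.5 kb, sdlog 0.8) — lognormal families
  because empirical length distributions are heavy-tailed and
  right-skewed. A fraction (`neuronal_long_fraction = 0.15`) of genes is
  flagged *neuronal-long*: their intron i draws
  `base × five_prime_scale × (1 + five_prime_bias)^-(i-1)` with defaults
  `five_prime_scale = 3` and `five_prime_bias = 0.5`, planting a 3×
  first-intron ratio and a geometric ordinal decay. The amplitude and the
  decay are separate parameters on purpose: a pure decay anchored at the
  first intron would leave ordinal-1 means equal between strata and no
  first-intron contrast would exist to recover. Strand is ± with equal
  probability and minus-strand genes are laid out reversed, so ordinal
  handling is exercised. Extra isoforms (Poisson, rate 0.5) each skip one
  internal exon; the merged introns they create dilute the recovered
  first-intron ratio slightly below 3 (the acceptance run recovers ≈ 2.9).
* **Expression.** log-counts are baseline (lognormal, median 10) + β ·
  z(log length) in neuronal tissues (`enrichment_effect = 1`) + a
  home-tissue boost + noise (sd 0.5), scaled by gene length so TPM
  recovers the planted effects. Neuronal-long genes are always
  tissue-specific at a neuronal home tissue (that *is* the planted
  coupling); other genes are tissue-specific with probability
  `specificity_fraction = 0.3` (boost lognormal, median 100×, so most
  specific genes clear the 50× filter), and broadly expressed otherwise —
  a majority of broad genes is what real transcriptomes look like, and it
  gives the fold-class stratification all three classes to work with.
  Six tissues (two neuronal) with one replicate each by default; a
  replicate count exercises the tissue-mean collapse.
* **Multi-species.** Species draw lognormal lengths around a clade-scaled
  median (`clade_scales` default roughly 1–9 across Protista, Plantae,
  Fungi, Metazoa, Chordata, echoing the relative scales seen across
  eukaryotes, with chordates about an order of magnitude above
  protists/fungi) with a 15% between-species spread.

Identical seeds give byte-identical outputs; the three generators use
fixed seed offsets so genome, expression and species draws are mutually
independent.

**What the generator does not emulate.** No sequence content, no reads
(so no mapping bias or count overdispersion beyond lognormal noise), no
correlated tissue structure beyond the two-group split, no annotation
errors or missing isoforms, no UTR/record-coordinate discrepancies. One
visible consequence: genes with a small fold-difference almost never pass
the 50× filter here (the generated `lt2` ∩ 50× stratum is essentially
empty and consists of single-exon genes whose lowest tissue rounds to
zero counts), whereas real multi-tissue atlases populate that stratum.
Passing tests therefore demonstrate correctness of the computations and
recoverability of planted effects under these idealized conditions — not
robustness to the many artefacts of real annotation and RNA-seq data.

# Recovery experiments and problem sizes

`beta_recovery_experiment()` draws lengths *independently* of the
neuronal-long flags (lognormal, median 5 kb), so with β = 0 the decile
contrast is sign-balanced by construction; with β = 1 it should be
positive in essentially every replicate. The test suite runs 50
replicates at β = 1 and 200 at β = 0 with 500 genes each.
`gamma_recovery_experiment()` runs the full genome → expression →
enrichment → ordinal-profile chain at 2,000 genes per replicate (50
replicates planted, 50 null), summarizing the neuronal ordinal slope and
the first-intron ratio with `max_ordinal = 4` and `min_n = 10` — sizes
chosen so the stratum means are estimated with standard errors well below
the ±20% recovery band. The interval-arithmetic oracle checks 1,000
random multi-isoform genes (spans < 10^5 bp) base-by-base, and the
strand-symmetry check mirrors a 500-gene genome.

# Known limitations

* The two readings of "gene length" (exon span vs record span) can
  differ for UTR-annotated genomes; both are computed, neither is
  declared the published one.
* The 95% ribbons of binned profiles use the normal approximation, not a
  smoother-based interval, so plotted ribbons from other toolchains will
  not match exactly.
* Whether published length bins were equal-count or equal-width is not
  derivable; equal-count is the default here, equal-width a flag.
* Absolute clade values depend on which genomes (and annotation
  versions) enter; the package reproduces the *procedure* and planted
  relative scales, not database-dependent absolute numbers.
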