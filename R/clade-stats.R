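#' Per-species gene-length summary
#'
#' Medians of gene length (all genes and the top 10% longest), exonic and
#' intronic content and exon count for one species. The top-10% subset is
#' the `ceil(n / 10)` longest genes — every gene whose length is at or
#' above the `(n - ceil(n/10) + 1)`-th smallest length, with ties at that
#' threshold included (so 10 genes of 1..10 kb give the single 10 kb
#' gene).
#'
#' @param arch architecture table for one species; needs `gene_length_bp`
#'   and optionally `exonic_bp`, `intronic_bp`, `n_exons_union`
#' @param species species label
#' @param clade clade label (e.g. Protista, Plantae, Fungi, Metazoa,
#'   Chordata)
#' @return one-row tibble: `species`, `clade`, `median_length_all`,
#'   `median_length_top10`, `median_exonic_bp`, `median_intronic_bp`,
#'   `median_exon_count`, `n_genes`. With fewer than 10 genes the top-10%
#'   median is `NA` with a warning.
#' @export
species_summary <- function(arch, species, clade) {
  len <- arch$gene_length_bp
  n <- length(len)
  if (n == 0L) stop("no genes for species ", species)
  if (n < 10L) {
    warning(sprintf("species '%s' has %d genes; top-10%% median undefined",
                    species, n))
    top10_med <- NA_real_
  } else {
    k <- ceiling(n / 10)                     # size of the top-10% subset
    thr <- sort(len)[n - k + 1L]
    top10_med <- stats::median(len[len >= thr])
  }
  med_or_na <- function(col) {
    if (col %in% names(arch)) stats::median(arch[[col]]) else NA_real_
  }
  tibble::tibble(
    species = species, clade = clade,
    median_length_all = stats::median(len),
    median_length_top10 = top10_med,
    median_exonic_bp = med_or_na("exonic_bp"),
    median_intronic_bp = med_or_na("intronic_bp"),
    median_exon_count = med_or_na("n_exons_union"),
    n_genes = n)
}

#' Aggregate species summaries to clade mean +/- SD
#'
#' The clade statistic reported alongside comparative gene-length
#' figures: the mean and sample standard deviation (n - 1 denominator),
#' across the species of a clade, of a per-species median. Single-species
#' clades report sd 0 with a warning.
#'
#' @param summaries row-bound [species_summary] tibbles
#' @param statistic which per-species median to aggregate (default
#'   `"median_length_all"`)
#' @return tibble with `clade`, `mean_of_medians`, `sd_of_medians`,
#'   `n_species`
#' @export
clade_aggregate <- function(summaries, statistic = "median_length_all") {
  if (!statistic %in% names(summaries)) {
    stop("unknown statistic '", statistic, "'")
  }
  vals <- summaries[[statistic]]
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(clade = summaries$clade, v = vals),
                    .data$clade),
    mean_of_medians = mean(.data$v),
    sd_of_medians = ifelse(dplyr::n() > 1, stats::sd(.data$v), 0),
    n_species = dplyr::n(), .groups = "drop")
  if (any(out$n_species == 1L)) {
    warning("clade(s) with a single species report sd 0: ",
            paste(out$clade[out$n_species == 1L], collapse = ", "))
  }
  attr(out, "statistic") <- statistic
  out
}

#' Rank-test comparison of two gene-length distributions
#'
#' Unpaired two-sample rank test (Mann-Whitney U) between the gene
#' lengths of two species groups. Follows the standard small/large-sample
#' rule: the exact null distribution when both groups have at most 50
#' observations and there are no ties, otherwise the normal approximation
#' with continuity correction. The reported z is always the
#' tie-corrected, continuity-corrected normal deviate of U.
#'
#' @param lengths_a,lengths_b numeric gene lengths of the two groups
#' @param exact force (`TRUE`)/suppress (`FALSE`) the exact distribution;
#'   `NULL` (default) applies the standard rule
#' @param correct continuity correction for the normal approximation
#'   (default `TRUE`)
#' @return list with `U` (statistic for group a), `z`, `p_value`,
#'   `method`
#' @export
compare_species_groups <- function(lengths_a, lengths_b, exact = NULL,
                                   correct = TRUE) {
  if (!length(lengths_a) || !length(lengths_b)) {
    stop("both groups must be non-empty")
  }
  wt <- suppressWarnings(
    stats::wilcox.test(lengths_a, lengths_b, exact = exact, correct = correct))
  n1 <- length(lengths_a); n2 <- length(lengths_b); N <- n1 + n2
  U <- unname(wt$statistic)
  mu <- n1 * n2 / 2
  ties <- table(c(lengths_a, lengths_b))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
  cc <- if (correct) 0.5 * sign(U - mu) else 0
  z <- if (sigma > 0) (U - mu - cc) / sigma else 0
  list(U = U, z = z, p_value = wt$p.value, method = wt$method)
}
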