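# Independent brute-force oracles and small fixture builders shared by the
# tests. These deliberately avoid the package's vectorized code paths.

make_models <- function(...) {
  gene_models(tibble::tibble(...))
}

# per-base membership oracle: exonic positions of a gene as an explicit set
oracle_exonic_positions <- function(exons_one_gene) {
  unique(unlist(Map(function(s, e) seq(s, e - 1), exons_one_gene$start,
                    exons_one_gene$end)))
}

# intervals from a sorted position set (0-based half-open)
oracle_intervals <- function(pos) {
  pos <- sort(pos)
  brk <- which(diff(pos) > 1)
  starts <- pos[c(1, brk + 1)]
  ends <- pos[c(brk, length(pos))] + 1
  tibble::tibble(start = starts, end = ends)
}

# per-transcript intron oracle: plain loop over sorted exons
oracle_introns_one_tx <- function(starts, ends, strand) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  k <- length(starts) - 1
  if (k < 1) return(tibble::tibble(ordinal = integer(), length_bp = numeric()))
  len <- starts[-1] - ends[-length(ends)]
  ord <- if (strand == "+") seq_len(k) else rev(seq_len(k))
  tibble::tibble(ordinal = ord, length_bp = len)
}

# reflect all exon coordinates of a model set about a point, flip strand
mirror_models <- function(models, pivot = 1e7) {
  ex <- models$exons
  tibble::tibble(gene_id = ex$gene_id, transcript_id = ex$transcript_id,
                 chrom = ex$chrom,
                 strand = ifelse(ex$strand == "+", "-", "+"),
                 start = pivot - ex$end, end = pivot - ex$start) |>
    gene_models()
}

# ordinary quantile normalization (tie-free input): per-rank cross-sample mean
oracle_quantile_normalize <- function(X) {
  Q <- apply(X, 2, sort)
  ref <- rowMeans(Q)
  out <- X
  for (s in seq_len(ncol(X))) out[order(X[, s]), s] <- ref
  out
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mw_u_distribution <- function(N, n1) {
  combs <- utils::combn(N, n1)
  apply(combs, 2, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
}

oracle_mw_exact_p <- function(u_obs, u_dist) {
  min(1, 2 * min(mean(u_dist <= u_obs), mean(u_dist >= u_obs)))
}

# closed-form weighted least-squares line fitted at a target point
oracle_wls_fit_at <- function(x, y, w, x0) {
  X <- cbind(1, x - x0)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  beta[1]
}

# small expression matrix fixture
make_em <- function(values, tissues = NULL, groups = NULL, units = "counts") {
  if (is.null(tissues)) {
    tissues <- stats::setNames(colnames(values), colnames(values))
  }
  if (is.null(groups)) {
    groups <- stats::setNames(rep("non_neuronal", length(unique(tissues))),
                              unique(tissues))
  }
  expression_matrix(values, tissues, groups, units = units)
}

# random multi-isoform genes with bounded span, as an exon tibble
random_gene_exons <- function(gene_id, n_tx = sample(1:3, 1),
                              max_exons = 8, max_span = 1e5) {
  rows <- list()
  for (t in seq_len(n_tx)) {
    k <- sample(1:max_exons, 1)
    starts <- sort(sample(0:(max_span - 200), k))
    ends <- starts + sample(10:150, k, replace = TRUE)
    o <- order(starts)
    starts <- starts[o]; ends <- ends[o]
    # enforce strictly positive gaps so the model is valid
    for (i in seq_len(k)[-1]) {
      if (starts[i] <= ends[i - 1]) starts[i] <- ends[i - 1] + 1
      if (ends[i] <= starts[i]) ends[i] <- starts[i] + sample(10:150, 1)
    }
    rows[[t]] <- tibble::tibble(
      gene_id = gene_id, transcript_id = sprintf("%s.t%d", gene_id, t),
      chrom = "chr1", strand = "+", start = starts, end = ends)
  }
  dplyr::bind_rows(rows)
}
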