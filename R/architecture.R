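#' Gene length
#'
#' Two readings of "gene length" are supported. `exon_span` (default) is
#' the distance from the start of a gene's first exon to the end of its
#' last exon across all isoforms. `genomic_span` uses record-level gene
#' start/end coordinates when the annotation provides them and falls back
#' to the exon span otherwise.
#'
#' @param models a [gene_models] object
#' @param method `"exon_span"` or `"genomic_span"`
#' @return tibble with `gene_id` and `length_bp`
#' @export
gene_length <- function(models, method = c("exon_span", "genomic_span")) {
  method <- match.arg(method)
  g <- models$genes
  len <- g$span_end - g$span_start
  if (method == "genomic_span") {
    has_rec <- !is.na(g$record_start) & !is.na(g$record_end)
    len[has_rec] <- g$record_end[has_rec] - g$record_start[has_rec]
  }
  tibble::tibble(gene_id = g$gene_id, length_bp = len)
}

#' Intron records with strand-aware ordinal positions
#'
#' Introns are inferred from exon positions of each transcript of each
#' gene: intron i (in genomic order) spans the gap between consecutive
#' exons. Ordinal position counts from the transcript's 5' end, so on the
#' minus strand the genomically last intron is ordinal 1.
#'
#' @param models a [gene_models] object (all transcripts contribute)
#' @return tibble with `gene_id`, `transcript_id`, `ordinal`, `length_bp`
#' @export
infer_introns <- function(models) {
  ex <- models$exons  # already sorted by gene, transcript, start
  n <- nrow(ex)
  if (n == 0L) {
    return(tibble::tibble(gene_id = character(), transcript_id = character(),
                          ordinal = integer(), length_bp = numeric()))
  }
  same_tx <- c(ex$transcript_id[-n] == ex$transcript_id[-1], FALSE)
  i <- which(same_tx)                     # row i and i+1 flank an intron
  if (!length(i)) {
    return(tibble::tibble(gene_id = character(), transcript_id = character(),
                          ordinal = integer(), length_bp = numeric()))
  }
  introns <- tibble::tibble(
    gene_id = ex$gene_id[i],
    transcript_id = ex$transcript_id[i],
    strand = ex$strand[i],
    length_bp = ex$start[i + 1L] - ex$end[i]
  )
  stopifnot(all(introns$length_bp >= 1))  # touching exons rejected upstream
  introns <- dplyr::mutate(
    dplyr::group_by(introns, .data$transcript_id),
    genomic_index = dplyr::row_number(),
    ordinal = ifelse(.data$strand == "+", .data$genomic_index,
                     dplyr::n() - .data$genomic_index + 1L))
  introns <- dplyr::ungroup(introns)
  introns$ordinal <- as.integer(introns$ordinal)
  introns[, c("gene_id", "transcript_id", "ordinal", "length_bp")]
}

#' Exon union per gene
#'
#' Minimal sorted set of disjoint intervals covering every base that is
#' exonic in at least one isoform; touching intervals are merged. Uses
#' IRanges reduction per gene.
#'
#' @param models a [gene_models] object
#' @return tibble with `gene_id`, `start`, `end` (0-based half-open)
#' @export
exon_union <- function(models) {
  ex <- models$exons
  ir <- IRanges::IRanges(start = ex$start + 1L, end = ex$end)  # 1-based incl.
  red <- IRanges::reduce(S4Vectors::split(ir, factor(ex$gene_id,
                                                     levels = unique(ex$gene_id))))
  flat <- unlist(red, use.names = FALSE)
  tibble::tibble(gene_id = rep(names(red), lengths(red)),
                 start = IRanges::start(flat) - 1,
                 end = as.numeric(IRanges::end(flat)))
}

#' Per-gene architecture table
#'
#' For each gene: gene length, exonic content (total bases in the exon
#' union across isoforms), intronic content (gene length minus exonic
#' content, so the two always sum to the gene length exactly), number of
#' union exon intervals, mean exon count per transcript and transcript
#' count.
#'
#' @param models a [gene_models] object
#' @param length_method passed to [gene_length]; intronic content is
#'   always defined against the exon-span length so the conservation
#'   identity holds.
#' @return tibble with columns `gene_id`, `gene_length_bp`, `exonic_bp`,
#'   `intronic_bp`, `n_exons_union`, `mean_exons_per_transcript`,
#'   `n_transcripts`; the length method used is stored in the
#'   `length_method` attribute.
#' @export
architecture_table <- function(models, length_method = c("exon_span",
                                                         "genomic_span")) {
  length_method <- match.arg(length_method)
  uni <- exon_union(models)
  per_gene_union <- dplyr::summarise(dplyr::group_by(uni, .data$gene_id),
                                     exonic_bp = sum(.data$end - .data$start),
                                     n_exons_union = dplyr::n(),
                                     .groups = "drop")
  ex_counts <- dplyr::summarise(
    dplyr::group_by(models$exons, .data$gene_id, .data$transcript_id),
    n_exons = dplyr::n(), .groups = "drop")
  per_gene_tx <- dplyr::summarise(dplyr::group_by(ex_counts, .data$gene_id),
                                  mean_exons_per_transcript = mean(.data$n_exons),
                                  n_transcripts = dplyr::n(), .groups = "drop")
  span_len <- gene_length(models, "exon_span")
  rep_len <- gene_length(models, length_method)

  out <- dplyr::left_join(span_len, per_gene_union, by = "gene_id")
  out <- dplyr::left_join(out, per_gene_tx, by = "gene_id")
  out <- tibble::tibble(
    gene_id = out$gene_id,
    gene_length_bp = rep_len$length_bp[match(out$gene_id, rep_len$gene_id)],
    exonic_bp = out$exonic_bp,
    intronic_bp = out$length_bp - out$exonic_bp,
    n_exons_union = out$n_exons_union,
    mean_exons_per_transcript = out$mean_exons_per_transcript,
    n_transcripts = out$n_transcripts)
  attr(out, "length_method") <- length_method
  out
}

#' Transcription time implied by gene length
#'
#' The intron-delay time cost of transcribing a gene: gene length divided
#' by the RNA polymerase II elongation rate. Eukaryotic elongation rates
#' are commonly estimated at 1-4 kb per minute; at 1 kb/min a typical
#' ~10 kb mammalian gene takes about 10 minutes, while a 2.3 Mb gene
#' takes well over 10 hours.
#'
#' @param gene_length_bp gene length(s) in bp
#' @param rate_bp_per_min elongation rate in bp per minute (default 1000)
#' @return transcription time in minutes
#' @export
transcription_time <- function(gene_length_bp, rate_bp_per_min = 1000) {
  if (any(rate_bp_per_min <= 0)) stop("elongation rate must be positive")
  if (any(gene_length_bp < 0)) stop("gene length must be non-negative")
  gene_length_bp / rate_bp_per_min
}

#' @rdname transcription_time
#' @param minutes a time in minutes
#' @export
minutes_to_hours <- function(minutes) minutes / 60
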