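#' Gene model collections
#'
#' A `gene_models` object holds a set of genes, each with one or more
#' transcripts defined by exon intervals. Internally all coordinates are
#' 0-based half-open, so an interval's length is simply `end - start`;
#' 1-based inclusive input (GFF3/GTF/BioMart) is converted on read and the
#' convention never leaks because every downstream quantity is a length.
#'
#' @param exons a data frame with columns `gene_id`, `transcript_id`,
#'   `chrom`, `strand` (`"+"` or `"-"`), `start`, `end` (0-based half-open).
#' @param genes optional data frame with one row per gene: `gene_id` and
#'   any of `biotype`, `record_start`, `record_end` (0-based half-open
#'   record-level gene coordinates, used by the `genomic_span` length
#'   method when present).
#' @param strict if `TRUE` (default), a zero-length gap between adjacent
#'   exons of a transcript is an error; if `FALSE`, touching exons are
#'   merged with a warning.
#'
#' @return an object of class `gene_models`: a list with tibbles `exons`
#'   (sorted by gene, transcript, start) and `genes` (gene span plus any
#'   record-level metadata).
#' @export
gene_models <- function(exons, genes = NULL, strict = TRUE) {
  exons <- tibble::as_tibble(exons)
  req <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  missing_cols <- setdiff(req, names(exons))
  if (length(missing_cols)) {
    stop("exon table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(exons) == 0L) stop("no exons")
  bad <- which(exons$end <= exons$start)
  if (length(bad)) {
    stop(sprintf("exon with end <= start (transcript '%s')",
                 exons$transcript_id[bad[1]]))
  }

  # one chrom and one strand per transcript
  per_tx <- dplyr::summarise(dplyr::group_by(exons, .data$transcript_id),
                             n_chrom = dplyr::n_distinct(.data$chrom),
                             n_strand = dplyr::n_distinct(.data$strand),
                             n_gene = dplyr::n_distinct(.data$gene_id),
                             .groups = "drop")
  inc <- per_tx$transcript_id[per_tx$n_chrom > 1L | per_tx$n_strand > 1L]
  if (length(inc)) {
    stop(sprintf("transcript '%s' has exons on multiple chroms/strands", inc[1]))
  }
  if (any(per_tx$n_gene > 1L)) {
    stop(sprintf("transcript '%s' is assigned to multiple genes",
                 per_tx$transcript_id[per_tx$n_gene > 1L][1]))
  }
  per_gene <- dplyr::summarise(dplyr::group_by(exons, .data$gene_id),
                               n_strand = dplyr::n_distinct(.data$strand),
                               n_chrom = dplyr::n_distinct(.data$chrom),
                               .groups = "drop")
  inc <- per_gene$gene_id[per_gene$n_strand > 1L | per_gene$n_chrom > 1L]
  if (length(inc)) {
    stop(sprintf("gene '%s' has transcripts on inconsistent strands/chroms", inc[1]))
  }

  exons <- dplyr::arrange(exons, .data$gene_id, .data$transcript_id, .data$start)

  # overlap / zero-gap checks within a transcript
  same_tx <- exons$transcript_id == dplyr::lag(exons$transcript_id,
                                               default = exons$transcript_id[1])
  same_tx[1] <- FALSE
  gap <- exons$start - dplyr::lag(exons$end, default = 0)
  ovl <- which(same_tx & gap < 0)
  if (length(ovl)) {
    stop(sprintf("overlapping exons within transcript '%s'",
                 exons$transcript_id[ovl[1]]))
  }
  touch <- which(same_tx & gap == 0)
  if (length(touch)) {
    if (strict) {
      stop(sprintf("zero-length intron (touching exons) in transcript '%s'",
                   exons$transcript_id[touch[1]]))
    }
    warning(sprintf("merged %d zero-length gap(s) between annotated exons",
                    length(touch)))
    keep <- rep(TRUE, nrow(exons))
    # walk backwards so runs of touching exons collapse into one
    for (i in rev(touch)) {
      exons$end[i - 1L] <- exons$end[i]
      keep[i] <- FALSE
    }
    exons <- exons[keep, , drop = FALSE]
  }

  span <- dplyr::summarise(dplyr::group_by(exons, .data$gene_id),
                           chrom = .data$chrom[1], strand = .data$strand[1],
                           span_start = min(.data$start),
                           span_end = max(.data$end),
                           n_transcripts = dplyr::n_distinct(.data$transcript_id),
                           .groups = "drop")
  if (!is.null(genes)) {
    genes <- tibble::as_tibble(genes)
    if (!"gene_id" %in% names(genes)) stop("gene table needs a gene_id column")
    span <- dplyr::left_join(span, genes, by = "gene_id")
  }
  if (!"biotype" %in% names(span)) span$biotype <- NA_character_
  if (!"record_start" %in% names(span)) span$record_start <- NA_real_
  if (!"record_end" %in% names(span)) span$record_end <- NA_real_

  structure(list(exons = exons, genes = span), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes, %d transcripts, %d exons\n",
              nrow(x$genes),
              dplyr::n_distinct(x$exons$transcript_id),
              nrow(x$exons)))
  invisible(x)
}

#' Number of genes in a collection
#' @param models a `gene_models` object
#' @return integer gene count
#' @export
n_genes <- function(models) nrow(models$genes)

#' Subset a gene model collection by gene id
#' @param models a `gene_models` object
#' @param gene_ids character vector of gene ids to keep
#' @return a `gene_models` object
#' @export
subset_genes <- function(models, gene_ids) {
  gene_models(models$exons[models$exons$gene_id %in% gene_ids, , drop = FALSE],
              genes = models$genes[models$genes$gene_id %in% gene_ids,
                                   c("gene_id", "biotype", "record_start",
                                     "record_end"), drop = FALSE])
}
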