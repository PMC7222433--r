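#' Parse a genome annotation into gene models
#'
#' Reads GFF3 or GTF (via rtracklayer) or a BioMart-style exon table and
#' builds a [gene_models] collection. Exon coordinates are converted from
#' the 1-based inclusive file convention to the internal 0-based half-open
#' one; within each transcript exons are kept in ascending genomic order
#' regardless of strand (ordinal positions are computed strand-aware
#' downstream, see [infer_introns]).
#'
#' Both GFF3 dialect (`ID`/`Parent` chains, optionally `transcript_id`
#' attributes) and GTF dialect (`gene_id "x"; transcript_id "y";`) are
#' supported. The BioMart-style TSV must have columns `gene_id`,
#' `transcript_id`, `chrom`, `strand`, `exon_start`, `exon_end` and
#' optionally `gene_biotype`, `gene_start`, `gene_end` (all 1-based
#' inclusive).
#'
#' @param path annotation file path.
#' @param format one of `"gff3"`, `"gtf"`, `"biomart_tsv"`.
#' @param biotype_filter optional biotype to keep (e.g. `"protein_coding"`);
#'   genes with no biotype annotation are dropped when a filter is given.
#' @param strict passed to [gene_models]: error on touching exons if `TRUE`.
#' @return a [gene_models] object.
#' @export
parse_annotation <- function(path,
                             format = c("gff3", "gtf", "biomart_tsv"),
                             biotype_filter = NULL,
                             strict = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  parts <- switch(format,
                  gff3 = parse_gff_like(path, "gff3"),
                  gtf = parse_gff_like(path, "gtf"),
                  biomart_tsv = parse_biomart_tsv(path))
  models <- gene_models(parts$exons, genes = parts$genes, strict = strict)
  if (!is.null(biotype_filter)) {
    keep <- models$genes$gene_id[!is.na(models$genes$biotype) &
                                   models$genes$biotype %in% biotype_filter]
    if (!length(keep)) stop("no genes left after biotype filter '",
                            biotype_filter, "'")
    models <- subset_genes(models, keep)
  }
  models
}

# cheap structural prescan so malformed lines are reported by number
check_nine_fields <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  if (!length(body)) stop("no feature lines in ", path)
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  bad <- body[nf != 9L]
  if (length(bad)) {
    stop(sprintf("unparseable line %d in '%s': expected 9 tab-separated fields",
                 bad[1], path))
  }
  invisible(TRUE)
}

first_present <- function(df, candidates) {
  hit <- intersect(candidates, names(df))
  if (length(hit)) df[[hit[1]]] else NULL
}

parse_gff_like <- function(path, format) {
  check_nine_fields(path)
  gr <- tryCatch(rtracklayer::import(path, format = format),
                 error = function(e) stop("failed to parse ", path, ": ",
                                          conditionMessage(e)))
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  is_exon <- type == "exon"
  if (!any(is_exon)) stop("no exon features in ", path)

  ex <- gr[is_exon]
  exm <- S4Vectors::mcols(ex)

  if (format == "gtf") {
    tid <- as.character(exm$transcript_id)
    gid <- as.character(exm$gene_id)
    if (anyNA(tid) || anyNA(gid)) {
      stop("exon feature lacking transcript_id/gene_id in ", path)
    }
    idx <- seq_along(ex)
  } else {
    # GFF3: one exon row per Parent transcript
    if (!is.null(exm$transcript_id) && !anyNA(exm$transcript_id)) {
      tid <- as.character(exm$transcript_id)
      idx <- seq_along(ex)
    } else {
      par <- exm$Parent
      if (is.null(par)) stop("GFF3 exons carry neither transcript_id nor Parent")
      np <- lengths(par)
      if (any(np == 0L)) stop("GFF3 exon without Parent in ", path)
      idx <- rep(seq_along(ex), np)
      tid <- unlist(par, use.names = FALSE)
    }
    # transcript -> gene via transcript features (mRNA/transcript/...)
    ids <- if (!is.null(mc$ID)) as.character(mc$ID) else rep(NA_character_, length(gr))
    tx_rows <- which(!is.na(ids) & ids %in% unique(tid))
    tx_gene <- rep(NA_character_, length(tx_rows))
    if (length(tx_rows)) {
      tpar <- mc$Parent[tx_rows]
      has_par <- lengths(tpar) > 0L
      tx_gene[has_par] <- vapply(tpar[has_par], function(p) p[[1]], character(1))
      tgid <- first_present(as.data.frame(mc[tx_rows, , drop = FALSE]),
                            c("gene_id", "geneID"))
      if (!is.null(tgid)) tx_gene[is.na(tx_gene)] <- as.character(tgid)[is.na(tx_gene)]
    }
    tx_map <- stats::setNames(tx_gene, ids[tx_rows])
    gid <- unname(tx_map[tid])
    exgid <- first_present(as.data.frame(exm), c("gene_id", "geneID"))
    if (!is.null(exgid)) {
      exgid <- as.character(exgid)[idx]
      gid[is.na(gid)] <- exgid[is.na(gid)]
    }
    if (anyNA(gid)) {
      stop("could not resolve a gene id for transcript '", tid[is.na(gid)][1], "'")
    }
  }

  exons <- tibble::tibble(
    gene_id = gid,
    transcript_id = tid,
    chrom = as.character(GenomicRanges::seqnames(ex))[idx],
    strand = as.character(GenomicRanges::strand(ex))[idx],
    start = GenomicRanges::start(ex)[idx] - 1,  # to 0-based half-open
    end = as.numeric(GenomicRanges::end(ex)[idx])
  )

  genes <- NULL
  grow <- which(type == "gene")
  if (length(grow)) {
    gm <- as.data.frame(mc[grow, , drop = FALSE])
    g_id <- first_present(gm, c("ID", "gene_id"))
    if (is.null(g_id) || anyNA(g_id)) {
      alt <- first_present(gm, c("gene_id", "ID"))
      if (!is.null(alt)) g_id[is.na(g_id)] <- as.character(alt)[is.na(g_id)]
    }
    bio <- first_present(gm, c("gene_biotype", "biotype", "gene_type"))
    genes <- tibble::tibble(
      gene_id = as.character(g_id),
      biotype = if (is.null(bio)) NA_character_ else as.character(bio),
      record_start = GenomicRanges::start(gr)[grow] - 1,
      record_end = as.numeric(GenomicRanges::end(gr)[grow])
    )
  } else if (format == "gtf") {
    bio <- first_present(as.data.frame(exm), c("gene_biotype", "biotype"))
    if (!is.null(bio)) {
      genes <- dplyr::distinct(tibble::tibble(gene_id = gid,
                                              biotype = as.character(bio)))
    }
  }
  list(exons = exons, genes = genes)
}

parse_biomart_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("gene_id", "transcript_id", "chrom", "strand", "exon_start", "exon_end")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols)) {
    stop("BioMart TSV missing columns: ", paste(missing_cols, collapse = ", "))
  }
  strand <- as.character(tab$strand)
  strand[strand %in% c("1", "+1")] <- "+"
  strand[strand == "-1"] <- "-"
  if (!all(strand %in% c("+", "-"))) {
    stop("unrecognized strand values in ", path)
  }
  exons <- tibble::tibble(
    gene_id = as.character(tab$gene_id),
    transcript_id = as.character(tab$transcript_id),
    chrom = as.character(tab$chrom),
    strand = strand,
    start = as.numeric(tab$exon_start) - 1,
    end = as.numeric(tab$exon_end)
  )
  genes <- NULL
  meta_cols <- intersect(c("gene_biotype", "gene_start", "gene_end"), names(tab))
  if (length(meta_cols)) {
    g <- dplyr::distinct(tab[, c("gene_id", meta_cols), drop = FALSE])
    genes <- tibble::tibble(gene_id = as.character(g$gene_id))
    if ("gene_biotype" %in% meta_cols) genes$biotype <- as.character(g$gene_biotype)
    if (all(c("gene_start", "gene_end") %in% meta_cols)) {
      genes$record_start <- as.numeric(g$gene_start) - 1
      genes$record_end <- as.numeric(g$gene_end)
    }
  }
  list(exons = exons, genes = genes)
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA and exon features with `ID`/`Parent` attributes plus
#' `gene_id`/`transcript_id`/`biotype` for interoperability. Coordinates
#' are converted back to the 1-based inclusive GFF convention.
#'
#' @param models a [gene_models] object
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gff3 <- function(models, path) {
  g <- models$genes
  ex <- models$exons
  tx <- dplyr::summarise(dplyr::group_by(ex, .data$gene_id, .data$transcript_id),
                         chrom = .data$chrom[1], strand = .data$strand[1],
                         start = min(.data$start), end = max(.data$end),
                         .groups = "drop")
  bio <- ifelse(is.na(g$biotype), "", paste0(";biotype=", g$biotype))
  gene_lines <- sprintf("%s\tgenespan\tgene\t%d\t%d\t.\t%s\t.\tID=%s%s",
                        g$chrom, as.integer(g$span_start + 1),
                        as.integer(g$span_end), g$strand, g$gene_id, bio)
  tx_lines <- sprintf("%s\tgenespan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                      tx$chrom, as.integer(tx$start + 1), as.integer(tx$end),
                      tx$strand, tx$transcript_id, tx$gene_id)
  ex_lines <- sprintf(
    "%s\tgenespan\texon\t%d\t%d\t.\t%s\t.\tParent=%s;gene_id=%s",
    ex$chrom, as.integer(ex$start + 1), as.integer(ex$end), ex$strand,
    ex$transcript_id, ex$gene_id)
  ord <- order(g$chrom, g$span_start, g$gene_id)
  # group lines per gene so the file reads top-down
  by_gene_tx <- split(tx_lines, tx$gene_id)
  by_gene_ex <- split(ex_lines, ex$gene_id)
  body <- unlist(lapply(ord, function(i) {
    gid <- g$gene_id[i]
    c(gene_lines[i], by_gene_tx[[gid]], by_gene_ex[[gid]])
  }), use.names = FALSE)
  writeLines(c("##gff-version 3", body), path)
  invisible(path)
}

#' Write gene models as GTF
#' @inheritParams write_gff3
#' @return `path`, invisibly
#' @export
write_gtf <- function(models, path) {
  ex <- models$exons
  bio <- models$genes$biotype[match(ex$gene_id, models$genes$gene_id)]
  attr_str <- sprintf('gene_id "%s"; transcript_id "%s";%s',
                      ex$gene_id, ex$transcript_id,
                      ifelse(is.na(bio), "",
                             sprintf(' gene_biotype "%s";', bio)))
  lines <- sprintf("%s\tgenespan\texon\t%d\t%d\t.\t%s\t.\t%s",
                   ex$chrom, as.integer(ex$start + 1), as.integer(ex$end),
                   ex$strand, attr_str)
  writeLines(lines, path)
  invisible(path)
}

#' Write gene models as a BioMart-style exon TSV
#' @inheritParams write_gff3
#' @return `path`, invisibly
#' @export
write_biomart_tsv <- function(models, path) {
  ex <- models$exons
  g <- models$genes
  m <- match(ex$gene_id, g$gene_id)
  out <- tibble::tibble(
    gene_id = ex$gene_id, transcript_id = ex$transcript_id,
    chrom = ex$chrom, strand = ex$strand,
    exon_start = as.integer(ex$start + 1), exon_end = as.integer(ex$end),
    gene_biotype = g$biotype[m],
    gene_start = as.integer(g$span_start[m] + 1),
    gene_end = as.integer(g$span_end[m]))
  readr::write_tsv(out, path)
  invisible(path)
}
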