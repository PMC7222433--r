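#' Read an expression study from TSV files
#'
#' The counts TSV has a `gene_id` first column and one column per sample;
#' the metadata TSV has columns `sample_id`, `tissue`, `group`.
#'
#' @param counts_path path to the counts (or TPM) matrix TSV
#' @param metadata_path path to the sample metadata TSV
#' @param units units of the matrix (default `"counts"`)
#' @return an [expression_matrix]
#' @export
read_expression_tsv <- function(counts_path, metadata_path,
                                units = "counts") {
  tab <- readr::read_tsv(counts_path, show_col_types = FALSE)
  if (names(tab)[1] != "gene_id") stop("first column must be gene_id")
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE)
  req <- c("sample_id", "tissue", "group")
  if (!all(req %in% names(meta))) {
    stop("metadata needs columns: ", paste(req, collapse = ", "))
  }
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab$gene_id
  expression_matrix(values,
                    sample_tissue = stats::setNames(meta$tissue, meta$sample_id),
                    tissue_group = stats::setNames(
                      meta$group, meta$tissue)[!duplicated(meta$tissue)],
                    units = units)
}

#' Write an expression matrix as TSV
#' @param em an [expression_matrix]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_expression_tsv <- function(em, path) {
  out <- tibble::as_tibble(em$values, rownames = "gene_id")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write sample metadata as TSV
#' @param em an [expression_matrix]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_metadata_tsv <- function(em, path) {
  meta <- tibble::tibble(
    sample_id = colnames(em$values),
    tissue = unname(em$sample_tissue[colnames(em$values)]),
    group = unname(em$tissue_group[em$sample_tissue[colnames(em$values)]]))
  readr::write_tsv(meta, path)
  invisible(path)
}
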