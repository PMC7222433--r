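#' Collapse samples to tissue-level means
#'
#' @param em an [expression_matrix]
#' @return numeric gene x tissue matrix; the tissue -> group map is kept
#'   in the `tissue_group` attribute
#' @export
tissue_means <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  tissues <- unique(unname(em$sample_tissue))
  out <- vapply(tissues, function(t) {
    cols <- names(em$sample_tissue)[em$sample_tissue == t]
    rowMeans(em$values[, cols, drop = FALSE])
  }, numeric(nrow(em$values)))
  dimnames(out) <- list(rownames(em$values), tissues)
  attr(out, "tissue_group") <- em$tissue_group
  out
}

#' Score per-gene tissue enrichment
#'
#' The tissue-specificity stratification: each gene is assigned to the
#' tissue in which its expression is maximal, and its fold-difference is
#' the ratio of that maximal value to the next-highest tissue's value.
#' Genes are classed by fold-difference with strict boundaries
#' (`lt2`: fold < low, `gt5`: fold > high, `2to5` otherwise) and a gene is
#' considered tissue-enriched (`passes_50x`) only when its maximal value
#' exceeds `ratio_filter` times its lowest cross-tissue value.
#'
#' A gene whose second-highest value is 0 (but max > 0) gets an infinite
#' fold-difference and class `gt5` (the limit of the ratio). All-zero
#' genes have no defined fold-difference: they are emitted with `NA`
#' fields and their count is messaged, so downstream stages can exclude
#' them explicitly.
#'
#' Ties for the maximal tissue are broken by column order.
#'
#' @param tissue_table gene x tissue matrix from [tissue_means]
#' @param tissue_group named tissue -> group map; defaults to the
#'   `tissue_group` attribute of `tissue_table`
#' @param fold_thresholds length-2 numeric `(low, high)`, default `c(2, 5)`
#' @param ratio_filter the max/min enrichment filter, default 50
#' @return tibble with one row per gene: `gene_id`, `max_tissue`,
#'   `group_of_max`, `max_value`, `second_value`, `min_value`,
#'   `fold_difference`, `fold_class`, `passes_50x`
#' @export
score_enrichment <- function(tissue_table,
                             tissue_group = attr(tissue_table, "tissue_group"),
                             fold_thresholds = c(2, 5),
                             ratio_filter = 50) {
  if (ncol(tissue_table) < 2L) stop("need at least 2 tissues")
  if (is.null(tissue_group)) stop("no tissue -> group map supplied")
  miss <- setdiff(colnames(tissue_table), names(tissue_group))
  if (length(miss)) stop("tissue(s) without a group: ",
                         paste(miss, collapse = ", "))
  low <- fold_thresholds[1]; high <- fold_thresholds[2]

  M <- unclass(tissue_table)
  imax <- max.col(M, ties.method = "first")
  max_value <- M[cbind(seq_len(nrow(M)), imax)]
  M2 <- M
  M2[cbind(seq_len(nrow(M)), imax)] <- -Inf
  second_value <- M2[cbind(seq_len(nrow(M)), max.col(M2, ties.method = "first"))]
  min_value <- do.call(pmin, as.data.frame(M))

  defined <- max_value > 0
  fold <- ifelse(second_value > 0, max_value / second_value, Inf)
  fold[!defined] <- NA_real_
  fold_class <- dplyr::case_when(
    is.na(fold) ~ NA_character_,
    fold < low ~ "lt2",
    fold > high ~ "gt5",
    TRUE ~ "2to5")
  n_zero <- sum(!defined)
  if (n_zero > 0) {
    message(n_zero, " all-zero gene(s) have undefined fold-difference")
  }
  max_tissue <- colnames(M)[imax]
  max_tissue[!defined] <- NA_character_

  tibble::tibble(
    gene_id = rownames(M),
    max_tissue = max_tissue,
    group_of_max = ifelse(defined, unname(tissue_group[colnames(M)[imax]]),
                          NA_character_),
    max_value = max_value,
    second_value = second_value,
    min_value = min_value,
    fold_difference = fold,
    fold_class = fold_class,
    passes_50x = ifelse(defined, max_value > ratio_filter * min_value, NA))
}
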