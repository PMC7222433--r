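#' Mean intron length by ordinal position, stratified by tissue group
#'
#' Joins intron records to per-gene enrichment records and summarizes mean
#' intron length (with standard error) at each ordinal position, per
#' tissue group of maximal expression. Only genes passing the max/min
#' enrichment filter are included (the descriptive "tissue-enriched"
#' subset); the stratum can further be restricted by fold-difference
#' class. Every transcript of a gene contributes its introns
#' independently unless `collapse_gene = TRUE`, which first averages
#' intron length within (gene, ordinal).
#'
#' @param introns tibble from [infer_introns]
#' @param enrichment tibble from [score_enrichment]
#' @param fold_class one of `"lt2"`, `"2to5"`, `"gt5"`, `"gt2"`
#'   (fold-difference > 2, the relaxed stratum) or `"all"`
#' @param max_ordinal largest ordinal position reported (default 20)
#' @param min_n minimum intron count for a (group, ordinal) row (default 25)
#' @param require_50x apply the enrichment filter (default `TRUE`)
#' @param collapse_gene average within gene and ordinal before pooling
#' @return tibble with `group`, `fold_class`, `ordinal`, `mean_length_bp`,
#'   `se_bp`, `n`
#' @export
ordinal_profile <- function(introns, enrichment, fold_class = "gt5",
                            max_ordinal = 20, min_n = 25,
                            require_50x = TRUE, collapse_gene = FALSE) {
  fold_class <- match.arg(fold_class, c("lt2", "2to5", "gt5", "gt2", "all"))
  enr <- enrichment[!is.na(enrichment$fold_difference), , drop = FALSE]
  if (require_50x) enr <- enr[enr$passes_50x, , drop = FALSE]
  keep <- switch(fold_class,
                 lt2 = enr$fold_difference < 2,
                 `2to5` = enr$fold_difference >= 2 & enr$fold_difference <= 5,
                 gt5 = enr$fold_difference > 5,
                 gt2 = enr$fold_difference > 2,
                 all = rep(TRUE, nrow(enr)))
  enr <- enr[keep, , drop = FALSE]
  df <- dplyr::inner_join(introns,
                          enr[, c("gene_id", "group_of_max")],
                          by = "gene_id")
  df <- df[df$ordinal <= max_ordinal, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop(sprintf("no introns left in stratum (fold_class = %s, 50x filter %s)",
                 fold_class, if (require_50x) "on" else "off"))
  }
  if (collapse_gene) {
    df <- dplyr::summarise(
      dplyr::group_by(df, .data$gene_id, .data$group_of_max, .data$ordinal),
      length_bp = mean(.data$length_bp), .groups = "drop")
  }
  out <- dplyr::summarise(
    dplyr::group_by(df, group = .data$group_of_max, ordinal = .data$ordinal),
    mean_length_bp = mean(.data$length_bp),
    se_bp = ifelse(dplyr::n() > 1,
                   stats::sd(.data$length_bp) / sqrt(dplyr::n()), 0),
    n = dplyr::n(), .groups = "drop")
  out <- out[out$n >= min_n, , drop = FALSE]
  out <- dplyr::arrange(out, .data$group, .data$ordinal)
  tibble::tibble(group = out$group, fold_class = fold_class,
                 ordinal = as.integer(out$ordinal),
                 mean_length_bp = out$mean_length_bp,
                 se_bp = out$se_bp, n = as.integer(out$n))
}

#' Ratio of first-intron mean lengths between two profiles
#'
#' @param profile_a,profile_b rows from [ordinal_profile] (e.g. the
#'   neuronal and non-neuronal strata); both must contain ordinal 1
#' @return `profile_a`'s ordinal-1 mean length over `profile_b`'s
#' @export
first_intron_ratio <- function(profile_a, profile_b) {
  a1 <- profile_a$mean_length_bp[profile_a$ordinal == 1L]
  b1 <- profile_b$mean_length_bp[profile_b$ordinal == 1L]
  if (length(a1) != 1L || length(b1) != 1L) {
    stop("both profiles must contain exactly one ordinal-1 row")
  }
  a1 / b1
}

#' Least-squares slope of mean intron length versus ordinal position
#'
#' Convenience summary of the 5' bias of a stratum: the slope of a simple
#' linear regression of per-ordinal mean intron length on ordinal
#' position. Negative slopes mean 5' introns are longer.
#'
#' @param profile rows from [ordinal_profile] for a single stratum
#' @return slope in bp per ordinal position
#' @export
ordinal_slope <- function(profile) {
  if (nrow(profile) < 2L) stop("need at least 2 ordinal positions")
  unname(stats::coef(stats::lm(mean_length_bp ~ ordinal, data = profile))[2])
}
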