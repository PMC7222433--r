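#' Assign genes to gene-length bins
#'
#' Equal-count (quantile) bins by ascending length: genes are ordered by
#' length (ties broken by gene id, so the assignment is stable) and split
#' into `n_bins` contiguous groups whose sizes differ by at most one
#' (larger bins first). An equal-width alternative divides the length
#' range into `n_bins` equal spans.
#'
#' @param lengths named numeric vector, gene id -> length in bp
#' @param n_bins number of bins (default 100); must not exceed the number
#'   of genes
#' @param method `"equal_count"` (default) or `"equal_width"`
#' @return named integer vector, gene id -> bin index in 1..n_bins
#' @export
assign_length_bins <- function(lengths, n_bins = 100,
                               method = c("equal_count", "equal_width")) {
  method <- match.arg(method)
  n <- length(lengths)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  if (n < n_bins) stop(sprintf("fewer genes (%d) than bins (%d)", n, n_bins))
  if (method == "equal_width") {
    brk <- seq(min(lengths), max(lengths), length.out = n_bins + 1L)
    bin <- findInterval(lengths, brk, rightmost.closed = TRUE, all.inside = TRUE)
    return(stats::setNames(as.integer(bin), names(lengths)))
  }
  ord <- order(lengths, names(lengths))
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  bin_sorted <- rep(seq_len(n_bins), times = sizes)
  bin <- integer(n)
  bin[ord] <- bin_sorted
  stats::setNames(bin, names(lengths))
}

#' Binned expression-versus-gene-length profiles
#'
#' Per tissue, genes are segregated into equal-count gene-length bins and
#' the mean transformed tissue-level expression of each bin is reported
#' together with a 95% normal-approximation confidence half-width
#' (1.96 * sd / sqrt(n)) and the average gene length of the bin. Genes
#' present in only one of the expression matrix and the length table are
#' dropped (inner join) with a message.
#'
#' @param em an [expression_matrix] (typically TPM or qsmooth-normalized
#'   TPM); replicate samples are collapsed to tissue means first
#' @param lengths named numeric vector, gene id -> length in bp
#' @param n_bins number of length bins (default 100)
#' @param transform transform applied to tissue-mean expression before
#'   averaging (default [cube_root])
#' @param bin_method passed to [assign_length_bins]
#' @return tibble with `tissue`, `group`, `bin_index`, `mean_length_bp`,
#'   `mean_expression`, `ci_half_width`, `n_genes`
#' @export
profile_expression_vs_length <- function(em, lengths, n_bins = 100,
                                         transform = cube_root,
                                         bin_method = "equal_count") {
  tm <- tissue_means(em)
  shared <- intersect(rownames(tm), names(lengths))
  dropped <- (nrow(tm) - length(shared)) + (length(lengths) - length(shared))
  if (dropped > 0) {
    message(dropped, " gene(s) absent from matrix or length table were dropped")
  }
  if (length(shared) < n_bins) stop("fewer shared genes than bins")
  tm <- tm[shared, , drop = FALSE]
  len <- lengths[shared]
  bins <- assign_length_bins(len, n_bins, method = bin_method)
  vals <- transform(unclass(tm))

  groups <- em$tissue_group
  res <- lapply(colnames(tm), function(t) {
    df <- tibble::tibble(bin_index = unname(bins), length_bp = unname(len),
                         expr = vals[, t])
    out <- dplyr::summarise(
      dplyr::group_by(df, .data$bin_index),
      mean_length_bp = mean(.data$length_bp),
      mean_expression = mean(.data$expr),
      ci_half_width = ifelse(dplyr::n() > 1,
                             1.96 * stats::sd(.data$expr) / sqrt(dplyr::n()), 0),
      n_genes = dplyr::n(), .groups = "drop")
    out$tissue <- t
    out$group <- unname(groups[t])
    out
  })
  out <- dplyr::bind_rows(res)
  out[, c("tissue", "group", "bin_index", "mean_length_bp",
          "mean_expression", "ci_half_width", "n_genes")]
}

#' Gene-length percentile profiles
#'
#' The percentile variant of [profile_expression_vs_length]: identical
#' equal-count partition, with the bin index read as a length percentile.
#' Because the partition is rank-based it is invariant to any monotone
#' transform of the lengths.
#'
#' @inheritParams profile_expression_vs_length
#' @return as [profile_expression_vs_length], with attribute
#'   `bin_type = "percentile"`
#' @export
percentile_profile <- function(em, lengths, n_bins = 100,
                               transform = cube_root) {
  out <- profile_expression_vs_length(em, lengths, n_bins = n_bins,
                                      transform = transform,
                                      bin_method = "equal_count")
  attr(out, "bin_type") <- "percentile"
  out
}

#' Top-minus-bottom decile group contrast of a length profile
#'
#' Summary statistic for planted-effect recovery: the neuronal-minus-
#' non-neuronal difference of bin-mean expression, averaged over the top
#' decile of length bins, minus the same difference over the bottom
#' decile. Positive values mean the longest genes are preferentially
#' expressed in neuronal tissues.
#'
#' @param profile output of [profile_expression_vs_length]
#' @param decile fraction of bins in each tail (default 0.1)
#' @return a single numeric contrast
#' @export
profile_decile_contrast <- function(profile, decile = 0.1) {
  by_group <- dplyr::summarise(
    dplyr::group_by(profile, .data$group, .data$bin_index),
    expr = mean(.data$mean_expression), .groups = "drop")
  wide <- tidyr::pivot_wider(by_group, names_from = "group",
                             values_from = "expr")
  if (!all(c("neuronal", "non_neuronal") %in% names(wide))) {
    stop("profile must contain both neuronal and non_neuronal tissues")
  }
  nb <- max(wide$bin_index)
  k <- max(1L, floor(decile * nb))
  diff <- wide$neuronal - wide$non_neuronal
  ord <- order(wide$bin_index)
  diff <- diff[ord]
  mean(diff[(nb - k + 1L):nb]) - mean(diff[seq_len(k)])
}
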