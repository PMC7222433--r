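#' Expression matrix with tissue and group metadata
#'
#' Container for a gene x sample matrix plus the two maps the analysis
#' needs: sample -> tissue and tissue -> group (`neuronal` or
#' `non_neuronal`). Values must be non-negative; units are tracked so
#' downstream steps can check they receive what they expect.
#'
#' @param values numeric matrix, rownames = gene ids, colnames = sample ids
#' @param sample_tissue named character vector mapping sample -> tissue
#' @param tissue_group named character vector mapping tissue ->
#'   `"neuronal"`/`"non_neuronal"`
#' @param units one of `"counts"`, `"TPM"`, `"qsmooth_TPM"`
#' @return an object of class `expression_matrix`
#' @export
expression_matrix <- function(values, sample_tissue, tissue_group,
                              units = c("counts", "TPM", "qsmooth_TPM")) {
  units <- match.arg(units)
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have gene rownames and sample colnames")
  }
  if (any(values < 0)) stop("expression values must be non-negative")
  missing_tissue <- setdiff(colnames(values), names(sample_tissue))
  if (length(missing_tissue)) {
    stop("sample(s) without a tissue: ", paste(missing_tissue, collapse = ", "))
  }
  tissues <- unique(unname(sample_tissue[colnames(values)]))
  missing_group <- setdiff(tissues, names(tissue_group))
  if (length(missing_group)) {
    stop("tissue(s) without a group: ", paste(missing_group, collapse = ", "))
  }
  if (!all(tissue_group %in% c("neuronal", "non_neuronal"))) {
    stop("tissue groups must be 'neuronal' or 'non_neuronal'")
  }
  structure(list(values = values,
                 sample_tissue = sample_tissue[colnames(values)],
                 tissue_group = tissue_group,
                 units = units),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%s), %d tissues\n",
              nrow(x$values), ncol(x$values), x$units,
              length(unique(x$sample_tissue))))
  invisible(x)
}

sample_groups <- function(em) {
  unname(em$tissue_group[em$sample_tissue[colnames(em$values)]])
}

#' TPM normalization
#'
#' Transcripts per million: per sample, each gene's count is divided by
#' its effective length to give a rate, and rates are rescaled to sum to
#' 10^6. Every column of the result sums to 10^6 by construction.
#'
#' @param em an [expression_matrix] in `counts` units
#' @param lengths named numeric vector of effective gene lengths in bp
#'   (typically the union exonic content from [architecture_table])
#' @return an [expression_matrix] in `TPM` units
#' @export
tpm_normalize <- function(em, lengths) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$units != "counts") stop("tpm_normalize expects counts")
  genes <- rownames(em$values)
  miss <- setdiff(genes, names(lengths))
  if (length(miss)) stop("gene(s) missing from length table: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  len <- lengths[genes]
  if (any(len <= 0)) stop("non-positive effective length for gene(s): ",
                          paste(genes[len <= 0][1], collapse = ", "))
  rates <- em$values / len
  totals <- colSums(rates)
  zero <- colnames(em$values)[totals == 0]
  if (length(zero)) stop("all-zero sample column(s): ",
                         paste(zero, collapse = ", "))
  tpm <- sweep(rates, 2, totals, "/") * 1e6
  expression_matrix(tpm, em$sample_tissue, em$tissue_group, units = "TPM")
}

#' Smooth quantile normalization
#'
#' A generalization of quantile normalization that assumes each sample's
#' statistical distribution is the same *within* biological groups but may
#' differ between them. Each sample's sorted values are replaced by a
#' rank-wise convex combination of the overall reference quantile (the
#' cross-sample mean at that rank) and the sample's group-specific
#' quantile, weighted by `w_k`: the running-median smoothing, over a
#' window of `ceil(window_fraction * n)` ranks, of `1 - SSB_k/SST_k`,
#' where SSB is the between-group and SST the total sum of squares of the
#' rank-k values (clipped to [0,1]; ranks with SST = 0 get weight 1).
#' With a single group every weight is 1 and the procedure reduces to
#' ordinary quantile normalization. Tied input values receive the mean of
#' their ranks' normalized values, so within-sample rank order is
#' preserved up to ties.
#'
#' Groups are taken from the tissue -> group map via each sample's tissue.
#'
#' @param em an [expression_matrix] with at least 2 samples and 2 genes
#' @param window_fraction running-median window as a fraction of the
#'   number of ranks (default 0.05)
#' @return an [expression_matrix] with the same units tagged
#'   `qsmooth_TPM` when the input was TPM
#' @export
qsmooth_normalize <- function(em, window_fraction = 0.05) {
  stopifnot(inherits(em, "expression_matrix"))
  X <- em$values
  n <- nrow(X); S <- ncol(X)
  if (n < 2L) stop("need at least 2 genes to normalize a distribution")
  if (S < 2L) stop("need at least 2 samples")
  if (window_fraction <= 0 || window_fraction > 1) {
    stop("window_fraction must be in (0, 1]")
  }
  groups <- sample_groups(em)

  ord <- apply(X, 2, order)               # stable: ties keep row order
  Q <- matrix(0, n, S)
  for (s in seq_len(S)) Q[, s] <- X[ord[, s], s]
  Qref <- rowMeans(Q)

  glev <- unique(groups)
  Qhat <- matrix(0, n, length(glev), dimnames = list(NULL, glev))
  for (g in glev) {
    Qhat[, g] <- rowMeans(Q[, groups == g, drop = FALSE])
  }
  SST <- rowSums((Q - Qref)^2)
  ng <- table(factor(groups, levels = glev))
  SSB <- as.vector((Qhat - Qref)^2 %*% as.numeric(ng))
  w_raw <- ifelse(SST == 0, 1, 1 - SSB / SST)
  w_raw <- pmin(pmax(w_raw, 0), 1)

  k <- ceiling(window_fraction * n)
  if (k %% 2 == 0) k <- k + 1L
  k <- max(1L, min(k, if (n %% 2 == 1L) n else n - 1L))
  w <- if (k >= 3L) as.numeric(stats::runmed(w_raw, k)) else w_raw
  w <- pmin(pmax(w, 0), 1)

  out <- X
  for (s in seq_len(S)) {
    norm_sorted <- w * Qref + (1 - w) * Qhat[, groups[s]]
    v <- numeric(n)
    v[ord[, s]] <- norm_sorted
    out[, s] <- stats::ave(v, X[, s], FUN = mean)  # ties -> mean of ranks
  }
  units <- if (em$units == "TPM") "qsmooth_TPM" else em$units
  expression_matrix(out, em$sample_tissue, em$tissue_group, units = units)
}

#' Cube-root transform
#'
#' The display transform used for expression-versus-length profiles:
#' element-wise x^(1/3). Strictly monotone, maps 0 to 0.
#'
#' @param x non-negative numeric vector/matrix, or an [expression_matrix]
#' @return same shape as input
#' @export
cube_root <- function(x) {
  if (inherits(x, "expression_matrix")) {
    x$values <- cube_root(x$values)
    return(x)
  }
  if (any(x < 0)) stop("cube_root expects non-negative values")
  x^(1 / 3)
}
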