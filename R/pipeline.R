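#' Pipeline configuration
#'
#' Single source of parameters for [run_pipeline]. Defaults mirror the
#' analysis's stated choices: 100 length bins, loess span 0.1,
#' fold-difference thresholds 2 and 5, 50x enrichment filter, exon-span
#' gene length. When no annotation/expression paths are given the
#' synthetic generator (seeded from `seed`) provides the inputs.
#'
#' @param out_dir output directory
#' @param seed RNG seed for synthetic inputs
#' @param annotation optional annotation path (`NULL` = synthetic genome)
#' @param annotation_format `"gff3"`, `"gtf"` or `"biomart_tsv"`
#' @param biotype_filter biotype to keep (default `"protein_coding"`;
#'   `NULL` keeps everything)
#' @param counts,metadata optional expression TSV paths (`NULL` =
#'   synthetic expression; requires a synthetic genome)
#' @param lengths optional TSV (`gene_id`, `length_bp`) of effective
#'   lengths for TPM; default is the union exonic content
#' @param length_method `"exon_span"` or `"genomic_span"`
#' @param n_bins,loess_span,fold_thresholds,ratio_filter,qsmooth,
#'   qsmooth_window,max_ordinal,min_n analysis parameters (see the
#'   respective functions)
#' @param synthetic a [synthetic_spec] for generated inputs
#' @return a list of class `run_config`
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            annotation = NULL,
                            annotation_format = "gff3",
                            biotype_filter = "protein_coding",
                            counts = NULL,
                            metadata = NULL,
                            lengths = NULL,
                            length_method = "exon_span",
                            n_bins = 100,
                            loess_span = 0.1,
                            fold_thresholds = c(2, 5),
                            ratio_filter = 50,
                            qsmooth = TRUE,
                            qsmooth_window = 0.05,
                            max_ordinal = 20,
                            min_n = 25,
                            synthetic = synthetic_spec(seed = seed)) {
  cfg <- as.list(environment())
  for (p in c("annotation", "counts", "metadata", "lengths")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop("input file not found: ", cfg[[p]])
    }
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config]; a `synthetic` mapping
#' is forwarded to [synthetic_spec]. Unknown keys are an error.
#'
#' @param path YAML file
#' @param out_dir overrides the `out_dir` key when given
#' @return a `run_config`
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(out_dir)) raw$out_dir <- out_dir
  if (!is.null(raw$synthetic)) {
    raw$synthetic <- do.call(synthetic_spec, raw$synthetic)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — annotation (or synthetic
#' genome) -> architecture and intron tables -> TPM (and optionally
#' smooth quantile) normalization -> tissue enrichment -> length and
#' intron-ordinal profiles -> multi-species clade statistics — writing
#' one TSV per product plus a `manifest.json` recording parameters, input
#' checksums and the per-filter gene ledger. Reruns with the same
#' configuration and seed produce byte-identical outputs.
#'
#' @param config a `run_config` from [pipeline_config] /
#'   [read_pipeline_config]
#' @return the manifest list, invisibly; files land in `config$out_dir`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(parameters = config[setdiff(names(config), "synthetic")],
                   synthetic = unclass(config$synthetic),
                   inputs = list(), counts = list())

  # --- annotation stage -----------------------------------------------
  if (is.null(config$annotation)) {
    genome <- generate_genome(config$synthetic)
    models <- genome$models
    truth <- genome$truth
    write_gff3(models, out("genome.gff3"))
    readr::write_tsv(truth, out("genome_truth.tsv"))
  } else {
    models <- parse_annotation(config$annotation, config$annotation_format,
                               biotype_filter = config$biotype_filter)
    truth <- NULL
    manifest$inputs$annotation <-
      unname(tools::md5sum(config$annotation))
  }
  arch <- architecture_table(models, length_method = config$length_method)
  introns <- infer_introns(models)
  readr::write_tsv(arch, out("architecture.tsv"))
  readr::write_tsv(introns, out("introns.tsv"))
  manifest$counts$genes_annotated <- nrow(arch)

  # --- expression stage -----------------------------------------------
  if (is.null(config$counts)) {
    if (is.null(truth)) {
      stop("synthetic expression needs a synthetic genome; provide counts")
    }
    ex <- generate_expression(config$synthetic, truth)
    em <- ex$counts
    write_expression_tsv(em, out("counts.tsv"))
    write_metadata_tsv(em, out("metadata.tsv"))
  } else {
    if (is.null(config$metadata)) stop("counts given without metadata")
    em <- read_expression_tsv(config$counts, config$metadata)
    manifest$inputs$counts <- unname(tools::md5sum(config$counts))
    manifest$inputs$metadata <- unname(tools::md5sum(config$metadata))
  }
  if (is.null(config$lengths)) {
    eff_len <- stats::setNames(arch$exonic_bp, arch$gene_id)
  } else {
    lt <- readr::read_tsv(config$lengths, show_col_types = FALSE)
    eff_len <- stats::setNames(lt$length_bp, lt$gene_id)
    manifest$inputs$lengths <- unname(tools::md5sum(config$lengths))
  }
  shared <- intersect(rownames(em$values), names(eff_len))
  manifest$counts$genes_expression <- nrow(em$values)
  manifest$counts$genes_shared <- length(shared)
  em$values <- em$values[shared, , drop = FALSE]
  tpm <- tpm_normalize(em, eff_len[shared])
  norm <- if (isTRUE(config$qsmooth)) {
    qsmooth_normalize(tpm, window_fraction = config$qsmooth_window)
  } else tpm
  write_expression_tsv(norm, out("tpm.tsv"))

  # --- enrichment stage -----------------------------------------------
  tt <- tissue_means(norm)
  enr <- withCallingHandlers(
    score_enrichment(tt, fold_thresholds = config$fold_thresholds,
                     ratio_filter = config$ratio_filter),
    message = function(m) invokeRestart("muffleMessage"))
  readr::write_tsv(enr, out("enrichment.tsv"))
  manifest$counts$genes_all_zero <- sum(is.na(enr$fold_difference))
  manifest$counts$genes_fold_defined <- sum(!is.na(enr$fold_difference))
  manifest$counts$genes_pass_50x <- sum(enr$passes_50x, na.rm = TRUE)
  manifest$counts$genes_fail_50x <-
    manifest$counts$genes_fold_defined - manifest$counts$genes_pass_50x

  # --- profiles stage -------------------------------------------------
  gl <- gene_length(models, config$length_method)
  lengths <- stats::setNames(gl$length_bp, gl$gene_id)
  prof <- suppressMessages(
    profile_expression_vs_length(norm, lengths, n_bins = config$n_bins))
  readr::write_tsv(prof, out("length_profile.tsv"))
  pct <- suppressMessages(
    percentile_profile(norm, lengths, n_bins = config$n_bins))
  readr::write_tsv(pct, out("length_percentile_profile.tsv"))
  smooth_tab <- dplyr::bind_rows(lapply(split(prof, prof$group), function(p) {
    bins <- dplyr::summarise(dplyr::group_by(p, .data$bin_index),
                             mean_length_bp = mean(.data$mean_length_bp),
                             mean_expression = mean(.data$mean_expression),
                             .groups = "drop")
    bins$smoothed_expression <- suppressMessages(
      loess_smooth(log10(bins$mean_length_bp), bins$mean_expression,
                   span = config$loess_span))
    bins$group <- p$group[1]
    bins
  }))
  readr::write_tsv(smooth_tab, out("length_profile_loess.tsv"))
  manifest$counts$genes_profiled <- sum(prof$n_genes[prof$tissue ==
                                                       prof$tissue[1]])

  iprof <- lapply(c("lt2", "gt5"), function(fc) {
    tryCatch(ordinal_profile(introns, enr, fold_class = fc,
                             max_ordinal = config$max_ordinal,
                             min_n = config$min_n),
             error = function(e) NULL)
  })
  iprof <- dplyr::bind_rows(iprof)
  readr::write_tsv(iprof, out("intron_profile.tsv"))

  # --- clade stage ----------------------------------------------------
  ms <- generate_multispecies(config$synthetic)
  summaries <- dplyr::bind_rows(lapply(names(ms$tables), function(sp) {
    cl <- ms$clade_map$clade[ms$clade_map$species == sp]
    species_summary(ms$tables[[sp]], sp, cl)
  }))
  readr::write_tsv(summaries, out("species_summary.tsv"))
  clades <- dplyr::bind_rows(
    dplyr::mutate(clade_aggregate(summaries, "median_length_all"),
                  statistic = "median_length_all"),
    dplyr::mutate(clade_aggregate(summaries, "median_length_top10"),
                  statistic = "median_length_top10"))
  readr::write_tsv(clades, out("clade_summary.tsv"))

  top_clade <- clades$clade[clades$statistic == "median_length_all"]
  top_clade <- top_clade[which.max(
    clades$mean_of_medians[clades$statistic == "median_length_all"])]
  sp_top <- ms$clade_map$species[ms$clade_map$clade == top_clade]
  len_a <- unlist(lapply(ms$tables[sp_top], `[[`, "gene_length_bp"),
                  use.names = FALSE)
  len_b <- unlist(lapply(ms$tables[setdiff(names(ms$tables), sp_top)],
                         `[[`, "gene_length_bp"), use.names = FALSE)
  cmp <- compare_species_groups(len_a, len_b)
  manifest$clade_comparison <- list(clade = top_clade, U = cmp$U, z = cmp$z,
                                    p_value = cmp$p_value)

  manifest$counts$ledger_consistent <-
    manifest$counts$genes_fold_defined + manifest$counts$genes_all_zero ==
    manifest$counts$genes_shared
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
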