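test_that("GFF3 and GTF encodings of one gene parse to the same model", {
  gff <- c("##gff-version 3",
           "chr1\tsrc\tgene\t101\t400\t.\t+\t.\tID=g1;biotype=protein_coding",
           "chr1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=t1;Parent=g1",
           "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=t1",
           "chr1\tsrc\texon\t301\t400\t.\t+\t.\tParent=t1")
  gtf <- c(paste0("chr1\tsrc\texon\t101\t200\t.\t+\t.\t",
                  'gene_id "g1"; transcript_id "t1"; gene_biotype "protein_coding";'),
           paste0("chr1\tsrc\texon\t301\t400\t.\t+\t.\t",
                  'gene_id "g1"; transcript_id "t1"; gene_biotype "protein_coding";'))
  f1 <- withr::local_tempfile(fileext = ".gff3")
  f2 <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gff, f1); writeLines(gtf, f2)

  m1 <- parse_annotation(f1, "gff3", biotype_filter = "protein_coding")
  m2 <- parse_annotation(f2, "gtf", biotype_filter = "protein_coding")
  expect_equal(gene_length(m1, "exon_span")$length_bp, 300)
  expect_equal(nrow(m1$exons), 2)
  a1 <- architecture_table(m1)
  a2 <- architecture_table(m2)
  expect_equal(a1, a2, ignore_attr = TRUE)
  expect_equal(a1$exonic_bp, 200)
  expect_equal(a1$intronic_bp, 100)
})

test_that("malformed annotations are rejected with informative errors", {
  bad <- c("##gff-version 3", "chr1\tsrc\tgene\t1\t100")
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(bad, f)
  expect_error(parse_annotation(f, "gff3"), "line 2")

  expect_error(
    make_models(gene_id = "g", transcript_id = "t", chrom = "chr1",
                strand = "+", start = 100, end = 100),
    "end <= start")
  expect_error(
    make_models(gene_id = "g", transcript_id = c("t", "t"),
                chrom = c("chr1", "chr2"), strand = "+",
                start = c(0, 500), end = c(100, 600)),
    "multiple chroms/strands")
  expect_error(
    make_models(gene_id = "g", transcript_id = "t", chrom = "chr1",
                strand = "+", start = c(0, 100), end = c(100, 200)),
    "zero-length intron")
  expect_warning(
    m <- gene_models(tibble::tibble(
      gene_id = "g", transcript_id = "t", chrom = "chr1", strand = "+",
      start = c(0, 100), end = c(100, 200)), strict = FALSE),
    "merged")
  expect_equal(nrow(m$exons), 1)
  expect_equal(m$exons$end - m$exons$start, 200)
})

test_that("gene_length matches a brute-force scan over every exon", {
  set.seed(41)
  for (r in 1:20) {
    ex <- random_gene_exons(sprintf("g%02d", r))
    m <- gene_models(ex)
    expect_equal(gene_length(m, "exon_span")$length_bp,
                 max(ex$end) - min(ex$start))
  }
  # single exon
  m <- make_models(gene_id = "g", transcript_id = "t", chrom = "c",
                   strand = "+", start = 0, end = 150)
  expect_equal(gene_length(m)$length_bp, 150)
})

test_that("genomic_span uses record-level gene coordinates when present", {
  m <- gene_models(
    tibble::tibble(gene_id = "g", transcript_id = "t", chrom = "c",
                   strand = "+", start = c(100, 300), end = c(200, 400)),
    genes = tibble::tibble(gene_id = "g", record_start = 50, record_end = 450))
  expect_equal(gene_length(m, "exon_span")$length_bp, 300)
  expect_equal(gene_length(m, "genomic_span")$length_bp, 400)
})

test_that("introns come from exon gaps with strand-aware ordinals", {
  m <- make_models(gene_id = "g", transcript_id = "t", chrom = "c",
                   strand = "+", start = 0, end = 100)
  expect_equal(nrow(infer_introns(m)), 0)

  plus <- make_models(gene_id = "g", transcript_id = "t", chrom = "c",
                      strand = "+", start = c(0, 200, 400),
                      end = c(100, 250, 500))
  ip <- infer_introns(plus)
  expect_equal(ip$length_bp, c(100, 150))
  expect_equal(ip$ordinal, c(1L, 2L))

  minus <- make_models(gene_id = "g", transcript_id = "t", chrom = "c",
                       strand = "-", start = c(0, 200, 400),
                       end = c(100, 250, 500))
  im <- infer_introns(minus)
  expect_equal(im$length_bp, c(100, 150))
  expect_equal(im$ordinal, c(2L, 1L))

  # mirror-image oracle: reflected minus-strand gene has the same profile
  mirrored <- mirror_models(plus)
  imir <- infer_introns(mirrored)
  expect_equal(imir[order(imir$ordinal), c("ordinal", "length_bp")],
               ip[order(ip$ordinal), c("ordinal", "length_bp")])
})

test_that("exon_union merges overlapping and touching intervals", {
  m <- gene_models(tibble::tibble(
    gene_id = "g", transcript_id = c("t1", "t2"), chrom = "c", strand = "+",
    start = c(0, 50), end = c(100, 150)))
  expect_equal(exon_union(m)[, c("start", "end")],
               tibble::tibble(start = 0, end = 150))

  m2 <- gene_models(tibble::tibble(
    gene_id = "g", transcript_id = c("t1", "t2"), chrom = "c", strand = "+",
    start = c(0, 100), end = c(100, 200)))
  expect_equal(exon_union(m2)[, c("start", "end")],
               tibble::tibble(start = 0, end = 200))
})

test_that("exon_union equals the per-base membership oracle on random isoforms", {
  set.seed(42)
  for (r in 1:10) {
    ex <- random_gene_exons("g", n_tx = 20, max_exons = 6, max_span = 5e3)
    m <- gene_models(ex)
    got <- exon_union(m)
    want <- oracle_intervals(oracle_exonic_positions(ex))
    expect_equal(got[, c("start", "end")], want)
  }
})

test_that("architecture identities hold and match the worked examples", {
  single <- make_models(gene_id = "g", transcript_id = "t", chrom = "c",
                        strand = "+", start = 0, end = 150)
  a <- architecture_table(single)
  expect_equal(a$intronic_bp, 0)
  expect_equal(a$exonic_bp, a$gene_length_bp)

  two <- gene_models(tibble::tibble(
    gene_id = "g", transcript_id = c("t1", "t1", "t2", "t2"),
    chrom = "c", strand = "+",
    start = c(0, 200, 0, 400), end = c(100, 300, 100, 500)))
  a2 <- architecture_table(two)
  expect_equal(a2$exonic_bp, 300)
  expect_equal(a2$gene_length_bp, 500)
  expect_equal(a2$intronic_bp, 200)
  expect_equal(a2$n_exons_union, 3L)
  expect_equal(a2$mean_exons_per_transcript, 2)

  # conservation identity on a synthetic genome
  g <- generate_genome(synthetic_spec(seed = 11, n_genes = 500))
  arch <- architecture_table(g$models)
  expect_true(all(arch$exonic_bp + arch$intronic_bp == arch$gene_length_bp))
  expect_true(all(arch$exonic_bp >= 1))
})

test_that("per-transcript exon/intron lengths partition the transcript span", {
  g <- generate_genome(synthetic_spec(seed = 12, n_genes = 100))
  introns <- infer_introns(g$models)
  ex <- g$models$exons
  per_tx_ex <- dplyr::summarise(
    dplyr::group_by(ex, transcript_id),
    exon_sum = sum(end - start),
    span = max(end) - min(start),
    n_exons = dplyr::n(), .groups = "drop")
  per_tx_in <- dplyr::summarise(
    dplyr::group_by(introns, transcript_id),
    intron_sum = sum(length_bp), n_introns = dplyr::n(),
    .groups = "drop")
  j <- dplyr::left_join(per_tx_ex, per_tx_in, by = "transcript_id")
  j$intron_sum[is.na(j$intron_sum)] <- 0
  j$n_introns[is.na(j$n_introns)] <- 0
  expect_true(all(j$n_introns == j$n_exons - 1))
  expect_true(all(j$exon_sum + j$intron_sum == j$span))
})

test_that("transcription time follows length over elongation rate", {
  expect_equal(transcription_time(10000, 1000), 10)
  t_long <- transcription_time(2.3e6, 1000)
  expect_equal(t_long, 2300)
  expect_gt(minutes_to_hours(t_long), 10)
  expect_equal(transcription_time(0, 500), 0)
  expect_error(transcription_time(1000, 0), "positive")
})
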