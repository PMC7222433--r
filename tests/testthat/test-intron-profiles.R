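make_enr <- function(gene_id, group, fold = 100, pass = TRUE) {
  tibble::tibble(gene_id = gene_id, group_of_max = group,
                 fold_difference = fold, passes_50x = pass)
}

test_that("ordinal profile splits strata by group of maximal expression", {
  introns <- tibble::tibble(
    gene_id = c("gn", "gn", "gx", "gx"),
    transcript_id = c("gn.t1", "gn.t1", "gx.t1", "gx.t1"),
    ordinal = c(1L, 2L, 1L, 2L),
    length_bp = c(1000, 100, 100, 100))
  enr <- make_enr(c("gn", "gx"), c("neuronal", "non_neuronal"))
  prof <- ordinal_profile(introns, enr, fold_class = "gt5",
                          max_ordinal = 5, min_n = 1)
  neur <- prof[prof$group == "neuronal", ]
  expect_equal(neur$mean_length_bp[neur$ordinal == 1], 1000)
  expect_equal(neur$mean_length_bp[neur$ordinal == 2], 100)
  expect_equal(prof$mean_length_bp[prof$group == "non_neuronal"], c(100, 100))
  # single intron per stratum: se 0, n 1
  expect_true(all(prof$se_bp == 0))
  expect_true(all(prof$n == 1L))

  expect_equal(first_intron_ratio(neur, prof[prof$group == "non_neuronal", ]),
               10)
  expect_equal(first_intron_ratio(neur, neur), 1)
  expect_error(first_intron_ratio(neur[neur$ordinal == 2, ], neur),
               "ordinal-1")
})

test_that("genes failing the enrichment filter are excluded", {
  introns <- tibble::tibble(
    gene_id = c("g1", "g2"), transcript_id = c("g1.t1", "g2.t1"),
    ordinal = c(1L, 1L), length_bp = c(500, 9000))
  enr <- make_enr(c("g1", "g2"), "neuronal", pass = c(TRUE, FALSE))
  prof <- ordinal_profile(introns, enr, fold_class = "gt5",
                          max_ordinal = 5, min_n = 1)
  expect_equal(prof$mean_length_bp, 500)
  expect_equal(prof$n, 1L)
  expect_error(
    ordinal_profile(introns, make_enr("zz", "neuronal"), min_n = 1),
    "no introns left")
})

test_that("pooled strata reproduce the unstratified means, n-weighted", {
  g <- generate_genome(synthetic_spec(seed = 51, n_genes = 400))
  introns <- infer_introns(g$models)
  enr <- make_enr(g$truth$gene_id,
                  ifelse(g$truth$is_neuronal_long, "neuronal",
                         "non_neuronal"))
  prof <- ordinal_profile(introns, enr, fold_class = "all",
                          max_ordinal = 6, min_n = 1)
  pooled <- dplyr::summarise(
    dplyr::group_by(prof, ordinal),
    mean_all = sum(mean_length_bp * n) / sum(n), .groups = "drop")
  direct <- dplyr::summarise(
    dplyr::group_by(introns[introns$ordinal <= 6, ], ordinal),
    mean_all = mean(length_bp), .groups = "drop")
  expect_equal(pooled$mean_all, direct$mean_all)
})

test_that("relaxing the fold-class selector never shrinks stratum sizes", {
  set.seed(52)
  n <- 300
  introns <- tibble::tibble(
    gene_id = rep(sprintf("g%03d", 1:n), each = 2),
    transcript_id = rep(sprintf("g%03d.t1", 1:n), each = 2),
    ordinal = rep(1:2, n),
    length_bp = rlnorm(2 * n, 7, 1))
  enr <- make_enr(sprintf("g%03d", 1:n),
                  sample(c("neuronal", "non_neuronal"), n, TRUE),
                  fold = rlnorm(n, 1.5, 1))
  p5 <- ordinal_profile(introns, enr, fold_class = "gt5",
                        max_ordinal = 2, min_n = 1)
  p2 <- ordinal_profile(introns, enr, fold_class = "gt2",
                        max_ordinal = 2, min_n = 1)
  j <- dplyr::inner_join(p5, p2, by = c("group", "ordinal"),
                         suffix = c("_5", "_2"))
  expect_true(all(j$n_2 >= j$n_5))
})

test_that("profiles are invariant under coordinate translation", {
  g <- generate_genome(synthetic_spec(seed = 53, n_genes = 100))
  ex <- g$models$exons
  shifted <- gene_models(dplyr::mutate(ex, start = start + 12345,
                                       end = end + 12345))
  enr <- make_enr(g$truth$gene_id,
                  ifelse(g$truth$is_neuronal_long, "neuronal",
                         "non_neuronal"))
  p0 <- ordinal_profile(infer_introns(g$models), enr, fold_class = "all",
                        max_ordinal = 8, min_n = 1)
  p1 <- ordinal_profile(infer_introns(shifted), enr, fold_class = "all",
                        max_ordinal = 8, min_n = 1)
  expect_equal(p0, p1)
})
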