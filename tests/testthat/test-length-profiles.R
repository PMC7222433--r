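test_that("equal-count length bins have near-equal sizes in length order", {
  lens <- stats::setNames(1:100 * 10, sprintf("g%03d", 1:100))
  b <- assign_length_bins(lens, 100)
  expect_equal(unname(b), 1:100)

  lens10 <- stats::setNames(sample(1:10) * 100, sprintf("g%02d", 1:10))
  b2 <- assign_length_bins(lens10, 2)
  expect_true(all(b2[lens10 <= 500] == 1))
  expect_true(all(b2[lens10 > 500] == 2))

  set.seed(31)
  for (r in 1:5) {
    n <- sample(50:300, 1); k <- sample(2:40, 1)
    lens_r <- stats::setNames(rlnorm(n, 8, 1), sprintf("g%04d", 1:n))
    br <- assign_length_bins(lens_r, k)
    sizes <- table(br)
    expect_lte(max(sizes) - min(sizes), 1)
    expect_equal(length(sizes), k)
    # bins ordered by length: max of bin i <= min of bin i+1
    mx <- tapply(lens_r, br, max); mn <- tapply(lens_r, br, min)
    expect_true(all(mx[-k] <= mn[-1]))
  }
  expect_error(assign_length_bins(c(a = 1), 2), "fewer genes")
})

test_that("constant expression gives flat profiles with zero CI width", {
  n <- 60
  v <- matrix(27, n, 2, dimnames = list(sprintf("g%02d", 1:n), c("a", "b")))
  em <- expression_matrix(v, c(a = "a", b = "b"),
                          c(a = "neuronal", b = "non_neuronal"), "TPM")
  lens <- stats::setNames(seq_len(n) * 100, rownames(v))
  prof <- profile_expression_vs_length(em, lens, n_bins = 10)
  expect_true(all(abs(prof$mean_expression - 3) < 1e-12))
  expect_true(all(prof$ci_half_width == 0))
  expect_equal(sum(prof$n_genes[prof$tissue == "a"]), n)
  # bin mean lengths non-decreasing within a tissue
  pa <- prof[prof$tissue == "a", ]
  expect_true(all(diff(pa$mean_length_bp[order(pa$bin_index)]) >= 0))
})

test_that("profiles are invariant to gene and sample order", {
  set.seed(32)
  n <- 120
  v <- matrix(rlnorm(n * 3, 3, 1), n, 3,
              dimnames = list(sprintf("g%03d", 1:n), c("a", "b", "c")))
  em <- expression_matrix(v, c(a = "a", b = "b", c = "c"),
                          c(a = "neuronal", b = "non_neuronal",
                            c = "non_neuronal"), "TPM")
  lens <- stats::setNames(rlnorm(n, 8, 1), rownames(v))
  p0 <- profile_expression_vs_length(em, lens, n_bins = 12)

  perm <- sample(n)
  em2 <- expression_matrix(v[perm, c(3, 1, 2)],
                           c(a = "a", b = "b", c = "c"),
                           c(a = "neuronal", b = "non_neuronal",
                             c = "non_neuronal"), "TPM")
  p1 <- profile_expression_vs_length(em2, lens, n_bins = 12)
  expect_equal(dplyr::arrange(p0, tissue, bin_index),
               dplyr::arrange(p1, tissue, bin_index))
})

test_that("percentile profile is the same partition, invariant to monotone maps", {
  set.seed(33)
  n <- 150
  v <- matrix(rlnorm(n * 2, 3, 1), n, 2,
              dimnames = list(sprintf("g%03d", 1:n), c("a", "b")))
  em <- expression_matrix(v, c(a = "a", b = "b"),
                          c(a = "neuronal", b = "non_neuronal"), "TPM")
  lens <- stats::setNames(rlnorm(n, 8, 1), rownames(v))
  p0 <- profile_expression_vs_length(em, lens, n_bins = 15)
  pp <- percentile_profile(em, lens, n_bins = 15)
  expect_equal(pp$mean_expression, p0$mean_expression)
  expect_equal(pp$n_genes, p0$n_genes)

  pl <- percentile_profile(em, log(lens), n_bins = 15)
  expect_equal(pl$mean_expression, pp$mean_expression)
  expect_equal(pl$n_genes, pp$n_genes)
})

test_that("loess reproduces polynomials and matches closed-form WLS", {
  set.seed(34)
  x <- sort(runif(60, 0, 10))
  y_lin <- 2 + 3 * x
  expect_lt(max(abs(loess_smooth(x, y_lin, span = 0.3, degree = 1) - y_lin)),
            1e-8)
  y_quad <- 1 - x + 0.5 * x^2
  expect_lt(max(abs(loess_smooth(x, y_quad, span = 1, degree = 2) - y_quad)),
            1e-8)
  y_const <- rep(4, 60)
  expect_lt(max(abs(loess_smooth(x, y_const, span = 0.2, degree = 2) - 4)),
            1e-10)

  y <- sin(x) + rnorm(60, 0, 0.2)
  fit <- loess_smooth(x, y, span = 1, degree = 1)
  for (i in c(1, 17, 42, 60)) {
    d <- abs(x - x[i]); dmax <- max(d)
    w <- (1 - (d / dmax)^3)^3
    expect_equal(fit[i], oracle_wls_fit_at(x, y, w, x[i]), tolerance = 1e-8)
  }
  expect_error(loess_smooth(1:3, 1:3, span = 0), "span")
})
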