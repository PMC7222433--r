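test_that("TPM normalization matches hand-computed rates and conserves 1e6", {
  v <- matrix(c(5, 0), 1, 2, dimnames = list("g1", c("s1", "s2")))
  v[1, 2] <- 3
  em <- make_em(v)
  tpm <- tpm_normalize(em, c(g1 = 1000))
  expect_equal(unname(tpm$values[1, ]), c(1e6, 1e6))

  v2 <- matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  tpm2 <- tpm_normalize(make_em(v2), c(g1 = 1000, g2 = 2000))
  expect_equal(unname(tpm2$values[, 1]), c(2e6 / 3, 1e6 / 3))

  n <- 25
  v3 <- matrix(7, n, 3, dimnames = list(sprintf("g%d", 1:n),
                                        c("a", "b", "c")))
  tpm3 <- tpm_normalize(make_em(v3), stats::setNames(rep(500, n),
                                                     rownames(v3)))
  expect_true(all(abs(tpm3$values - 1e6 / n) < 1e-9))

  set.seed(5)
  v4 <- matrix(rpois(200 * 4, 40), 200, 4,
               dimnames = list(sprintf("g%d", 1:200), sprintf("s%d", 1:4)))
  tpm4 <- tpm_normalize(make_em(v4),
                        stats::setNames(runif(200, 200, 5000),
                                        rownames(v4)))
  expect_true(all(abs(colSums(tpm4$values) - 1e6) < 1e6 * 1e-9))
})

test_that("TPM errors name the offending gene or sample", {
  v <- matrix(c(1, 2, 0, 0), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(tpm_normalize(make_em(v), c(g1 = 100)), "g2")
  expect_error(tpm_normalize(make_em(v), c(g1 = 100, g2 = 100)), "s2")
})

test_that("qsmooth with a single group equals quantile normalization", {
  set.seed(9)
  X <- matrix(rlnorm(300 * 5, 2, 1), 300, 5,
              dimnames = list(sprintf("g%d", 1:300), sprintf("s%d", 1:5)))
  em <- make_em(X)  # all samples non_neuronal -> one group
  qn <- qsmooth_normalize(em)
  expect_lt(max(abs(qn$values - oracle_quantile_normalize(X))), 1e-10)
})

test_that("identically distributed groups reduce qsmooth to quantile normalization", {
  set.seed(10)
  base <- rlnorm(400, 2, 1)
  # same values, permuted across genes in each sample
  X <- vapply(1:6, function(i) sample(base), numeric(400))
  dimnames(X) <- list(sprintf("g%d", 1:400), sprintf("s%d", 1:6))
  tissues <- stats::setNames(c("a", "a", "a", "b", "b", "b"), colnames(X))
  groups <- c(a = "neuronal", b = "non_neuronal")
  em <- expression_matrix(X, tissues, groups, "counts")
  qn <- qsmooth_normalize(em)
  expect_lt(max(abs(qn$values - oracle_quantile_normalize(X))), 1e-10)
})

test_that("qsmooth keeps group distributions closer than quantile normalization", {
  set.seed(11)
  n <- 500
  Xa <- matrix(rlnorm(n * 3, 2, 1), n, 3)
  Xb <- matrix(rlnorm(n * 3, 4, 1.5), n, 3)     # different scale
  X <- cbind(Xa, Xb)
  dimnames(X) <- list(sprintf("g%d", 1:n), sprintf("s%d", 1:6))
  tissues <- stats::setNames(c("a", "a", "a", "b", "b", "b"), colnames(X))
  em <- expression_matrix(X, tissues,
                          c(a = "neuronal", b = "non_neuronal"), "counts")
  qs <- qsmooth_normalize(em)$values
  qn <- oracle_quantile_normalize(X)
  # group references: per-rank means within each group of the raw data
  ss_to_group_ref <- function(M, cols) {
    Q <- apply(M[, cols, drop = FALSE], 2, sort)
    ref <- rowMeans(apply(X[, cols, drop = FALSE], 2, sort))
    sum((Q - ref)^2)
  }
  ss_qs <- ss_to_group_ref(qs, 1:3) + ss_to_group_ref(qs, 4:6)
  ss_qn <- ss_to_group_ref(qn, 1:3) + ss_to_group_ref(qn, 4:6)
  expect_lt(ss_qs, ss_qn)
})

test_that("qsmooth preserves within-sample rank order up to ties", {
  set.seed(12)
  X <- matrix(rlnorm(200 * 4), 200, 4,
              dimnames = list(sprintf("g%d", 1:200), sprintf("s%d", 1:4)))
  tissues <- stats::setNames(c("a", "a", "b", "b"), colnames(X))
  em <- expression_matrix(X, tissues,
                          c(a = "neuronal", b = "non_neuronal"), "counts")
  qs <- qsmooth_normalize(em)$values
  for (s in 1:4) {
    expect_equal(order(qs[, s]), order(X[, s]))
  }
  expect_error(qsmooth_normalize(make_em(
    matrix(1, 1, 2, dimnames = list("g1", c("s1", "s2"))))), "2 genes")
})

test_that("cube root is the monotone display transform", {
  expect_equal(cube_root(0), 0)
  expect_equal(cube_root(8), 2)
  expect_equal(cube_root(1e6), 100)
  expect_error(cube_root(-1), "non-negative")
  set.seed(13)
  x <- rlnorm(100)
  expect_equal(order(cube_root(x)), order(x))
})
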