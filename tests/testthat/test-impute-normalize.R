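na_matrix <- function(seed = 1, n = 60, p_na = 0.2, ncol = 4) {
  withr::with_seed(seed, {
    mat <- matrix(rnorm(n * ncol, 25, 2), nrow = n)
    mat[runif(length(mat)) < p_na] <- NA
    mat
  })
}

test_that("tune_sigma = 0 imputes exactly the column q-quantile, whatever the seed", {
  mat <- na_matrix()
  m <- intensity_from_matrix(mat, groups = rep(c("a", "b"), each = 2))
  imp1 <- suppressMessages(impute_minprob(m, q = 0.05, tune_sigma = 0, seed = 1))
  imp2 <- suppressMessages(impute_minprob(m, q = 0.05, tune_sigma = 0, seed = 99))
  expect_identical(im_matrix(imp1), im_matrix(imp2))
  for (j in seq_len(ncol(mat))) {
    qj <- unname(quantile(mat[, j], 0.05, na.rm = TRUE, type = 7))
    filled <- unname(im_matrix(imp1)[is.na(mat[, j]), j])
    expect_equal(filled, rep(qj, length(filled)))
  }
})

test_that("imputation is seed-reproducible and touches exactly the missing cells", {
  mat <- na_matrix(seed = 2)
  m <- intensity_from_matrix(mat, groups = rep(c("a", "b"), each = 2))
  imp1 <- suppressMessages(impute_minprob(m, seed = 7))
  imp2 <- suppressMessages(impute_minprob(m, seed = 7))
  imp3 <- suppressMessages(impute_minprob(m, seed = 8))
  expect_identical(im_matrix(imp1), im_matrix(imp2))
  expect_false(identical(im_matrix(imp1), im_matrix(imp3)))

  # observed cells untouched; previously-missing cells all filled
  obs <- !is.na(mat)
  expect_identical(im_matrix(imp1)[obs], mat[obs])
  expect_false(anyNA(im_matrix(imp1)))
  expect_equal(sum(im_matrix(imp1) != mat, na.rm = TRUE), 0)
  expect_equal(im_stage(imp1), "imputed")
})

test_that("imputed draws follow Normal(mu_j, sigma) (KS test)", {
  withr::with_seed(10, {
    mat <- matrix(rnorm(4000 * 3, 25, 2), ncol = 3)
    mat[sample(4000, 2500), 1] <- NA
  })
  m <- intensity_from_matrix(mat, groups = c("a", "a", "b"))
  imp <- suppressMessages(impute_minprob(m, q = 0.01, tune_sigma = 1, seed = 3))
  params <- attr(imp, "impute_params")
  filled <- im_matrix(imp)[is.na(mat[, 1]), 1]
  ks <- suppressWarnings(ks.test(filled, "pnorm", params$mu[1], params$sigma))
  expect_gt(ks$p.value, 0.01)
})

test_that("columns with fewer than 2 observed values refuse imputation, naming the column", {
  mat <- na_matrix(seed = 3)
  mat[-1, 2] <- NA
  m <- intensity_from_matrix(mat, groups = rep(c("a", "b"), each = 2))
  expect_error(impute_minprob(m, seed = 1), "S2")
})

test_that("quantile normalization matches the hand example and rank-mean definition", {
  mat <- matrix(c(1, 3, 2, 4), ncol = 2)
  m <- intensity_from_matrix(mat, groups = c("a", "b"))
  out <- im_matrix(suppressMessages(quantile_normalize(m)))
  expect_equal(unname(out), matrix(c(1.5, 3.5, 1.5, 3.5), ncol = 2), ignore_attr = TRUE)

  # independent oracle on random complete data: mean of sorted columns
  withr::with_seed(4, big <- matrix(rnorm(200 * 5, 25, 2), ncol = 5))
  mb <- intensity_from_matrix(big, groups = c("a", "a", "a", "b", "b"))
  got <- im_matrix(suppressMessages(quantile_normalize(mb)))
  target <- rowMeans(apply(big, 2, sort))
  for (j in 1:5) {
    expect_equal(unname(got[order(big[, j]), j]), target)
  }
})

test_that("normalization invariants: identical sorted columns, fixed point, rank preservation", {
  withr::with_seed(5, mat <- matrix(rnorm(120 * 4, 25, 2), ncol = 4))
  m <- intensity_from_matrix(mat, groups = rep(c("a", "b"), each = 2))
  out <- im_matrix(suppressMessages(quantile_normalize(m)))
  sorted <- apply(out, 2, sort)
  for (j in 2:4) expect_equal(unname(sorted[, j]), unname(sorted[, 1]))
  for (j in 1:4) expect_equal(unname(rank(out[, j])), unname(rank(mat[, j])))

  # already identical columns are a fixed point
  same <- matrix(rep(sort(rnorm(50, 25, 2)), 3), ncol = 3)
  ms <- intensity_from_matrix(same, groups = c("a", "a", "b"))
  expect_equal(im_matrix(suppressMessages(quantile_normalize(ms))), im_matrix(ms))
})

test_that("missing values stay missing and observed ranks survive normalization", {
  mat <- na_matrix(seed = 6, n = 100)
  m <- intensity_from_matrix(mat, groups = rep(c("a", "b"), each = 2))
  out <- im_matrix(suppressMessages(quantile_normalize(m)))
  expect_identical(unname(is.na(out)), is.na(mat))
  for (j in seq_len(ncol(mat))) {
    obs <- !is.na(mat[, j])
    expect_equal(unname(rank(out[obs, j])), unname(rank(mat[obs, j])))
  }
})

test_that("both pipeline orders run; single-column normalization warns and is a no-op", {
  mat <- na_matrix(seed = 7)
  m <- intensity_from_matrix(mat, groups = rep(c("a", "b"), each = 2))
  a <- suppressMessages(quantile_normalize(impute_minprob(m, seed = 1)))
  b <- suppressMessages(impute_minprob(quantile_normalize(m), seed = 1))
  expect_equal(im_stage(a), "normalized")
  expect_equal(im_stage(b), "imputed")

  one <- intensity_from_matrix(matrix(rnorm(10, 25, 2), ncol = 1), groups = "a")
  expect_warning(out <- quantile_normalize(one), "one sample")
  expect_equal(im_matrix(out), im_matrix(one))
  expect_equal(im_stage(out), "normalized")
})
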