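test_that("two-group fit reproduces hand-computed means, fold change and pooled variance", {
  mat <- matrix(c(10, 12, 7, 9), nrow = 1)
  colnames(mat) <- c("h1", "h2", "l1", "l2")
  m <- intensity_from_matrix(mat, groups = c("H", "H", "L", "L"), stage = "imputed")
  fit <- fit_group_model(m)
  expect_equal(fit$mean_1, 11)
  expect_equal(fit$mean_2, 8)
  expect_equal(fit$log2FC, 3)
  expect_equal(fit$s2, 2) # ((-1)^2+1^2+(-1)^2+1^2)/2
  expect_equal(attr(fit, "d"), 2)
  expect_equal(attr(fit, "v"), 1)

  # constant groups: beta = 2, s2 = 0, d = 4
  mat2 <- matrix(c(10, 10, 10, 8, 8, 8), nrow = 1)
  m2 <- intensity_from_matrix(mat2, groups = rep(c("H", "L"), each = 3), stage = "imputed")
  fit2 <- fit_group_model(m2)
  expect_equal(fit2$log2FC, 2)
  expect_equal(fit2$s2, 0)
  expect_equal(attr(fit2, "d"), 4)

  # permuting sample columns changes nothing
  perm <- m[, c("protein_id", "l1", "h2", "l2", "h1")]
  attr(perm, "stage") <- "imputed"
  attr(perm, "design") <- im_design(m) # same design, matrix columns shuffled
  fitp <- fit_group_model(perm)
  expect_equal(fitp$log2FC, fit$log2FC)
  expect_equal(fitp$s2, fit$s2)
})

test_that("fit errors: missing values, too-small groups, >2 groups without a pair", {
  mat <- matrix(rnorm(20), nrow = 5)
  m <- intensity_from_matrix(mat, groups = c("a", "a", "b", "b"), stage = "imputed")
  mm <- m
  mm[2, 3] <- NA
  attr(mm, "stage") <- "imputed"
  attr(mm, "design") <- im_design(m)
  expect_error(fit_group_model(mm), "missing")

  m1 <- intensity_from_matrix(mat, groups = c("a", "b", "b", "b"), stage = "imputed")
  expect_error(fit_group_model(m1), "at least 2 samples")

  m3 <- intensity_from_matrix(mat, groups = c("a", "a", "b", "c"), stage = "imputed")
  expect_error(fit_group_model(m3), "a, b, c")
})

test_that("variance squeezing matches limma and recovers simulated priors", {
  # equal variances -> infinite prior df, posterior = exp(mean of e)
  eb0 <- squeeze_variances(rep(2, 50), d = 4)
  expect_true(is.infinite(eb0$d0))
  expect_equal(eb0$s2_post, rep(eb0$s02, 50))

  # cross-check against limma::squeezeVar on dispersed variances
  withr::with_seed(20, {
    s2 <- 1 * (4 / stats::rchisq(300, 4)) * (stats::rchisq(300, 4) / 4)
  })
  eb <- squeeze_variances(s2, d = 4)
  sq <- limma::squeezeVar(s2, df = 4)
  expect_equal(eb$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(eb$s02, sq$var.prior, tolerance = 1e-6)
  expect_equal(eb$s2_post, sq$var.post, tolerance = 1e-6)

  # parameter recovery at scale
  withr::with_seed(21, {
    s2_big <- 1 * (4 / stats::rchisq(5000, 4)) * (stats::rchisq(5000, 4) / 4)
  })
  eb_big <- squeeze_variances(s2_big, d = 4)
  expect_lt(abs(eb_big$d0 - 4) / 4, 0.15)
  expect_lt(abs(eb_big$s02 - 1), 0.05)
})

test_that("shrinkage bounds hold and zero variances are handled", {
  withr::with_seed(22, s2 <- stats::rchisq(2000, 3))
  eb <- squeeze_variances(s2, d = 5)
  expect_true(all(eb$s2_post >= pmin(s2, eb$s02) - 1e-12))
  expect_true(all(eb$s2_post <= pmax(s2, eb$s02) + 1e-12))

  s2z <- c(0, 0, s2[1:50])
  ebz <- squeeze_variances(s2z, d = 5)
  expect_equal(ebz$s2_post[1], ebz$d0 * ebz$s02 / (ebz$d0 + 5))
  expect_error(squeeze_variances(c(0, 0, 1), d = 5), "fewer than 2")
})

test_that("moderated t reduces to the pooled t at d0 = 0 and matches limma's eBayes", {
  # heteroscedastic rows so the prior df is moderate (not degenerate)
  withr::with_seed(23, {
    row_sd <- sqrt(1 * 4 / stats::rchisq(50, 4))
    mat <- matrix(rnorm(50 * 6, 25, rep(row_sd, 6)), ncol = 6)
  })
  m <- intensity_from_matrix(mat, groups = rep(c("a", "b"), each = 3), stage = "imputed")
  fit <- fit_group_model(m)
  d <- attr(fit, "d")

  # no-shrinkage limit: ordinary pooled two-sample t
  eb0 <- structure(list(d0 = 0, s02 = 1, s2_post = fit$s2, d = d), class = "lfq_ebayes")
  tt0 <- moderated_t(fit, eb0)
  pooled <- apply(mat, 1, function(x) {
    stats::t.test(x[1:3], x[4:6], var.equal = TRUE)$statistic
  })
  expect_equal(tt0$t, unname(pooled), tolerance = 1e-10)

  # full route equals limma's moderated fit
  eb <- squeeze_variances(fit$s2, d)
  tt <- moderated_t(fit, eb)
  design <- cbind(1, rep(c(1, 0), each = 3))
  lfit <- limma::eBayes(limma::lmFit(mat, design))
  expect_equal(tt$t, unname(lfit$t[, 2]), tolerance = 1e-8)
  expect_equal(tt$p_value, unname(lfit$p.value[, 2]), tolerance = 1e-8)
})

test_that("moderated t hand values and degenerate cases", {
  fit <- structure(
    tibble::tibble(protein_id = c("p1", "p2"), mean_1 = c(3, 5), mean_2 = c(0, 5),
      log2FC = c(3, 0), s2 = c(2, 2)),
    groups = c("a", "b"), d = 2, v = 1, n = c(2, 2),
    class = c("lfq_group_fit", class(tibble::tibble()))
  )
  eb <- structure(list(d0 = 0, s02 = 1, s2_post = c(2, 2), d = 2), class = "lfq_ebayes")
  tt <- moderated_t(fit, eb)
  expect_equal(tt$t[1], 3 / sqrt(2), tolerance = 1e-12)
  expect_equal(tt$t[2], 0)
  expect_equal(tt$p_value[2], 1)

  ebz <- structure(list(d0 = 0, s02 = 0, s2_post = c(0, 0), d = 2), class = "lfq_ebayes")
  ttz <- moderated_t(fit, ebz)
  expect_equal(ttz$t[1], Inf)
  expect_equal(ttz$p_value[1], 0)
  expect_true(ttz$degenerate_variance[1])
  expect_equal(ttz$t[2], 0)

  # d0 = Inf -> normal tail
  ebi <- structure(list(d0 = Inf, s02 = 2, s2_post = c(2, 2), d = 2), class = "lfq_ebayes")
  tti <- moderated_t(fit, ebi)
  expect_equal(tti$p_value[1], 2 * stats::pnorm(-3 / sqrt(2)), tolerance = 1e-12)
})

test_that("BH adjustment equals the brute-force step-up and stats::p.adjust", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.3), 0.3)
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")

  withr::with_seed(24, {
    for (i in 1:50) {
      p <- runif(sample(1:12, 1))
      expect_equal(adjust_bh(p), bh_bruteforce(p))
      expect_equal(adjust_bh(p), stats::p.adjust(p, method = "BH"))
    }
  })
})

test_that("find_dep applies strict thresholds and sorts by adjusted p", {
  m <- gaussian_two_group(200, 3, effect_ids = 1:20, effect = 4, sigma = 0.4, seed = 30)
  de <- suppressMessages(find_dep(m))
  expect_s3_class(de, "lfq_de")
  expect_false(is.unsorted(de$adj_p_value))
  expect_true(all(de$adj_p_value >= de$p_value - 1e-15))
  expect_true(all(
    de$significant == (abs(de$log2FC) > 1 & de$adj_p_value < 0.05)
  ))
  # the planted strong effects dominate the significant set
  expect_gt(sum(de$significant[de$protein_id %in% sprintf("P%04d", 1:20)]), 15)

  # a fold change of exactly the cutoff is NOT significant
  expect_false(1.0 > attr(de, "lfc_cut"))
})

test_that("relabeling the groups negates fold changes and keeps p-values", {
  m <- gaussian_two_group(50, 3, effect_ids = 1:5, effect = 2, sigma = 0.5, seed = 31)
  de_ab <- suppressMessages(find_dep(m, groups = c("A", "B")))
  de_ba <- suppressMessages(find_dep(m, groups = c("B", "A")))
  ord <- match(de_ab$protein_id, de_ba$protein_id)
  expect_equal(de_ab$log2FC, -de_ba$log2FC[ord])
  expect_equal(de_ab$p_value, de_ba$p_value[ord], tolerance = 1e-12)
})

test_that("p-values are approximately uniform under the global null", {
  m <- gaussian_two_group(2000, 3, seed = 32)
  de <- suppressMessages(find_dep(m))
  ks <- suppressWarnings(ks.test(de$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lte(mean(de$significant), 0.01)
})

test_that("DE TSV export carries thresholds as comment lines", {
  m <- gaussian_two_group(30, 3, effect_ids = 1:3, effect = 3, sigma = 0.3, seed = 33)
  de <- suppressMessages(find_dep(m))
  path <- tempfile(fileext = ".tsv")
  write_de_tsv(de, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# contrast", lines)))
  expect_true(any(grepl("^# lfc_cut: 1", lines)))
  body <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  expect_equal(nrow(body), 30)
})
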