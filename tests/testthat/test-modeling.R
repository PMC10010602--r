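# A small complete intensity table with a matching DE result, for
# feature-selection tests with controlled correlations.
de_from_matrix <- function(mat, groups, adj_p) {
  m <- intensity_from_matrix(mat, groups = groups, stage = "imputed")
  de <- structure(
    tibble::tibble(
      protein_id = rownames(mat),
      log2FC = rep(2, nrow(mat)),
      t = rep(5, nrow(mat)),
      p_value = adj_p / 2,
      adj_p_value = adj_p,
      significant = TRUE
    ),
    contrast = unique(groups), lfc_cut = 1, adj_p_cut = 0.05,
    d0 = 4, s02 = 1, d = 4, p_adjust_method = "BH",
    class = c("lfq_de", class(tibble::tibble()))
  )
  de <- de[order(de$adj_p_value), ]
  list(m = m, de = de)
}

test_that("greedy correlation pruning removes the member with larger mean |r|", {
  # f1-f2 correlated 0.95, f1-f3 0.60, f2-f3 0.10 (approximately, by
  # construction below the realized values match the intent)
  withr::with_seed(50, {
    n <- 200
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    f2 <- z1
    f3 <- z2
    f1 <- scale(0.73 * scale(z1) + 0.6 * scale(z2) + 0.33 * rnorm(n))[, 1]
    mat <- rbind(F1 = f1, F2 = f2, F3 = f3) + 25
  })
  r12 <- abs(cor(mat["F1", ], mat["F2", ]))
  r13 <- abs(cor(mat["F1", ], mat["F3", ]))
  r23 <- abs(cor(mat["F2", ], mat["F3", ]))
  expect_gt(r12, 0.6)
  expect_lt(r23, 0.3)
  # mean |r| of F1 exceeds that of F2 -> F1 should be removed
  expect_gt((r12 + r13) / 2, (r12 + r23) / 2)

  fx <- de_from_matrix(mat, groups = rep(c("a", "b"), each = 100),
    adj_p = c(0.001, 0.002, 0.003))
  mf <- suppressMessages(
    select_features(fx$de, fx$m, top_n = 20, corr_cut = min(r12, 0.9) - 0.01)
  )
  expect_setequal(attr(mf, "features")$protein_id, c("F2", "F3"))
})

test_that("feature selection caps at top_n, keeps small panels whole, drops zero variance", {
  withr::with_seed(51, mat <- matrix(rnorm(30 * 10, 25, 1), nrow = 30,
    dimnames = list(sprintf("P%02d", 1:30), NULL)))
  fx <- de_from_matrix(mat, groups = rep(c("a", "b"), each = 5),
    adj_p = seq(0.001, 0.030, by = 0.001))
  mf <- suppressMessages(select_features(fx$de, fx$m, top_n = 20, corr_cut = 0.99))
  expect_lte(nrow(attr(mf, "features")), 20)
  expect_equal(ncol(mf) - 2, nrow(attr(mf, "features")))
  expect_equal(nrow(mf), 10) # samples x features orientation

  small <- de_from_matrix(mat[1:5, , drop = FALSE],
    groups = rep(c("a", "b"), each = 5), adj_p = seq(0.001, 0.005, by = 0.001))
  mf5 <- suppressMessages(select_features(small$de, small$m))
  expect_equal(nrow(attr(mf5, "features")), 5)

  flat <- mat
  flat["P01", ] <- 25 # zero variance
  fz <- de_from_matrix(flat, groups = rep(c("a", "b"), each = 5),
    adj_p = seq(0.001, 0.030, by = 0.001))
  expect_warning(
    suppressMessages(select_features(fz$de, fz$m, corr_cut = 0.99)),
    "zero-variance"
  )
})

test_that("selection is invariant to input ordering of proteins with distinct adjusted p", {
  withr::with_seed(52, mat <- matrix(rnorm(8 * 40, 25, 1), nrow = 8,
    dimnames = list(sprintf("P%d", 1:8), NULL)))
  fx <- de_from_matrix(mat, groups = rep(c("a", "b"), each = 20),
    adj_p = seq(0.001, 0.008, by = 0.001))
  shuffled <- fx$de[sample(8), ]
  attr_keep <- attributes(fx$de)
  shuffled <- structure(shuffled,
    contrast = attr_keep$contrast, lfc_cut = 1, adj_p_cut = 0.05,
    class = class(fx$de)
  )
  mf1 <- suppressMessages(select_features(fx$de, fx$m, corr_cut = 0.8))
  mf2 <- suppressMessages(select_features(shuffled, fx$m, corr_cut = 0.8))
  expect_equal(attr(mf1, "features")$protein_id, attr(mf2, "features")$protein_id)
})

test_that("stratified split honours per-class rounding and determinism", {
  mf <- separable_model_frame(n_per_class = 10)
  sp <- split_data(mf, train_frac = 0.7, seed = 5)
  train_cls <- mf$class[mf$sample_id %in% sp$train]
  test_cls <- mf$class[mf$sample_id %in% sp$test]
  expect_equal(sum(train_cls == "healthy"), 7)
  expect_equal(sum(train_cls == "disease"), 7)
  expect_equal(sum(test_cls == "healthy"), 3)
  expect_equal(sum(test_cls == "disease"), 3)

  # disjoint, complete
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), mf$sample_id)

  sp2 <- split_data(mf, train_frac = 0.7, seed = 5)
  expect_identical(sp, sp2)
  sp3 <- split_data(mf, train_frac = 0.7, seed = 6)
  expect_equal(length(sp3$train), length(sp$train))
  expect_false(identical(sp3$train, sp$train))

  # stratification: per-class train fraction within 1/n_c of target
  expect_lt(abs(mean(train_cls == "healthy") - 0.5), 1 / 10)

  tiny <- mf[c(1, 11:20), ]
  tiny <- structure(tiny,
    features = attr(mf, "features"), classes = attr(mf, "classes"),
    class = class(mf)
  )
  expect_error(split_data(tiny, seed = 1), "at least 2")
})

test_that("ROC and AUC match hand counting, the trapezoid rule and pROC", {
  rr <- roc_auc(c(0.9, 0.8, 0.4, 0.3), c("+", "-", "+", "-"), "+")
  expect_equal(rr$auc, 0.75) # 3 of 4 pos-neg pairs ordered correctly

  perfect <- roc_auc(c(5, 4, 1, 0), c("+", "+", "-", "-"), "+")
  expect_equal(perfect$auc, 1)
  expect_equal(roc_auc(c(0, 1, 4, 5), c("+", "+", "-", "-"), "+")$auc, 0)
  expect_equal(perfect$roc$fpr[1], 0)
  expect_equal(perfect$roc$tpr[1], 0)
  expect_equal(perfect$roc$fpr[nrow(perfect$roc)], 1)
  expect_equal(perfect$roc$tpr[nrow(perfect$roc)], 1)

  trapezoid <- function(roc) {
    sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  }
  withr::with_seed(53, {
    for (i in 1:20) {
      n <- sample(10:40, 1)
      scores <- round(runif(n), 2) # ties likely
      labels <- sample(c("pos", "neg"), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      rr <- roc_auc(scores, labels, "pos")
      expect_equal(rr$auc, trapezoid(rr$roc), tolerance = 1e-12)
      expect_equal(
        rr$auc,
        as.numeric(suppressMessages(pROC::auc(pROC::roc(labels, scores, levels = c("neg", "pos"), direction = "<")))),
        tolerance = 1e-12
      )
    }
  })
  expect_error(roc_auc(c(1, 2), c("+", "+"), "+"), "both classes")
})

test_that("training records k x repeats resamples per setting and refuses bad input", {
  mf <- separable_model_frame(n_per_class = 8, n_features = 4)
  sp <- split_data(mf, seed = 2)
  ms <- suppressMessages(train_models(sp, mf,
    algorithms = c("glm", "knn"), k = 3, repeats = 2, seed = 9
  ))
  expect_s3_class(ms$glm$fit, "train")
  expect_equal(nrow(ms$glm$resamples), 3 * 2) # one (implicit) setting
  expect_equal(nrow(ms$knn$resamples), 3 * 2 * 3) # 3 candidate k values
  for (kk in unique(ms$knn$resamples$k)) {
    expect_equal(sum(ms$knn$resamples$k == kk), 6)
  }

  expect_error(
    suppressMessages(train_models(sp, mf, algorithms = "superboost", seed = 1)),
    "unknown algorithm"
  )
  expect_error(
    suppressMessages(train_models(sp, mf, algorithms = "glm", k = 50, seed = 1)),
    "smaller k"
  )
})

test_that("training is deterministic under a fixed seed", {
  mf <- separable_model_frame(n_per_class = 8, n_features = 4)
  sp <- split_data(mf, seed = 2)
  ms1 <- suppressMessages(train_models(sp, mf, algorithms = "rf", k = 3, repeats = 2, seed = 11))
  ms2 <- suppressMessages(train_models(sp, mf, algorithms = "rf", k = 3, repeats = 2, seed = 11))
  expect_equal(ms1$rf$resamples$Accuracy, ms2$rf$resamples$Accuracy)
  expect_equal(ms1$rf$best, ms2$rf$best)
})

test_that("held-out probabilities are normalized and separable data is classified perfectly", {
  mf <- separable_model_frame(n_per_class = 10, n_features = 5)
  sp <- split_data(mf, seed = 3)
  ms <- suppressMessages(train_models(sp, mf,
    algorithms = c("glm", "naive_bayes"), k = 3, repeats = 2, seed = 4
  ))
  ps <- test_models(ms, sp, mf)
  for (alg in names(ps)) {
    pr <- ps[[alg]]
    expect_equal(nrow(pr), length(sp$test))
    expect_true(all(abs(rowSums(pr[, c("healthy", "disease")]) - 1) < 1e-9))
    expect_true(all(pr[, c("healthy", "disease")] >= 0 & pr[, c("healthy", "disease")] <= 1))
    expect_equal(mean(pr$predicted == pr$truth), 1)
  }

  # feature mismatch is caught
  mf_bad <- mf
  names(mf_bad)[3] <- "RENAMED"
  mf_bad <- structure(mf_bad,
    features = attr(mf, "features"), classes = attr(mf, "classes"),
    class = class(mf)
  )
  expect_error(test_models(ms, sp, mf_bad), "mismatch")
})

test_that("tidiers summarise model sets and probability sets", {
  mf <- separable_model_frame(n_per_class = 8, n_features = 3)
  sp <- split_data(mf, seed = 7)
  ms <- suppressMessages(train_models(sp, mf, algorithms = "glm", k = 3, repeats = 2, seed = 8))
  td <- tidy(ms)
  expect_equal(nrow(td), 6)
  expect_true(all(c("algorithm", "accuracy", "kappa") %in% names(td)))
  gl <- glance(ms)
  expect_equal(gl$algorithm, "glm")
  expect_true(gl$accuracy >= 0.9)

  ps <- test_models(ms, sp, mf)
  gt <- glance(ps)
  expect_true(all(c("algorithm", "test_accuracy", "auc") %in% names(gt)))
  long <- tidy(ps)
  expect_equal(nrow(long), length(sp$test) * 2)
})
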