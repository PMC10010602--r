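# Classifier panels from top differential proteins: feature pruning,
# stratified splitting, repeated cross-validated training, held-out
# class probabilities and ROC/AUC.

#' Build a modeling frame from top differential proteins
#'
#' Takes the up-to-`top_n` significant proteins with the smallest
#' adjusted p-values, drops zero-variance features (with a warning), and
#' greedily removes highly correlated features: while any pair of
#' remaining features has `|r| > corr_cut` (Pearson, across samples),
#' the member of the worst pair with the larger mean absolute
#' correlation to all remaining features is removed (ties broken towards
#' the feature appearing later in the significance ordering). The result
#' is transposed to samples x features with the class label of each
#' sample taken from the design.
#'
#' @param de An `lfq_de` result from [find_dep()].
#' @param m The complete intensity table the result was computed on.
#' @param top_n Maximum number of proteins entering pruning (default 20).
#' @param corr_cut Absolute pairwise-correlation threshold (default 0.90).
#' @return A tibble of class `lfq_model_frame`: `sample_id`, `class`,
#'   then one column per retained protein. Attributes: `features`
#'   (tibble `protein_id`, `adj_p_value`), `classes` (class levels in
#'   design order).
#' @export
select_features <- function(de, m, top_n = 20, corr_cut = 0.90) {
  stopifnot(inherits(de, "lfq_de"), inherits(m, "lfq_intensity"))
  sig <- de[de$significant, , drop = FALSE]
  if (nrow(sig) == 0) stop_lfq("nothing to model: no significant proteins")
  # significance ordering is re-derived here so selection does not
  # depend on the row order of the input
  sig <- sig[order(sig$adj_p_value, -abs(sig$log2FC), sig$protein_id), ]
  sig <- utils::head(sig, top_n)
  missing_ids <- setdiff(sig$protein_id, m$protein_id)
  if (length(missing_ids) > 0) {
    stop_lfq(paste0("proteins absent from the intensity table: ",
      paste(missing_ids, collapse = ", ")))
  }
  mat <- im_matrix(m)
  if (anyNA(mat)) stop_lfq("intensity table contains missing values; impute first")
  X <- t(mat[sig$protein_id, , drop = FALSE]) # samples x features

  zero_var <- apply(X, 2, function(x) sd(x) == 0)
  if (any(zero_var)) {
    warn_lfq(paste0("dropping zero-variance features: ",
      paste(colnames(X)[zero_var], collapse = ", ")))
    X <- X[, !zero_var, drop = FALSE]
  }

  keep <- colnames(X) # ordered by significance
  while (length(keep) >= 2) {
    r <- abs(cor(X[, keep, drop = FALSE]))
    diag(r) <- 0
    if (max(r) <= corr_cut) break
    worst <- which(r == max(r), arr.ind = TRUE)[1, ] # the worst pair
    pair <- keep[worst]
    mean_abs <- rowMeans(r[pair, , drop = FALSE]) * length(keep) / (length(keep) - 1)
    # tie -> the member later in the significance ordering
    victim <- if (mean_abs[1] > mean_abs[2]) pair[1]
      else if (mean_abs[2] > mean_abs[1]) pair[2]
      else pair[which.max(match(pair, keep))]
    keep <- setdiff(keep, victim)
  }

  design <- im_design(m)
  classes <- unique(design$group)
  out <- tibble::tibble(
    sample_id = rownames(X),
    class = design$group[match(rownames(X), design$column)]
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(X[, keep, drop = FALSE]))
  log_stage("select_features",
    significant = sum(de$significant), entered = nrow(sig),
    retained = length(keep), corr_cut = corr_cut
  )
  structure(out,
    features = tibble::tibble(
      protein_id = keep,
      adj_p_value = sig$adj_p_value[match(keep, sig$protein_id)]
    ),
    classes = classes,
    class = c("lfq_model_frame", class(tibble::tibble()))
  )
}

#' Stratified train/test split
#'
#' For each class with `n_c` samples the training partition receives
#' `round(train_frac * n_c)` samples (round half up), drawn uniformly
#' without replacement under `seed`, with at least one sample of every
#' class left in each partition; the remainder forms the test set.
#'
#' @param mf An `lfq_model_frame` from [select_features()].
#' @param train_frac Fraction of each class assigned to training
#'   (default 0.7).
#' @param seed Integer seed making the split reproducible.
#' @return An object of class `lfq_split`: list with `train` and `test`
#'   sample-id vectors, `train_frac`, `seed`.
#' @export
split_data <- function(mf, train_frac = 0.7, seed = NULL) {
  stopifnot(inherits(mf, "lfq_model_frame"))
  if (!(train_frac > 0 && train_frac < 1)) stop_lfq("train_frac must be in (0, 1)")
  counts <- table(mf$class)
  if (any(counts < 2)) {
    stop_lfq(paste0("every class needs at least 2 samples; too few: ",
      paste(names(counts)[counts < 2], collapse = ", ")))
  }
  pick <- function() {
    train <- character(0)
    for (cl in names(counts)) {
      ids <- mf$sample_id[mf$class == cl]
      n_tr <- round_half_up(train_frac * length(ids))
      n_tr <- max(1L, min(length(ids) - 1L, n_tr)) # both partitions non-empty
      train <- c(train, sample(ids, n_tr))
    }
    train
  }
  train <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  structure(
    list(
      train = sort(train),
      test = sort(setdiff(mf$sample_id, train)),
      train_frac = train_frac, seed = seed
    ),
    class = "lfq_split"
  )
}

# Registry mapping the workflow's algorithm names onto caret methods.
# `naive_bayes` is a custom caret model spec backed by e1071 (Gaussian
# naive Bayes); `xgbLinear` is gradient boosting with linear base
# learners. Grids are small and fixed so runs are reproducible.
#' @noRd
algorithm_registry <- function(n_features) {
  mtry <- sort(unique(pmin(n_features, c(2L, max(1L, floor(sqrt(n_features))), n_features))))
  list(
    rf = list(method = "rf", grid = data.frame(mtry = mtry)),
    svmRadial = list(
      method = "svmRadial",
      grid = expand.grid(sigma = c(0.5, 1, 2) / max(1, n_features), C = c(0.25, 1, 4))
    ),
    svmLinear = list(method = "svmLinear", grid = data.frame(C = c(0.25, 1, 4))),
    glm = list(method = "glm", grid = NULL),
    xgbLinear = list(
      method = xgblinear_caret_spec(),
      grid = expand.grid(nrounds = 50, lambda = c(0, 0.1, 1), alpha = 0, eta = 0.3)
    ),
    naive_bayes = list(method = nb_caret_spec(), grid = data.frame(laplace = 0)),
    knn = list(method = "knn", grid = data.frame(k = c(3, 5, 7)))
  )
}

#' Supported classification algorithms
#'
#' @return Character vector of algorithm names accepted by
#'   [train_models()]. The default panel mirrors the workflow's five
#'   standard choices.
#' @export
supported_algorithms <- function() names(algorithm_registry(2))

#' @noRd
default_algorithms <- function() c("svmRadial", "glm", "rf", "xgbLinear", "naive_bayes")

# Gradient boosting with linear base learners as a caret custom model
# (xgboost gblinear backend; binary classification, single-threaded for
# reproducibility).
#' @noRd
xgblinear_caret_spec <- function() {
  list(
    label = "Boosted linear model (xgboost)",
    library = "xgboost",
    type = "Classification",
    parameters = data.frame(
      parameter = c("nrounds", "lambda", "alpha", "eta"),
      class = rep("numeric", 4),
      label = c("boosting rounds", "L2 penalty", "L1 penalty", "learning rate")
    ),
    grid = function(x, y, len = NULL, search = "grid") {
      expand.grid(nrounds = 50, lambda = c(0, 0.1, 1), alpha = 0, eta = 0.3)
    },
    fit = function(x, y, wts, param, lev, last, weights, classProbs, ...) {
      if (length(lev) != 2) stop("xgbLinear supports two classes")
      dm <- xgboost::xgb.DMatrix(as.matrix(x), label = as.numeric(y == lev[2]))
      mod <- xgboost::xgb.train(
        params = list(
          booster = "gblinear", objective = "binary:logistic",
          eta = param$eta, lambda = param$lambda, alpha = param$alpha,
          nthread = 1
        ),
        data = dm, nrounds = param$nrounds, verbose = 0
      )
      # plain list so caret can attach its bookkeeping fields
      list(booster = mod, class_levels = lev)
    },
    predict = function(modelFit, newdata, submodels = NULL) {
      p <- predict(modelFit$booster, xgboost::xgb.DMatrix(as.matrix(newdata)))
      lev <- modelFit$class_levels
      ifelse(p >= 0.5, lev[2], lev[1])
    },
    prob = function(modelFit, newdata, submodels = NULL) {
      p <- predict(modelFit$booster, xgboost::xgb.DMatrix(as.matrix(newdata)))
      lev <- modelFit$class_levels
      out <- data.frame(p1 = 1 - p, p2 = p)
      names(out) <- lev
      out
    },
    levels = function(x) x$class_levels,
    sort = function(x) x
  )
}

# Gaussian naive Bayes as a caret custom model (e1071 backend).
#' @noRd
nb_caret_spec <- function() {
  list(
    label = "Naive Bayes (e1071)",
    library = "e1071",
    type = "Classification",
    parameters = data.frame(
      parameter = "laplace", class = "numeric", label = "Laplace smoothing"
    ),
    grid = function(x, y, len = NULL, search = "grid") data.frame(laplace = 0),
    fit = function(x, y, wts, param, lev, last, weights, classProbs, ...) {
      e1071::naiveBayes(as.data.frame(x), y, laplace = param$laplace)
    },
    predict = function(modelFit, newdata, submodels = NULL) {
      predict(modelFit, as.data.frame(newdata), type = "class")
    },
    prob = function(modelFit, newdata, submodels = NULL) {
      predict(modelFit, as.data.frame(newdata), type = "raw")
    },
    levels = function(x) x$levels,
    sort = function(x) x
  )
}

#' Train classifiers with repeated cross-validation
#'
#' Trains each requested algorithm on the training partition with
#' stratified k-fold cross-validation repeated `repeats` times over a
#' small fixed hyperparameter grid (via [caret::train()]). Per-resample
#' accuracy and Cohen's kappa are recorded for every candidate setting;
#' the setting with the highest mean accuracy wins and the final model
#' is refit on the whole training partition.
#'
#' @param split An `lfq_split` from [split_data()].
#' @param mf The `lfq_model_frame` the split was made from.
#' @param algorithms Algorithm names from [supported_algorithms()].
#'   Default: random forest, RBF-kernel SVM, GLM (logistic), linear
#'   gradient boosting, naive Bayes.
#' @param k Number of cross-validation folds (default 10).
#' @param repeats Number of repeats (default 3), giving `k * repeats`
#'   resampling measurements per candidate hyperparameter setting.
#' @param seed Integer seed; fixed seed reproduces identical resampling
#'   metrics and models.
#' @return An object of class `lfq_model_set`: per algorithm a list with
#'   the fitted caret model (`fit`), the grid searched, the per-resample
#'   metrics for all settings (`resamples`) and the selected
#'   hyperparameters (`best`). Attributes: `features`, `classes`,
#'   `class_levels` (syntactic names used internally), `k`, `repeats`,
#'   `seed`.
#' @export
train_models <- function(split, mf, algorithms = default_algorithms(),
                         k = 10, repeats = 3, seed = NULL) {
  stopifnot(inherits(split, "lfq_split"), inherits(mf, "lfq_model_frame"))
  registry <- algorithm_registry(n_features = ncol(mf) - 2L)
  unknown <- setdiff(algorithms, names(registry))
  if (length(unknown) > 0) {
    stop_lfq(paste0(
      "unknown algorithm(s): ", paste(unknown, collapse = ", "),
      "; supported: ", paste(names(registry), collapse = ", ")
    ))
  }
  train_df <- mf[mf$sample_id %in% split$train, , drop = FALSE]
  counts <- table(train_df$class)
  if (k > min(counts)) {
    stop_lfq(sprintf(
      "k = %d exceeds the smallest class count in the training partition (%d); use a smaller k",
      k, min(counts)
    ))
  }
  classes <- attr(mf, "classes", exact = TRUE)
  levels_syn <- make.names(classes, unique = TRUE) # caret needs syntactic levels
  y <- factor(levels_syn[match(train_df$class, classes)], levels = levels_syn)
  x <- as.data.frame(train_df[, setdiff(names(mf), c("sample_id", "class")), drop = FALSE])

  ctrl <- caret::trainControl(
    method = "repeatedcv", number = k, repeats = repeats,
    classProbs = TRUE, returnResamp = "all", savePredictions = "none"
  )
  models <- list()
  for (i in seq_along(algorithms)) {
    alg <- algorithms[i]
    entry <- registry[[alg]]
    fit_one <- function() {
      suppressWarnings(caret::train(
        x = x, y = y, method = entry$method,
        tuneGrid = entry$grid, trControl = ctrl, metric = "Accuracy"
      ))
    }
    fit <- if (is.null(seed)) fit_one() else withr::with_seed(seed + i, fit_one())
    models[[alg]] <- list(
      fit = fit,
      grid = entry$grid,
      resamples = tibble::as_tibble(fit$resample),
      best = fit$bestTune,
      mean_accuracy = max(fit$results$Accuracy, na.rm = TRUE)
    )
    log_stage("train_models",
      algorithm = alg,
      resamples = nrow(fit$resample),
      mean_accuracy = signif(models[[alg]]$mean_accuracy, 4)
    )
  }
  structure(models,
    features = setdiff(names(mf), c("sample_id", "class")),
    classes = classes, class_levels = levels_syn,
    k = k, repeats = repeats, seed = seed,
    class = "lfq_model_set"
  )
}

#' Predict class probabilities on the test partition
#'
#' Applies every trained model to the held-out test samples and returns
#' class-probability matrices; the predicted label is the class with the
#' largest probability (ties resolved towards the first class in design
#' order).
#'
#' @param ms An `lfq_model_set` from [train_models()].
#' @param split The `lfq_split` used for training.
#' @param mf The `lfq_model_frame`.
#' @return An object of class `lfq_probability_set`: per algorithm a
#'   tibble `sample_id`, `truth`, one probability column per class,
#'   `predicted`. Attribute `classes`.
#' @export
test_models <- function(ms, split, mf) {
  stopifnot(inherits(ms, "lfq_model_set"), inherits(split, "lfq_split"),
    inherits(mf, "lfq_model_frame"))
  features <- attr(ms, "features", exact = TRUE)
  if (!all(features %in% names(mf))) {
    stop_lfq("feature mismatch between the model set and the model frame")
  }
  test_df <- mf[mf$sample_id %in% split$test, , drop = FALSE]
  if (nrow(test_df) == 0) stop_lfq("test partition is empty")
  classes <- attr(ms, "classes", exact = TRUE)
  levels_syn <- attr(ms, "class_levels", exact = TRUE)
  x <- as.data.frame(test_df[, features, drop = FALSE])

  out <- lapply(ms, function(model) {
    probs <- predict(model$fit, newdata = x, type = "prob")
    probs <- as.matrix(probs[, levels_syn, drop = FALSE])
    if (any(abs(rowSums(probs) - 1) > 1e-9)) {
      stop_lfq("class probabilities do not sum to 1")
    }
    pred_idx <- apply(probs, 1, which.max) # ties -> first class in design order
    colnames(probs) <- classes
    res <- tibble::tibble(
      sample_id = test_df$sample_id,
      truth = test_df$class
    )
    res <- dplyr::bind_cols(res, tibble::as_tibble(probs))
    res$predicted <- classes[pred_idx]
    res
  })
  structure(out, classes = classes, class = "lfq_probability_set")
}

#' ROC curve and AUC
#'
#' Computes the receiver operating characteristic at every distinct
#' score threshold (with endpoints (0,0) and (1,1)) and the area under
#' the curve as the Mann-Whitney pair-counting statistic: the fraction
#' of positive-negative pairs ranked correctly, ties counting 1/2.
#'
#' @param scores Numeric scores (larger = more positive).
#' @param labels Class labels, same length as `scores`.
#' @param positive_class The label treated as positive.
#' @return A list of class `lfq_roc`: `roc` (tibble `threshold`, `fpr`,
#'   `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels, positive_class) {
  if (length(scores) != length(labels)) stop_lfq("scores and labels differ in length")
  pos <- labels == positive_class
  if (!any(pos) || all(pos)) {
    stop_lfq("both classes must be present to compute a ROC curve")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  roc <- tibble::tibble(
    threshold = c(Inf, thr, -Inf),
    fpr = c(0, fpr, 1),
    tpr = c(0, tpr, 1)
  )
  roc <- roc[!duplicated(roc[, c("fpr", "tpr")]), , drop = FALSE]
  sp <- scores[pos]
  sn <- scores[!pos]
  cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  structure(list(roc = roc, auc = mean(cmp)), class = "lfq_roc")
}
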