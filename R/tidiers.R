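# broom-style tidiers for the fitted objects.

#' Tidy a differential-abundance result
#'
#' @param x An `lfq_de` from [find_dep()].
#' @param ... Unused.
#' @return A plain tibble, one row per protein.
#' @method tidy lfq_de
#' @export
tidy.lfq_de <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a differential-abundance result
#'
#' @param x An `lfq_de` from [find_dep()].
#' @param ... Unused.
#' @return A one-row tibble: contrast, protein counts, thresholds and
#'   the empirical-Bayes prior (`d0`, `s02`).
#' @method glance lfq_de
#' @export
glance.lfq_de <- function(x, ...) {
  tibble::tibble(
    contrast = paste(attr(x, "contrast", exact = TRUE), collapse = " - "),
    n_proteins = nrow(x),
    n_significant = sum(x$significant),
    lfc_cut = attr(x, "lfc_cut", exact = TRUE),
    adj_p_cut = attr(x, "adj_p_cut", exact = TRUE),
    d0 = attr(x, "d0", exact = TRUE),
    s02 = attr(x, "s02", exact = TRUE),
    residual_df = attr(x, "d", exact = TRUE)
  )
}

#' Tidy the resampling records of a model set
#'
#' @param x An `lfq_model_set` from [train_models()].
#' @param ... Unused.
#' @return A tibble with one row per resample per hyperparameter
#'   setting per algorithm: `algorithm`, the tuning columns, `accuracy`,
#'   `kappa`, `resample`.
#' @method tidy lfq_model_set
#' @export
tidy.lfq_model_set <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x), function(alg) {
    r <- tibble::as_tibble(x[[alg]]$resamples)
    names(r)[names(r) == "Accuracy"] <- "accuracy"
    names(r)[names(r) == "Kappa"] <- "kappa"
    names(r)[names(r) == "Resample"] <- "resample"
    dplyr::bind_cols(tibble::tibble(algorithm = alg), r)
  }))
}

#' One-row-per-algorithm summary of a model set
#'
#' @param x An `lfq_model_set` from [train_models()].
#' @param ... Unused.
#' @return A tibble: `algorithm`, mean cross-validated `accuracy` and
#'   `kappa` of the selected hyperparameters, and the selected setting
#'   as a character string.
#' @method glance lfq_model_set
#' @export
glance.lfq_model_set <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x), function(alg) {
    fit <- x[[alg]]$fit
    best <- x[[alg]]$best
    res <- fit$results
    if (!is.null(best) && ncol(best) > 0) {
      for (p in names(best)) res <- res[res[[p]] == best[[p]], , drop = FALSE]
    }
    tibble::tibble(
      algorithm = alg,
      accuracy = res$Accuracy[1],
      kappa = res$Kappa[1],
      best = paste(names(best), unlist(best), sep = "=", collapse = ", ")
    )
  }))
}

#' Tidy held-out class probabilities
#'
#' @param x An `lfq_probability_set` from [test_models()].
#' @param ... Unused.
#' @return A long tibble: `algorithm`, `sample_id`, `truth`,
#'   `predicted`, `class`, `probability`.
#' @method tidy lfq_probability_set
#' @export
tidy.lfq_probability_set <- function(x, ...) {
  classes <- attr(x, "classes", exact = TRUE)
  dplyr::bind_rows(lapply(names(x), function(alg) {
    long <- tidyr::pivot_longer(x[[alg]],
      cols = dplyr::all_of(classes),
      names_to = "class", values_to = "probability"
    )
    dplyr::bind_cols(tibble::tibble(algorithm = alg), long)
  }))
}

#' Per-algorithm test-set summary
#'
#' @param x An `lfq_probability_set` from [test_models()].
#' @param positive_class Label treated as positive for the AUC; default
#'   the second class in design order.
#' @param ... Unused.
#' @return A tibble: `algorithm`, `test_accuracy`, `auc`.
#' @method glance lfq_probability_set
#' @export
glance.lfq_probability_set <- function(x, positive_class = NULL, ...) {
  classes <- attr(x, "classes", exact = TRUE)
  positive_class <- positive_class %||% classes[2]
  dplyr::bind_rows(lapply(names(x), function(alg) {
    pr <- x[[alg]]
    tibble::tibble(
      algorithm = alg,
      test_accuracy = mean(pr$predicted == pr$truth),
      auc = roc_auc(pr[[positive_class]], pr$truth, positive_class)$auc
    )
  }))
}
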