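# Left-censored (MNAR) missing-value imputation and quantile
# normalization. The two steps can be applied in either order.

#' MinProb imputation of left-censored missing values
#'
#' Replaces each missing value in sample column *j* with an independent
#' draw from `Normal(mu_j, sigma)`, where `mu_j` is the `q`-th quantile
#' (type 7) of the column's observed values — i.e. a value near the
#' sample's detection limit — and `sigma = tune_sigma * median` over
#' proteins of the per-protein standard deviation of observed values.
#' This models intensities that are missing because they fell below the
#' detection limit (missing-not-at-random, left-censored).
#'
#' Observed entries are never altered. With `tune_sigma = 0` every
#' imputed value in column *j* is exactly `mu_j`, regardless of seed.
#' One seeded generator serves the whole call and draws are consumed
#' column by column, so results are reproducible independent of any
#' parallel setup.
#'
#' @param m An intensity table of stage `"raw"` or `"normalized"`.
#' @param q Quantile of the observed distribution used as the imputation
#'   centre, in (0, 1). Default 0.01.
#' @param tune_sigma Multiplier on the spread of the imputation
#'   distribution; non-negative. Default 1.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return The imputed intensity table, stage `"imputed"`, with an
#'   `impute_params` attribute recording `q`, `tune_sigma`, `seed`, the
#'   per-column centres `mu` and the common `sigma`.
#' @export
impute_minprob <- function(m, q = 0.01, tune_sigma = 1, seed = NULL) {
  stopifnot(inherits(m, "lfq_intensity"))
  if (!(q > 0 && q < 1)) stop_lfq("q must be in (0, 1)")
  if (tune_sigma < 0) stop_lfq("tune_sigma must be >= 0")
  if (!im_stage(m) %in% c("raw", "normalized")) {
    stop_lfq("impute_minprob expects a raw or normalized intensity table")
  }
  mat <- im_matrix(m)
  n_obs <- colSums(!is.na(mat))
  if (any(n_obs < 2)) {
    stop_lfq(paste0(
      "columns with fewer than 2 observed values cannot be imputed: ",
      paste(colnames(mat)[n_obs < 2], collapse = ", ")
    ))
  }
  mu <- apply(mat, 2, function(x) unname(quantile(x, probs = q, na.rm = TRUE, type = 7)))
  row_sd <- apply(mat, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) >= 2) sd(x) else NA_real_
  })
  if (all(is.na(row_sd))) {
    stop_lfq("no protein has 2 or more observed values; cannot estimate imputation spread")
  }
  sigma <- tune_sigma * median(row_sd, na.rm = TRUE)

  draw <- function() {
    for (j in seq_len(ncol(mat))) { # column-major consumption of the RNG
      miss <- which(is.na(mat[, j]))
      if (length(miss) > 0) {
        mat[miss, j] <<- rnorm(length(miss), mean = mu[j], sd = sigma)
      }
    }
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())

  log_stage("impute_minprob",
    imputed_cells = sum(is.na(im_matrix(m))), q = q,
    tune_sigma = tune_sigma, sigma = signif(sigma, 6)
  )
  out <- im_rebuild(mat, m, stage = "imputed")
  attr(out, "impute_params") <- list(
    q = q, tune_sigma = tune_sigma, seed = seed, mu = mu, sigma = sigma
  )
  out
}

#' Quantile normalization
#'
#' Forces every sample column to share one common intensity
#' distribution: on complete data the value at rank *r* in each column
#' is replaced by the mean across columns of the rank-*r* order
#' statistics, ties receiving the mean of their tied target values.
#' Columns containing missing values are normalized by linear
#' interpolation of the mean quantile function at the observed entries'
#' quantile positions; missing entries stay missing. Within-column rank
#' order of observed values is preserved.
#'
#' The computation is delegated to [limma::normalizeQuantiles()]
#' (`ties = TRUE`), which implements exactly this rule.
#'
#' @param m An intensity table of stage `"raw"` or `"imputed"`.
#' @return The normalized intensity table, stage `"normalized"`. A
#'   single-column table is returned unchanged with a warning.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "lfq_intensity"))
  if (!im_stage(m) %in% c("raw", "imputed")) {
    stop_lfq("quantile_normalize expects a raw or imputed intensity table")
  }
  mat <- im_matrix(m)
  if (ncol(mat) < 2) {
    warn_lfq("only one sample column; quantile normalization is a no-op")
    return(new_intensity_tbl(m, stage = "normalized", design = im_design(m)))
  }
  norm <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(norm) <- dimnames(mat)
  log_stage("quantile_normalize", columns = ncol(mat), rows = nrow(mat))
  im_rebuild(norm, m, stage = "normalized")
}
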