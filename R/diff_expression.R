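# Two-group differential abundance with empirical-Bayes variance
# squeezing and moderated t-statistics.
#
# Per protein g with groups A (first in design order) and B:
#   beta_g = mean_A - mean_B            (log2 fold change)
#   s2_g   = pooled residual variance, d = n_A + n_B - 2 df
#   v      = 1/n_A + 1/n_B
# The protein-wise variances share information through a scaled
# inverse-chi-square prior (d0, s02) estimated by moment matching on
# log s2; the posterior variance
#   s2_post_g = (d0*s02 + d*s2_g) / (d0 + d)
# yields the moderated statistic t_g = beta_g / sqrt(s2_post_g * v)
# on d + d0 degrees of freedom.

#' Fit the per-protein two-group model
#'
#' Computes group means, log2 fold changes and pooled residual variances
#' for every protein. The contrast is `group1 - group2` where `group1`
#' is the first group in design order.
#'
#' @param m A complete (post-imputation) intensity table.
#' @param groups Optional character vector of length 2 naming the two
#'   groups to contrast; required when the design has more than two
#'   groups.
#' @return A tibble of class `lfq_group_fit`: `protein_id`, `mean_1`,
#'   `mean_2`, `log2FC`, `s2`. Attributes `groups`, `d` (residual df),
#'   `v` (unscaled squared standard-error factor), `n` (per-group sizes).
#' @export
fit_group_model <- function(m, groups = NULL) {
  stopifnot(inherits(m, "lfq_intensity"))
  design <- im_design(m)
  all_groups <- unique(design$group)
  if (is.null(groups)) {
    if (length(all_groups) != 2) {
      stop_lfq(paste0(
        "design has ", length(all_groups),
        " groups (", paste(all_groups, collapse = ", "),
        "); name a pair via `groups`"
      ))
    }
    groups <- all_groups
  }
  if (length(groups) != 2 || !all(groups %in% all_groups)) {
    stop_lfq(paste0(
      "`groups` must name two of: ", paste(all_groups, collapse = ", ")
    ))
  }
  mat <- im_matrix(m)
  cols1 <- design$column[design$group == groups[1]]
  cols2 <- design$column[design$group == groups[2]]
  n1 <- length(cols1)
  n2 <- length(cols2)
  if (n1 < 2 || n2 < 2) {
    stop_lfq("each group needs at least 2 samples for the two-group fit")
  }
  sub <- mat[, c(cols1, cols2), drop = FALSE]
  if (anyNA(sub)) {
    stop_lfq("intensity table contains missing values; impute before fitting")
  }
  m1 <- rowMeans(sub[, cols1, drop = FALSE])
  m2 <- rowMeans(sub[, cols2, drop = FALSE])
  d <- n1 + n2 - 2
  rss <- rowSums((sub[, cols1, drop = FALSE] - m1)^2) +
    rowSums((sub[, cols2, drop = FALSE] - m2)^2)
  fit <- tibble::tibble(
    protein_id = rownames(mat),
    mean_1 = unname(m1),
    mean_2 = unname(m2),
    log2FC = unname(m1 - m2),
    s2 = unname(rss / d)
  )
  structure(fit,
    groups = groups, d = d, v = 1 / n1 + 1 / n2, n = c(n1, n2),
    class = c("lfq_group_fit", class(tibble::tibble()))
  )
}

#' Empirical-Bayes squeezing of per-protein variances
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s02`
#' of a scaled inverse-chi-square prior by moment matching on
#' `e_g = log(s2_g) - digamma(d/2) + log(d/2)`: with `ebar` the mean and
#' `V` the unbiased variance of the finite `e_g`, set
#' `V' = V - trigamma(d/2)`; if `V' > 0` then
#' `d0 = 2 * trigamma_inverse(V')` and
#' `s02 = exp(ebar + digamma(d0/2) - log(d0/2))`, otherwise the variances
#' are less dispersed than chi-square sampling alone predicts and
#' `d0 = Inf`, `s02 = exp(ebar)`. Posterior variances are
#' `(d0*s02 + d*s2_g)/(d0 + d)` (equal to `s02` when `d0 = Inf`).
#'
#' Proteins with `s2 = 0` are excluded from the moment estimation
#' (log 0 is undefined) but still receive the posterior
#' `d0*s02/(d0 + d)`.
#'
#' @param s2 Numeric vector of per-protein residual variances (>= 0).
#' @param d Residual degrees of freedom shared by all proteins (>= 1).
#' @return An object of class `lfq_ebayes`: list with `d0`, `s02`,
#'   `s2_post` (aligned with `s2`), `d`.
#' @export
squeeze_variances <- function(s2, d) {
  if (any(s2 < 0, na.rm = TRUE)) stop_lfq("variances must be non-negative")
  if (d < 1) stop_lfq("residual degrees of freedom must be >= 1")
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  fin <- is.finite(e)
  if (sum(fin) < 2) stop_lfq("cannot estimate prior: fewer than 2 positive variances")
  ebar <- mean(e[fin])
  V <- var(e[fin]) # unbiased (n-1) variance
  Vprime <- V - trigamma(d / 2)
  if (is.finite(Vprime) && Vprime > 0) {
    d0 <- 2 * trigamma_inverse(Vprime)
    s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(ebar)
  }
  s2_post <- if (is.infinite(d0)) {
    rep(s02, length(s2))
  } else {
    (d0 * s02 + d * s2) / (d0 + d)
  }
  structure(
    list(d0 = d0, s02 = s02, s2_post = s2_post, d = d),
    class = "lfq_ebayes"
  )
}

# Solve trigamma(x) = y for x > 0 by damped Newton iteration.
# trigamma is positive, decreasing and convex, so Newton from a point
# right of the root converges monotonically; damping guards the first
# steps. Iterates until |delta| < 1e-8.
#' @noRd
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y)) # trigamma(x) ~ 1/x^2 as x -> 0
  if (y < 1e-6) return(1 / y) # trigamma(x) ~ 1/x as x -> Inf
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    delta <- (trigamma(x) - y) / psigamma(x, deriv = 2)
    # full Newton can overshoot to x <= 0 far from the root; damp it
    while (x - delta <= 0) delta <- delta / 2
    x <- x - delta
    if (abs(delta) < 1e-8) break
  }
  x
}

#' Moderated t-statistics and p-values
#'
#' Combines a two-group fit with squeezed variances:
#' `t_g = log2FC_g / sqrt(s2_post_g * v)`, referred to a Student-t
#' distribution with `d + d0` degrees of freedom (the normal tail when
#' `d0 = Inf`). With `d0 = 0` this is the ordinary pooled two-sample t.
#' Proteins whose posterior variance is 0 get `t = +/-Inf`, `p = 0` and
#' are flagged.
#'
#' @param fit An `lfq_group_fit` from [fit_group_model()].
#' @param eb An `lfq_ebayes` from [squeeze_variances()] computed on
#'   `fit`'s variances.
#' @return A tibble: `protein_id`, `t`, `df`, `p_value`,
#'   `degenerate_variance`.
#' @export
moderated_t <- function(fit, eb) {
  stopifnot(inherits(fit, "lfq_group_fit"), inherits(eb, "lfq_ebayes"))
  if (length(eb$s2_post) != nrow(fit)) {
    stop_lfq("squeezed variances do not match the fit")
  }
  v <- attr(fit, "v", exact = TRUE)
  df_total <- attr(fit, "d", exact = TRUE) + eb$d0
  se <- sqrt(eb$s2_post * v)
  t_stat <- fit$log2FC / se
  degenerate <- eb$s2_post == 0
  t_stat[degenerate] <- sign(fit$log2FC[degenerate]) * Inf
  t_stat[degenerate & fit$log2FC == 0] <- 0
  p <- 2 * pt(-abs(t_stat), df = df_total)
  p[degenerate & is.infinite(t_stat)] <- 0
  tibble::tibble(
    protein_id = fit$protein_id,
    t = t_stat,
    df = df_total,
    p_value = p,
    degenerate_variance = degenerate
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `q_(i) = min over j >= i of p_(j) * m / j`, capped at 1, returned in
#' the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop_lfq("p-values must lie in [0, 1] with no missing values")
  }
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(scaled)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

#' Differential abundance analysis
#'
#' Runs the full per-protein pipeline — two-group fit, empirical-Bayes
#' variance squeezing, moderated t-tests, multiple-testing adjustment —
#' and flags a protein as significant when `|log2FC| > lfc_cut` and its
#' adjusted p-value is below `adj_p_cut` (both strict).
#'
#' @inheritParams fit_group_model
#' @param lfc_cut Absolute log2 fold-change threshold (default 1).
#' @param adj_p_cut Adjusted p-value threshold (default 0.05).
#' @param p_adjust_method `"BH"` (default, the package's own step-up) or
#'   any method name accepted by [stats::p.adjust()].
#' @return A tibble of class `lfq_de` sorted by adjusted p ascending
#'   (ties: larger `|log2FC|` first, then `protein_id`): `protein_id`,
#'   `log2FC`, `t`, `p_value`, `adj_p_value`, `significant`. Attributes
#'   record the contrast, thresholds and the prior (`d0`, `s02`).
#' @export
find_dep <- function(m, groups = NULL, lfc_cut = 1, adj_p_cut = 0.05,
                     p_adjust_method = "BH") {
  fit <- fit_group_model(m, groups = groups)
  eb <- squeeze_variances(fit$s2, attr(fit, "d", exact = TRUE))
  tt <- moderated_t(fit, eb)
  adj <- if (identical(p_adjust_method, "BH")) {
    adjust_bh(tt$p_value)
  } else {
    stats::p.adjust(tt$p_value, method = p_adjust_method)
  }
  res <- tibble::tibble(
    protein_id = fit$protein_id,
    log2FC = fit$log2FC,
    t = tt$t,
    p_value = tt$p_value,
    adj_p_value = adj,
    significant = abs(fit$log2FC) > lfc_cut & adj < adj_p_cut
  )
  res <- res[order(res$adj_p_value, -abs(res$log2FC), res$protein_id), ]
  contrast <- attr(fit, "groups", exact = TRUE)
  log_stage("find_dep",
    contrast = paste(contrast, collapse = " - "),
    proteins = nrow(res), significant = sum(res$significant),
    d0 = signif(eb$d0, 6), s02 = signif(eb$s02, 6)
  )
  structure(res,
    contrast = contrast, lfc_cut = lfc_cut, adj_p_cut = adj_p_cut,
    d0 = eb$d0, s02 = eb$s02, d = attr(fit, "d", exact = TRUE),
    p_adjust_method = p_adjust_method,
    class = c("lfq_de", class(tibble::tibble()))
  )
}

#' Write a differential-abundance result as TSV
#'
#' Thresholds and the contrast are recorded as leading `#` comment
#' lines, followed by a header and one row per protein.
#'
#' @param de An `lfq_de` result from [find_dep()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_tsv <- function(de, path) {
  stopifnot(inherits(de, "lfq_de"))
  hdr <- c(
    paste0("# contrast: ", paste(attr(de, "contrast", exact = TRUE), collapse = " - ")),
    paste0("# lfc_cut: ", attr(de, "lfc_cut", exact = TRUE)),
    paste0("# adj_p_cut: ", attr(de, "adj_p_cut", exact = TRUE))
  )
  writeLines(hdr, path)
  readr::write_tsv(tibble::as_tibble(de), path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}
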