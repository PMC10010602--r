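# Figure suite. Every figure is a ggplot built from a small tidy data
# frame; render_figure() writes the image (PNG, plus SVG where cairo is
# available) and a sidecar TSV of the plotted numbers, so figures are
# assertable without image diffing.

#' Colour-blind-safe palette
#'
#' @param n Number of colours (up to 8).
#' @return Character vector of hex colours (Okabe-Ito set).
#' @export
lfq_palette <- function(n = 8) {
  unname(grDevices::palette.colors(n, palette = "Okabe-Ito"))
}

#' @noRd
figure_kinds <- c(
  "corr_plot", "heatmap_na", "impute_plot", "norm_plot", "heatmap_de",
  "volcano_plot", "feature_plot", "varimp_plot", "performance_plot",
  "roc_plot"
)

# Each builder returns list(plot = <ggplot>, data = <tibble>).

#' @noRd
build_volcano <- function(de, lfc_cut = NULL, adj_p_cut = NULL) {
  stopifnot(inherits(de, "lfq_de"))
  lfc_cut <- lfc_cut %||% attr(de, "lfc_cut", exact = TRUE)
  adj_p_cut <- adj_p_cut %||% attr(de, "adj_p_cut", exact = TRUE)
  dat <- tibble::tibble(
    protein_id = de$protein_id,
    log2FC = de$log2FC,
    neg_log10_adj_p = -log10(pmax(de$adj_p_value, .Machine$double.xmin)),
    significant = de$significant
  )
  p <- ggplot2::ggplot(dat, ggplot2::aes(log2FC, neg_log10_adj_p, colour = significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-lfc_cut, lfc_cut), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(adj_p_cut), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = lfq_palette(2)[2])) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p", colour = "significant") +
    ggplot2::theme_minimal()
  list(plot = p, data = dat)
}

#' @noRd
build_heatmap_na <- function(m) {
  stopifnot(inherits(m, "lfq_intensity"))
  mat <- im_matrix(m)
  dat <- tibble::as_tibble(as.data.frame(is.na(mat), check.names = FALSE))
  dat$protein_id <- rownames(mat)
  dat <- tidyr::pivot_longer(dat, -"protein_id",
    names_to = "sample", values_to = "missing"
  )
  p <- ggplot2::ggplot(dat, ggplot2::aes(sample, protein_id, fill = missing)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = lfq_palette(3)[3], `TRUE` = "grey90")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  list(plot = p, data = dat)
}

#' @noRd
build_impute_plot <- function(before, after) {
  stopifnot(inherits(before, "lfq_intensity"), inherits(after, "lfq_intensity"))
  dat <- dplyr::bind_rows(
    tibble::tibble(stage = "before", value = as.vector(im_matrix(before))),
    tibble::tibble(stage = "after", value = as.vector(im_matrix(after)))
  )
  dat <- dat[!is.na(dat$value), , drop = FALSE]
  p <- ggplot2::ggplot(dat, ggplot2::aes(value, colour = stage)) +
    ggplot2::geom_density() +
    ggplot2::scale_colour_manual(values = lfq_palette(2)) +
    ggplot2::labs(x = "log2 intensity", y = "density") +
    ggplot2::theme_minimal()
  list(plot = p, data = dat)
}

#' @noRd
build_norm_plot <- function(before, after) {
  stopifnot(inherits(before, "lfq_intensity"), inherits(after, "lfq_intensity"))
  longen <- function(m, stage) {
    mat <- im_matrix(m)
    tibble::tibble(
      stage = stage,
      sample = rep(colnames(mat), each = nrow(mat)),
      value = as.vector(mat)
    )
  }
  dat <- dplyr::bind_rows(longen(before, "before"), longen(after, "after"))
  dat <- dat[!is.na(dat$value), , drop = FALSE]
  dat$stage <- factor(dat$stage, levels = c("before", "after"))
  p <- ggplot2::ggplot(dat, ggplot2::aes(sample, value, fill = stage)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~stage, ncol = 1) +
    ggplot2::scale_fill_manual(values = lfq_palette(2)) +
    ggplot2::labs(y = "log2 intensity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
  list(plot = p, data = dat)
}

#' @noRd
build_heatmap_de <- function(de, m, top_n = 20) {
  stopifnot(inherits(de, "lfq_de"), inherits(m, "lfq_intensity"))
  top <- utils::head(de$protein_id[de$significant], top_n)
  if (length(top) == 0) stop_lfq("no significant proteins to draw")
  mat <- im_matrix(m)
  top <- intersect(top, rownames(mat))
  dat <- tibble::as_tibble(as.data.frame(mat[top, , drop = FALSE], check.names = FALSE))
  dat$protein_id <- top
  dat <- tidyr::pivot_longer(dat, -"protein_id",
    names_to = "sample", values_to = "log2_intensity"
  )
  dat <- dplyr::group_by(dat, .data$protein_id)
  dat <- dplyr::mutate(dat,
    z = (log2_intensity - mean(log2_intensity, na.rm = TRUE)) /
      sd(log2_intensity, na.rm = TRUE)
  )
  dat <- dplyr::ungroup(dat)
  p <- ggplot2::ggplot(dat, ggplot2::aes(sample, protein_id, fill = z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = lfq_palette(8)[6], high = lfq_palette(8)[7]) +
    ggplot2::theme_minimal()
  list(plot = p, data = dat)
}

#' @noRd
build_corr_plot <- function(m) {
  stopifnot(inherits(m, "lfq_intensity"))
  design <- im_design(m)
  if (all(is.na(design$tech_rep))) {
    stop_lfq("corr_plot needs technical replicates in the design")
  }
  mat <- im_matrix(m)
  pairs <- list()
  for (s in unique(design$sample_id)) {
    cols <- design$column[design$sample_id == s]
    if (length(cols) < 2) next
    cmb <- utils::combn(cols, 2)
    for (i in seq_len(ncol(cmb))) {
      x <- mat[, cmb[1, i]]
      y <- mat[, cmb[2, i]]
      ok <- !is.na(x) & !is.na(y)
      pairs[[length(pairs) + 1]] <- tibble::tibble(
        sample_id = s, rep_x = cmb[1, i], rep_y = cmb[2, i],
        x = x[ok], y = y[ok],
        pearson_r = cor(x[ok], y[ok])
      )
    }
  }
  if (length(pairs) == 0) stop_lfq("no technical-replicate pairs found")
  dat <- dplyr::bind_rows(pairs)
  dat$panel <- paste0(dat$rep_x, " vs ", dat$rep_y, " (r=", signif(dat$pearson_r, 3), ")")
  p <- ggplot2::ggplot(dat, ggplot2::aes(x, y)) +
    ggplot2::geom_point(alpha = 0.4, colour = lfq_palette(1)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "log2 intensity", y = "log2 intensity") +
    ggplot2::theme_minimal()
  list(plot = p, data = dat)
}

#' @noRd
build_feature_plot <- function(mf) {
  stopifnot(inherits(mf, "lfq_model_frame"))
  dat <- tidyr::pivot_longer(tibble::as_tibble(mf),
    cols = -c("sample_id", "class"),
    names_to = "protein_id", values_to = "log2_intensity"
  )
  p <- ggplot2::ggplot(dat, ggplot2::aes(class, log2_intensity, fill = class)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~protein_id, scales = "free_y") +
    ggplot2::scale_fill_manual(values = lfq_palette(8)) +
    ggplot2::theme_minimal()
  list(plot = p, data = dat)
}

#' @noRd
build_performance_plot <- function(ms) {
  stopifnot(inherits(ms, "lfq_model_set"))
  dat <- dplyr::bind_rows(lapply(names(ms), function(alg) {
    r <- ms[[alg]]$resamples
    tibble::tibble(
      algorithm = alg, resample = r$Resample,
      accuracy = r$Accuracy, kappa = r$Kappa
    )
  }))
  long <- tidyr::pivot_longer(dat, c("accuracy", "kappa"),
    names_to = "metric", values_to = "value"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(algorithm, value, fill = algorithm)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_fill_manual(values = lfq_palette(8)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  list(plot = p, data = long)
}

#' Permutation feature importance
#'
#' Model-agnostic importance: the drop in training-partition accuracy
#' when one feature's values are permuted, averaged over `n_perm`
#' permutations under `seed`.
#'
#' @param ms An `lfq_model_set`.
#' @param split The `lfq_split` used for training.
#' @param mf The `lfq_model_frame`.
#' @param n_perm Permutations per feature (default 5).
#' @param seed Integer seed.
#' @return A tibble: `algorithm`, `protein_id`, `importance`.
#' @export
permutation_importance <- function(ms, split, mf, n_perm = 5, seed = NULL) {
  stopifnot(inherits(ms, "lfq_model_set"), inherits(mf, "lfq_model_frame"))
  features <- attr(ms, "features", exact = TRUE)
  classes <- attr(ms, "classes", exact = TRUE)
  levels_syn <- attr(ms, "class_levels", exact = TRUE)
  train_df <- mf[mf$sample_id %in% split$train, , drop = FALSE]
  x <- as.data.frame(train_df[, features, drop = FALSE])
  y <- levels_syn[match(train_df$class, classes)]
  run <- function() {
    dplyr::bind_rows(lapply(names(ms), function(alg) {
      fit <- ms[[alg]]$fit
      base_acc <- mean(as.character(predict(fit, newdata = x)) == y)
      imp <- vapply(features, function(f) {
        drops <- vapply(seq_len(n_perm), function(i) {
          xp <- x
          xp[[f]] <- sample(xp[[f]])
          base_acc - mean(as.character(predict(fit, newdata = xp)) == y)
        }, numeric(1))
        mean(drops)
      }, numeric(1))
      tibble::tibble(algorithm = alg, protein_id = features, importance = unname(imp))
    }))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @noRd
build_varimp_plot <- function(ms, split, mf, n_perm = 5, seed = 1L) {
  dat <- permutation_importance(ms, split, mf, n_perm = n_perm, seed = seed)
  p <- ggplot2::ggplot(dat, ggplot2::aes(importance, stats::reorder(protein_id, importance))) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = stats::reorder(protein_id, importance)),
      colour = "grey70"
    ) +
    ggplot2::geom_point(colour = lfq_palette(1), size = 2) +
    ggplot2::facet_wrap(~algorithm) +
    ggplot2::labs(x = "permutation importance (accuracy drop)", y = NULL) +
    ggplot2::theme_minimal()
  list(plot = p, data = dat)
}

#' @noRd
build_roc_plot <- function(ps, positive_class = NULL) {
  stopifnot(inherits(ps, "lfq_probability_set"))
  classes <- attr(ps, "classes", exact = TRUE)
  positive_class <- positive_class %||% classes[2]
  dat <- dplyr::bind_rows(lapply(names(ps), function(alg) {
    probs <- ps[[alg]]
    rr <- roc_auc(probs[[positive_class]], probs$truth, positive_class)
    out <- rr$roc
    out$algorithm <- paste0(alg, " (AUC=", sprintf("%.3f", rr$auc), ")")
    out$auc <- rr$auc
    out
  }))
  p <- ggplot2::ggplot(dat, ggplot2::aes(fpr, tpr, colour = algorithm)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = lfq_palette(8)) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
  list(plot = p, data = dat)
}

#' Render a figure with its data export
#'
#' Builds one of the workflow's figures, writes it as PNG (and SVG when
#' cairo is available), and writes the plotted numbers as a sidecar TSV
#' next to the image (same path, `.tsv` extension). The sidecar makes
#' the plotted data assertable without image diffing.
#'
#' @param kind One of `"corr_plot"`, `"heatmap_na"`, `"impute_plot"`,
#'   `"norm_plot"`, `"heatmap_de"`, `"volcano_plot"`, `"feature_plot"`,
#'   `"varimp_plot"`, `"performance_plot"`, `"roc_plot"`.
#' @param path Output image path (`.png`).
#' @param ... Inputs required by the kind: `de` and/or `m` for
#'   volcano/heatmaps, `before`/`after` intensity tables for
#'   impute/norm plots, `mf`/`ms`/`split`/`ps` for the modeling figures,
#'   plus kind-specific options.
#' @param width,height Image size in inches.
#' @return Invisibly, a list with `plot` (the ggplot), `data` (the
#'   plotted tibble) and `paths` (files written).
#' @export
render_figure <- function(kind, path, ..., width = 7, height = 5) {
  if (!kind %in% figure_kinds) {
    stop_lfq(paste0(
      "unknown figure kind '", kind, "'; known kinds: ",
      paste(figure_kinds, collapse = ", ")
    ))
  }
  args <- list(...)
  need <- function(nm) {
    if (is.null(args[[nm]])) stop_lfq(paste0("figure '", kind, "' needs input '", nm, "'"))
    args[[nm]]
  }
  built <- switch(kind,
    volcano_plot = build_volcano(need("de")),
    heatmap_na = build_heatmap_na(need("m")),
    impute_plot = build_impute_plot(need("before"), need("after")),
    norm_plot = build_norm_plot(need("before"), need("after")),
    heatmap_de = build_heatmap_de(need("de"), need("m")),
    corr_plot = build_corr_plot(need("m")),
    feature_plot = build_feature_plot(need("mf")),
    varimp_plot = build_varimp_plot(need("ms"), need("split"), need("mf"),
      seed = args$seed %||% 1L
    ),
    performance_plot = build_performance_plot(need("ms")),
    roc_plot = build_roc_plot(need("ps"), positive_class = args$positive_class)
  )
  paths <- character(0)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  grDevices::png(path, width = width, height = height, units = "in", res = 150)
  print(built$plot)
  grDevices::dev.off()
  paths <- c(paths, png = path)
  if (isTRUE(unname(capabilities("cairo")))) {
    svg_path <- sub("\\.png$", ".svg", path)
    grDevices::svg(svg_path, width = width, height = height)
    print(built$plot)
    grDevices::dev.off()
    paths <- c(paths, svg = svg_path)
  }
  tsv_path <- sub("\\.[A-Za-z]+$", ".tsv", path)
  readr::write_tsv(built$data, tsv_path, progress = FALSE)
  paths <- c(paths, data = tsv_path)
  invisible(list(plot = built$plot, data = built$data, paths = paths))
}

#' @rdname render_figure
#' @param object,x An `lfq_de`, `lfq_model_set` or `lfq_probability_set`
#'   object.
#' @method autoplot lfq_de
#' @export
autoplot.lfq_de <- function(object, ...) build_volcano(object)$plot

#' @rdname render_figure
#' @method autoplot lfq_model_set
#' @export
autoplot.lfq_model_set <- function(object, ...) build_performance_plot(object)$plot

#' @rdname render_figure
#' @method autoplot lfq_probability_set
#' @export
autoplot.lfq_probability_set <- function(object, ...) build_roc_plot(object, ...)$plot
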