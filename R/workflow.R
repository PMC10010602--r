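# Orchestration of the two pipelines behind a flat config, with stage
# TSVs, figures and a JSON run manifest.

#' Default run configuration
#'
#' A flat key-value list holding every tunable of the two pipelines,
#' with the workflow's standard defaults: unique-peptide minimum 3,
#' group-missingness cap 0.34, MinProb imputation, quantile
#' normalization, |log2FC| > 1 at adjusted p < 0.05, top 20 features,
#' 0.90 correlation cut, 70/30 split, 10-fold CV repeated 3 times, and
#' the five standard algorithms.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list.
#' @export
lfq_config <- function(...) {
  defaults <- list(
    intensity_type = "LFQ",
    uniq_pep_min = 3,
    max_group_na = 0.34,
    impute_q = 0.01,
    tune_sigma = 1,
    order = "impute_first", # impute_first | normalize_first | skip_normalization
    lfc_cut = 1,
    adj_p_cut = 0.05,
    top_n = 20,
    corr_cut = 0.90,
    train_frac = 0.7,
    algorithms = default_algorithms(),
    k = 10,
    repeats = 3,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop_lfq(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  modifyList(defaults, overrides)
}

#' @noRd
write_manifest <- function(manifest, outdir) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null"
  )
}

#' @noRd
file_md5 <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the analysis pipeline
#'
#' Executes parse -> filter -> (average technical replicates) ->
#' group-missingness filter -> imputation/normalization (in the
#' configured order) -> differential abundance, writing stage TSVs, QC
#' figures, the DE table and a JSON manifest (package version, config,
#' seeds, per-stage row counts, input checksums) under `outdir`. If a
#' stage fails, the manifest written so far is persisted before the
#' error propagates.
#'
#' @param protein_groups_path Path to a proteinGroups-style TSV (or a
#'   generic intensity matrix when `generic = TRUE`).
#' @param design_path Path to the design TSV.
#' @param outdir Output directory (created).
#' @param config A list from [lfq_config()].
#' @param generic Read the input with [read_intensity_matrix()] instead
#'   of [read_protein_groups()].
#' @return Invisibly, a list with the final intensity table (`m`), the
#'   DE result (`de`), the design, and the manifest.
#' @export
run_analysis <- function(protein_groups_path, design_path, outdir,
                         config = lfq_config(), generic = FALSE) {
  for (p in c(protein_groups_path, design_path)) {
    if (!file.exists(p)) stop_lfq(sprintf("input file not found: %s", p))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "lfqpipe",
    version = as.character(packageVersion("lfqpipe")),
    config = config,
    inputs = file_md5(c(protein_groups_path, design_path)),
    stages = list()
  )
  note <- function(.stage, ...) {
    manifest$stages[[.stage]] <<- list(...)
    write_manifest(manifest, outdir)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages[[stage]] <<- list(error = conditionMessage(e))
      write_manifest(manifest, outdir)
      stop_lfq(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
    })
  }

  table <- run_stage("read", {
    if (generic) {
      read_intensity_matrix(protein_groups_path)
    } else {
      read_protein_groups(protein_groups_path, intensity_type = config$intensity_type)
    }
  })
  design <- run_stage("read", read_design(design_path, table))
  note("read", proteins = nrow(table), columns = length(attr(table, "intensity_cols", exact = TRUE)))

  m <- run_stage("create_intensity_frame",
    create_intensity_frame(table, design, uniq_pep_min = config$uniq_pep_min))
  note("create_intensity_frame", proteins = nrow(m))
  has_tr <- !all(is.na(im_design(m)$tech_rep))
  if (has_tr) {
    render_figure("corr_plot", file.path(outdir, "corr_plot.png"), m = m)
    m <- run_stage("average_tech_reps", average_tech_reps(m))
    note("average_tech_reps", samples = nrow(im_design(m)))
  }
  write_intensity_tsv(m, file.path(outdir, "raw.tsv"))
  render_figure("heatmap_na", file.path(outdir, "heatmap_na.png"), m = m)

  m <- run_stage("filter_by_group_na", filter_by_group_na(m, max_group_na = config$max_group_na))
  note("filter_by_group_na", proteins = nrow(m))
  write_intensity_tsv(m, file.path(outdir, "filtered.tsv"))

  pre <- m
  impute_with_sidecar <- function(mm) {
    imp <- impute_minprob(mm,
      q = config$impute_q, tune_sigma = config$tune_sigma, seed = config$seed
    )
    ip <- attr(imp, "impute_params", exact = TRUE)
    jsonlite::write_json(
      list(seed = ip$seed, q = ip$q, tune_sigma = ip$tune_sigma,
        mu = as.list(ip$mu), sigma = ip$sigma),
      file.path(outdir, "impute_params.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null"
    )
    imp
  }
  m <- run_stage("impute_normalize", switch(config$order,
    impute_first = quantile_normalize(impute_with_sidecar(m)),
    normalize_first = impute_with_sidecar(quantile_normalize(m)),
    skip_normalization = impute_with_sidecar(m),
    stop_lfq("config$order must be impute_first, normalize_first or skip_normalization")
  ))
  note("impute_normalize", order = config$order, stage = im_stage(m))
  write_intensity_tsv(m, file.path(outdir, "processed.tsv"))
  render_figure("impute_plot", file.path(outdir, "impute_plot.png"),
    before = pre, after = m
  )
  if (config$order != "skip_normalization") {
    render_figure("norm_plot", file.path(outdir, "norm_plot.png"),
      before = pre, after = m
    )
  }

  de <- run_stage("find_dep",
    find_dep(m, lfc_cut = config$lfc_cut, adj_p_cut = config$adj_p_cut))
  note("find_dep", proteins = nrow(de), significant = sum(de$significant))
  write_de_tsv(de, file.path(outdir, "de_results.tsv"))
  render_figure("volcano_plot", file.path(outdir, "volcano_plot.png"), de = de)
  if (any(de$significant)) {
    render_figure("heatmap_de", file.path(outdir, "heatmap_de.png"), de = de, m = m)
  }

  write_manifest(manifest, outdir)
  invisible(list(m = m, de = de, design = design, manifest = manifest))
}

#' Run the modeling pipeline
#'
#' Builds a classifier panel from a differential-abundance result:
#' feature selection and correlation pruning, stratified 70/30 split,
#' repeated cross-validated training, held-out class probabilities and
#' ROC/AUC. Writes a JSON run report (selected features, split
#' membership, grids, per-resample metrics, confusion matrices, ROC
#' coordinates and AUC per algorithm) plus the modeling figures under
#' `outdir`.
#'
#' @param de An `lfq_de` result with at least one significant protein.
#' @param m The complete intensity table the result was computed on.
#' @param outdir Output directory (created).
#' @param config A list from [lfq_config()].
#' @return Invisibly, a list with `mf`, `split`, `models`, `probs`,
#'   `report`.
#' @export
run_modeling <- function(de, m, outdir, config = lfq_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  mf <- select_features(de, m, top_n = config$top_n, corr_cut = config$corr_cut)
  split <- split_data(mf, train_frac = config$train_frac, seed = config$seed)
  models <- train_models(split, mf,
    algorithms = config$algorithms,
    k = config$k, repeats = config$repeats, seed = config$seed
  )
  probs <- test_models(models, split, mf)
  classes <- attr(probs, "classes", exact = TRUE)
  positive <- classes[2]

  report <- list(
    package = "lfqpipe",
    version = as.character(packageVersion("lfqpipe")),
    config = config,
    features = as.list(attr(mf, "features", exact = TRUE)$protein_id),
    split = list(train = as.list(split$train), test = as.list(split$test)),
    positive_class = positive,
    algorithms = lapply(names(models), function(alg) {
      pr <- probs[[alg]]
      cm <- table(truth = pr$truth, predicted = factor(pr$predicted, levels = classes))
      rr <- roc_auc(pr[[positive]], pr$truth, positive)
      list(
        name = alg,
        grid = if (is.null(models[[alg]]$grid)) NULL else as.list(models[[alg]]$grid),
        best = as.list(models[[alg]]$best),
        mean_cv_accuracy = models[[alg]]$mean_accuracy,
        resamples = as.list(models[[alg]]$resamples),
        confusion = as.list(as.data.frame(cm)),
        test_accuracy = mean(pr$predicted == pr$truth),
        roc = as.list(rr$roc),
        auc = rr$auc
      )
    })
  )
  jsonlite::write_json(report, file.path(outdir, "model_report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null"
  )
  render_figure("feature_plot", file.path(outdir, "feature_plot.png"), mf = mf)
  render_figure("performance_plot", file.path(outdir, "performance_plot.png"), ms = models)
  render_figure("varimp_plot", file.path(outdir, "varimp_plot.png"),
    ms = models, split = split, mf = mf, seed = config$seed
  )
  render_figure("roc_plot", file.path(outdir, "roc_plot.png"),
    ps = probs, positive_class = positive
  )
  invisible(list(mf = mf, split = split, models = models, probs = probs, report = report))
}
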