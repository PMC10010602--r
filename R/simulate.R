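# Ground-truth synthetic LFQ experiments in the MaxQuant dialect, so
# every pipeline stage is testable offline.

#' Simulate a label-free proteomics experiment
#'
#' Generates a MaxQuant-dialect protein-groups table with known ground
#' truth. Protein base abundances are drawn from
#' `Normal(base_mean, base_sd)` on the log2 scale (i.e. log-normal
#' intensities); `n_de` proteins receive a shift of `+/- effect_log2`
#' in the second group; biological replicates add
#' `Normal(0, sigma_within)` noise, and technical replicates scatter
#' around their biological value with half the variance
#' (`sigma_within / sqrt(2)`), so technical replicates are tighter than
#' biological ones. Dropout is intensity-dependent (left-censored,
#' missing-not-at-random): a cell at log2 intensity `x` is censored with
#' probability `plogis(mnar_steepness * (c - x))`, where `c` is the
#' `mnar_center` quantile of all simulated log2 intensities; censored
#' cells are written as 0 in the linear-scale table.
#' `mnar_steepness = 0` disables dropout altogether (a literal logistic
#' with zero steepness would drop half of all cells uniformly, which is
#' not a useful control). Decoy rows (contaminant / reverse / only-by-
#' site) are appended per the fraction parameters with intensities from
#' the same distribution and 1-10 unique peptides; genuine proteins get
#' 3-30 unique peptides so they pass the default peptide filter.
#'
#' @param n_proteins Number of genuine proteins (default 500).
#' @param n_de Number of differentially abundant proteins (default 50).
#' @param groups Two group names (default `c("WT", "KO")`).
#' @param bio_reps Biological replicates per group (default 3).
#' @param tech_reps Technical replicates per biological sample
#'   (default 1 = none).
#' @param effect_log2 Absolute log2 fold change of true effects
#'   (default 2).
#' @param sigma_within Between-replicate noise SD, log2 units
#'   (default 0.5).
#' @param base_mean,base_sd Log2 intensity distribution of protein base
#'   abundances (defaults 25 and 2, typical of MaxQuant LFQ scales).
#' @param mnar_center Quantile of the intensity distribution at which
#'   dropout probability is 50% (default 0.1).
#' @param mnar_steepness Steepness of the logistic dropout curve per
#'   log2 unit (default 1); 0 disables dropout.
#' @param contaminant_frac,reverse_frac,site_frac Fractions (of
#'   `n_proteins`) of appended decoy rows (defaults 0.02 each).
#' @param seed Integer seed; identical seeds give identical experiments.
#' @return A list with `table` (an `lfq_protein_groups` tibble),
#'   `design` (an `lfq_design` tibble) and `truth` (tibble `protein_id`,
#'   `true_log2fc`, `is_de`, with a `censored` attribute holding the
#'   proteins x columns censoring mask of the genuine proteins).
#'   `true_log2fc` is on the `groups[1] - groups[2]` contrast.
#' @export
simulate_lfq_experiment <- function(n_proteins = 500, n_de = 50,
                                    groups = c("WT", "KO"),
                                    bio_reps = 3, tech_reps = 1,
                                    effect_log2 = 2, sigma_within = 0.5,
                                    base_mean = 25, base_sd = 2,
                                    mnar_center = 0.1, mnar_steepness = 1,
                                    contaminant_frac = 0.02,
                                    reverse_frac = 0.02, site_frac = 0.02,
                                    seed = NULL) {
  if (n_de > n_proteins) stop_lfq("n_de must not exceed n_proteins")
  if (length(groups) != 2) stop_lfq("exactly two groups are supported")
  stopifnot(bio_reps >= 2, tech_reps >= 1)
  fracs <- c(contaminant_frac, reverse_frac, site_frac)
  if (any(fracs < 0 | fracs > 1)) stop_lfq("decoy fractions must be in [0, 1]")
  if (!(mnar_center > 0 && mnar_center < 1)) stop_lfq("mnar_center must be in (0, 1)")
  if (mnar_steepness < 0) stop_lfq("mnar_steepness must be >= 0")

  build <- function() {
    sample_ids <- as.vector(t(outer(groups, seq_len(bio_reps), paste, sep = "_")))
    sample_group <- rep(groups, each = bio_reps)
    has_tr <- tech_reps > 1
    col_sample <- rep(sample_ids, each = tech_reps)
    col_group <- rep(sample_group, each = tech_reps)
    col_tr <- rep(seq_len(tech_reps), times = length(sample_ids))
    col_label <- if (has_tr) paste0(col_sample, "_", col_tr) else col_sample
    n_cols <- length(col_label)

    ids <- sprintf("PROT%04d", seq_len(n_proteins))
    base <- rnorm(n_proteins, base_mean, base_sd)
    is_de <- rep(FALSE, n_proteins)
    is_de[sample.int(n_proteins, n_de)] <- TRUE
    shift2 <- numeric(n_proteins) # applied to group 2
    shift2[is_de] <- sample(c(-1, 1), n_de, replace = TRUE) * effect_log2
    true_lfc <- -shift2 # contrast is group1 - group2

    # biological values: proteins x biological samples
    bio_mean <- outer(base, numeric(length(sample_ids)), "+") +
      outer(shift2, as.numeric(sample_group == groups[2]), "*")
    bio_val <- bio_mean + matrix(
      rnorm(n_proteins * length(sample_ids), 0, sigma_within),
      nrow = n_proteins
    )
    # expand to technical-replicate columns
    log2_mat <- bio_val[, rep(seq_along(sample_ids), each = tech_reps), drop = FALSE]
    if (has_tr) {
      log2_mat <- log2_mat + matrix(
        rnorm(n_proteins * n_cols, 0, sigma_within / sqrt(2)),
        nrow = n_proteins
      )
    }
    colnames(log2_mat) <- col_label

    censored <- matrix(FALSE, n_proteins, n_cols, dimnames = list(ids, col_label))
    if (mnar_steepness > 0) {
      cq <- quantile(log2_mat, probs = mnar_center, type = 7)
      p_drop <- plogis(mnar_steepness * (cq - log2_mat))
      censored <- matrix(
        runif(length(p_drop)) < p_drop,
        nrow = n_proteins, dimnames = dimnames(censored)
      )
    }
    linear <- 2^log2_mat
    linear[censored] <- 0

    # decoy rows: same intensity distribution, flags set, 1-10 peptides
    n_dec <- round(fracs * n_proteins)
    n_dec_tot <- sum(n_dec)
    decoy_linear <- 2^matrix(
      rnorm(n_dec_tot * n_cols, base_mean, base_sd),
      nrow = n_dec_tot, ncol = n_cols, dimnames = list(NULL, col_label)
    )
    tbl <- tibble::tibble(
      protein_id = c(ids, sprintf("DECOY%03d", seq_len(n_dec_tot))),
      unique_peptides = c(
        sample(3:30, n_proteins, replace = TRUE),
        sample(1:10, n_dec_tot, replace = TRUE)
      ),
      is_contaminant = c(rep(FALSE, n_proteins),
        rep(c(TRUE, FALSE, FALSE), times = n_dec)),
      is_reverse = c(rep(FALSE, n_proteins),
        rep(c(FALSE, TRUE, FALSE), times = n_dec)),
      only_by_site = c(rep(FALSE, n_proteins),
        rep(c(FALSE, FALSE, TRUE), times = n_dec))
    )
    int_cols <- paste0("LFQ intensity ", col_label)
    intens <- rbind(linear, decoy_linear)
    colnames(intens) <- int_cols
    tbl <- dplyr::bind_cols(tbl, tibble::as_tibble(intens))
    table <- new_protein_groups(tbl, int_cols, "LFQ", has_peptides = TRUE)

    design <- tibble::tibble(
      column_label = int_cols,
      sample_id = col_sample,
      group = col_group,
      tech_rep = if (has_tr) col_tr else NA_integer_
    )
    design <- structure(design, class = c("lfq_design", class(tibble::tibble())))

    truth <- tibble::tibble(
      protein_id = ids, true_log2fc = true_lfc, is_de = is_de
    )
    attr(truth, "censored") <- censored
    list(table = table, design = design, truth = truth)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Write a simulated experiment to disk
#'
#' Writes a MaxQuant-dialect `proteinGroups` TSV (with
#' `LFQ intensity <sample>` columns, `+`-marked flag columns and a
#' `Unique peptides` column; censored cells as `0`) and a matching
#' design TSV (`sample<TAB>group[<TAB>tech_rep]`). Both round-trip
#' through [read_protein_groups()] and [read_design()].
#'
#' @param table An `lfq_protein_groups` tibble.
#' @param design The matching `lfq_design` tibble.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"sim"`).
#' @return Named character vector with the written `protein_groups` and
#'   `design` paths, invisibly.
#' @export
write_protein_groups <- function(table, design, dir, prefix = "sim") {
  stopifnot(inherits(table, "lfq_protein_groups"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  int_cols <- attr(table, "intensity_cols", exact = TRUE)

  flag_col <- function(x) ifelse(x, "+", "")
  out <- tibble::tibble(
    `Majority protein IDs` = table$protein_id,
    `Unique peptides` = table$unique_peptides
  )
  out <- dplyr::bind_cols(out, table[, int_cols, drop = FALSE])
  out$Reverse <- flag_col(table$is_reverse)
  out$`Potential contaminant` <- flag_col(table$is_contaminant)
  out$`Only identified by site` <- flag_col(table$only_by_site)

  pg_path <- file.path(dir, paste0(prefix, "_proteinGroups.txt"))
  readr::write_tsv(out, pg_path, progress = FALSE)

  des <- tibble::tibble(
    sample = design$sample_id,
    group = design$group
  )
  if (!all(is.na(design$tech_rep))) des$tech_rep <- design$tech_rep
  design_path <- file.path(dir, paste0(prefix, "_design.txt"))
  readr::write_tsv(des, design_path, progress = FALSE)

  invisible(c(protein_groups = pg_path, design = design_path))
}
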