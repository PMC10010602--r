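# From a raw protein-groups table to a filtered log2 intensity table.

#' Build a log2 intensity table from a protein-groups table
#'
#' Applies the standard protein-level quality filters and the log2
#' transform: rows flagged as contaminant, reverse (decoy) or
#' only-identified-by-site are removed; rows identified by fewer than
#' `uniq_pep_min` unique peptides are removed (skipped, with a notice,
#' when peptide counts are unavailable); zero intensities become missing
#' values; everything else is log2-transformed. Columns are selected and
#' ordered by the design, not by file order.
#'
#' @param table A protein-groups tibble from [read_protein_groups()] /
#'   [read_intensity_matrix()] or [simulate_lfq_experiment()].
#' @param design An `lfq_design` tibble (see [read_design()]).
#' @param uniq_pep_min Minimum unique-peptide count to keep a protein.
#'   The default 3 drops proteins identified by two or fewer unique
#'   peptides.
#' @return A tibble of class `lfq_intensity` (stage `"raw"`):
#'   `protein_id` plus one log2 intensity column per design row, named
#'   `sample_id` (or `sample_id_techrep` when technical replicates are
#'   present). Missing values are `NA`.
#' @export
create_intensity_frame <- function(table, design, uniq_pep_min = 3) {
  stopifnot(inherits(table, "lfq_protein_groups"))
  design <- validate_design(design, table)

  n0 <- nrow(table)
  flagged <- table$is_contaminant | table$is_reverse | table$only_by_site
  n_contam <- sum(table$is_contaminant)
  n_rev <- sum(table$is_reverse)
  n_site <- sum(table$only_by_site)
  keep <- !flagged

  has_pep <- isTRUE(attr(table, "has_peptides", exact = TRUE))
  n_pep <- 0L
  if (has_pep && uniq_pep_min > 0) {
    low <- !is.na(table$unique_peptides) & table$unique_peptides < uniq_pep_min
    n_pep <- sum(low & keep)
    keep <- keep & !low
  } else if (!has_pep) {
    rlang::inform("unique-peptide counts unavailable; skipping the peptide filter",
      class = "lfqpipe_log"
    )
  }
  log_stage("create_intensity_frame",
    rows_in = n0, contaminant = n_contam, reverse = n_rev,
    only_by_site = n_site, low_peptides = n_pep, retained = sum(keep)
  )
  if (!any(keep)) stop_lfq("no proteins survive filters")

  kept <- table[keep, , drop = FALSE]
  mat <- as.matrix(kept[, design$column_label, drop = FALSE])
  storage.mode(mat) <- "double"
  mat[mat == 0] <- NA_real_
  mat <- log2(mat)
  rownames(mat) <- kept$protein_id

  has_tr <- !all(is.na(design$tech_rep))
  colnames(mat) <- if (has_tr) {
    paste0(design$sample_id, "_", design$tech_rep)
  } else {
    design$sample_id
  }
  col_design <- tibble::tibble(
    column = colnames(mat),
    sample_id = design$sample_id,
    group = design$group,
    tech_rep = design$tech_rep
  )
  out <- tibble::as_tibble(as.data.frame(mat, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(protein_id = rownames(mat)), out)
  new_intensity_tbl(out, stage = "raw", design = col_design)
}

#' Average technical replicates
#'
#' Collapses the technical-replicate columns of each biological sample to
#' their arithmetic mean on the log2 scale, computed over observed values
#' only; a cell is missing in the result only when all of the sample's
#' technical replicates are missing.
#'
#' @param m A raw-stage intensity table whose design carries technical
#'   replicate indices.
#' @return An intensity table with one column per biological sample.
#' @export
average_tech_reps <- function(m) {
  stopifnot(inherits(m, "lfq_intensity"))
  design <- im_design(m)
  if (all(is.na(design$tech_rep))) {
    stop_lfq("design has no technical-replicate information; nothing to average")
  }
  mat <- im_matrix(m)
  samples <- unique(design$sample_id)
  avg <- vapply(samples, function(s) {
    cols <- design$column[design$sample_id == s]
    sub <- mat[, cols, drop = FALSE]
    rowMeans(sub, na.rm = TRUE)
  }, numeric(nrow(mat)))
  avg[is.nan(avg)] <- NA_real_ # all-replicate-missing cells
  avg <- matrix(avg,
    nrow = nrow(mat),
    dimnames = list(rownames(mat), samples)
  )
  new_design <- design[!duplicated(design$sample_id), c("sample_id", "group")]
  new_design <- tibble::tibble(
    column = new_design$sample_id,
    sample_id = new_design$sample_id,
    group = new_design$group,
    tech_rep = NA_integer_
  )
  log_stage("average_tech_reps",
    columns_in = ncol(mat), samples_out = length(samples)
  )
  im_rebuild(avg, m, stage = "raw", design = new_design)
}

#' Filter proteins by group-wise missingness
#'
#' Keeps a protein only if, in every group, its fraction of missing
#' values does not exceed `max_group_na`. The comparison is strict: a
#' protein is removed when some group's missing fraction is greater than
#' the threshold (default 0.34, i.e. proteins with more than 34% missing
#' values in at least one group are dropped).
#'
#' @param m An intensity table.
#' @param max_group_na Highest allowed missing-value fraction within any
#'   single group, in `[0, 1]`.
#' @return The filtered intensity table (possibly empty, with a warning).
#' @export
filter_by_group_na <- function(m, max_group_na = 0.34) {
  stopifnot(inherits(m, "lfq_intensity"))
  if (max_group_na < 0 || max_group_na > 1) {
    stop_lfq("max_group_na must be in [0, 1]")
  }
  design <- im_design(m)
  mat <- im_matrix(m)
  groups <- unique(design$group)
  # small slack so exact-rational boundaries (1/3 vs 1/3) are kept
  keep <- rep(TRUE, nrow(mat))
  for (g in groups) {
    cols <- design$column[design$group == g]
    frac <- rowMeans(is.na(mat[, cols, drop = FALSE]))
    keep <- keep & (frac <= max_group_na + 1e-12)
  }
  log_stage("filter_by_group_na",
    rows_in = nrow(mat), removed = sum(!keep), retained = sum(keep),
    max_group_na = max_group_na
  )
  if (!any(keep)) warn_lfq("no proteins survive the group-missingness filter")
  out <- m[keep, , drop = FALSE]
  new_intensity_tbl(out, stage = im_stage(m), design = design)
}

#' Write an intensity table as TSV
#'
#' Serializes an intensity table (proteins x samples, log2 scale) as
#' tab-separated text with `NA` for missing values.
#'
#' @param m An intensity table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_tsv <- function(m, path) {
  stopifnot(inherits(m, "lfq_intensity"))
  readr::write_tsv(tibble::as_tibble(m), path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @noRd
validate_design <- function(design, table) {
  stopifnot(inherits(design, "lfq_design") || is.data.frame(design))
  needed <- c("column_label", "sample_id", "group")
  if (!all(needed %in% names(design))) {
    stop_lfq("design must have columns column_label, sample_id, group (see read_design)")
  }
  if (!"tech_rep" %in% names(design)) design$tech_rep <- NA_integer_
  missing_cols <- setdiff(design$column_label, names(table))
  if (length(missing_cols) > 0) {
    stop_lfq(paste0(
      "design refers to intensity columns absent from the table: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  tibble::as_tibble(design)
}
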