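# Readers for the MaxQuant proteinGroups dialect, generic intensity
# matrices, and experimental-design files. All files are tab-separated
# text; LF and CRLF line endings are both accepted, decimals use "." only.

#' Read a MaxQuant proteinGroups table
#'
#' Parses a tab-delimited `proteinGroups.txt` file into a protein-groups
#' tibble: one row per protein group, with protein IDs, unique-peptide
#' counts, decoy/contaminant flags and the linear-scale intensity columns
#' of the requested type.
#'
#' Intensity columns are recognised by their MaxQuant prefix
#' (`"LFQ intensity "`, `"iBAQ "` or `"Intensity "`); the remainder of the
#' column name is the sample label. Flag columns (`Reverse`,
#' `Potential contaminant` or the older `Contaminant`,
#' `Only identified by site`) mark a row with a literal `"+"`; anything
#' else counts as unflagged. Blank intensity cells are read as 0.
#'
#' @param path Path to a tab-delimited proteinGroups file.
#' @param intensity_type One of `"LFQ"`, `"iBAQ"`, `"Intensity"`; selects
#'   which family of intensity columns to keep.
#' @return A tibble of class `lfq_protein_groups` with columns
#'   `protein_id`, `unique_peptides`, `is_contaminant`, `is_reverse`,
#'   `only_by_site`, followed by one column per intensity column (original
#'   names, linear scale). Attributes: `intensity_cols` (column names),
#'   `intensity_type`, `has_peptides`.
#' @export
read_protein_groups <- function(path, intensity_type = c("LFQ", "iBAQ", "Intensity")) {
  intensity_type <- match.arg(intensity_type)
  raw <- read_tsv_text(path)
  prefix <- intensity_prefixes[[intensity_type]]
  int_cols <- grep(paste0("^", prefix), names(raw), value = TRUE)
  # "Intensity " must not swallow "LFQ intensity ..." columns
  if (intensity_type == "Intensity") {
    int_cols <- setdiff(int_cols, grep("^(LFQ intensity |iBAQ )", names(raw), value = TRUE))
  }
  if (length(int_cols) == 0) {
    stop_lfq(sprintf(
      "no intensity columns of type '%s' found: expected column names starting with \"%s\"",
      intensity_type, prefix
    ), class = "lfqpipe_format_error")
  }

  id_col <- intersect(c("Majority protein IDs", "Protein IDs", "Protein"), names(raw))[1]
  if (is.na(id_col)) {
    stop_lfq("no protein ID column found (expected 'Majority protein IDs' or 'Protein IDs')",
      class = "lfqpipe_format_error"
    )
  }

  contam_col <- intersect(c("Potential contaminant", "Contaminant"), names(raw))[1]
  pep_col <- intersect(c("Unique peptides", "Razor + unique peptides"), names(raw))[1]
  has_peptides <- !is.na(pep_col)
  if (!has_peptides) {
    warn_lfq("no unique-peptides column found; peptide counts set to 0 and the peptide filter will be skipped")
  }

  flag_of <- function(col) {
    if (is.na(col) || !col %in% names(raw)) {
      rep(FALSE, nrow(raw))
    } else {
      !is.na(raw[[col]]) & trimws(raw[[col]]) == "+"
    }
  }

  intens <- parse_numeric_block(raw, int_cols, path)

  out <- tibble::tibble(
    protein_id = as.character(raw[[id_col]]),
    unique_peptides = if (has_peptides) {
      as.integer(parse_numeric_block(raw, pep_col, path)[, 1])
    } else {
      rep(0L, nrow(raw))
    },
    is_contaminant = flag_of(contam_col),
    is_reverse = flag_of(if ("Reverse" %in% names(raw)) "Reverse" else NA_character_),
    only_by_site = flag_of(if ("Only identified by site" %in% names(raw)) "Only identified by site" else NA_character_)
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(intens))
  new_protein_groups(out, int_cols, intensity_type, has_peptides)
}

#' Read a generic protein x sample intensity matrix
#'
#' Reads a plain tab-delimited table whose first column holds protein IDs
#' and whose remaining columns are numeric linear-scale intensities, and
#' returns it in the same protein-groups form as [read_protein_groups()],
#' with all decoy flags false and unique-peptide counts marked unavailable
#' (the peptide filter is then skipped, with a notice).
#'
#' @param path Path to a tab-delimited file.
#' @return A tibble of class `lfq_protein_groups`; see
#'   [read_protein_groups()].
#' @export
read_intensity_matrix <- function(path) {
  raw <- read_tsv_text(path)
  if (ncol(raw) < 2) {
    stop_lfq("intensity matrix needs an ID column plus at least one sample column",
      class = "lfqpipe_format_error"
    )
  }
  ids <- as.character(raw[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop_lfq(paste0(
      "duplicate protein IDs in intensity matrix: ",
      paste(dup, collapse = ", ")
    ))
  }
  int_cols <- names(raw)[-1]
  intens <- parse_numeric_block(raw, int_cols, path)
  rlang::inform("no unique-peptide information in a generic intensity matrix; the peptide filter will be skipped",
    class = "lfqpipe_log"
  )
  out <- tibble::tibble(
    protein_id = ids,
    unique_peptides = NA_integer_,
    is_contaminant = FALSE,
    is_reverse = FALSE,
    only_by_site = FALSE
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(intens))
  new_protein_groups(out, int_cols, "generic", has_peptides = FALSE)
}

#' Read an experimental-design file
#'
#' The design file is tab-delimited with a header and columns
#' `sample`, `group` and optionally `tech_rep` (a positive integer).
#' Each row describes one intensity column of `table`. A row is matched to
#' its column by trying, in order: the `sample` value as a full column
#' name; `sample` plus `"_<tech_rep>"` as a full column name; and both of
#' those as the sample label following the table's intensity prefix
#' (e.g. `sample = "WT_1", tech_rep = 2` matches
#' `"LFQ intensity WT_1_2"`).
#'
#' @param path Path to the design file.
#' @param table A protein-groups tibble the design refers to.
#' @return A tibble of class `lfq_design` with columns `column_label`,
#'   `sample_id`, `group`, `tech_rep` (NA when absent from the file).
#' @export
read_design <- function(path, table) {
  stopifnot(inherits(table, "lfq_protein_groups"))
  raw <- read_tsv_text(path)
  names(raw) <- tolower(names(raw))
  if (!all(c("sample", "group") %in% names(raw))) {
    stop_lfq("design file must have columns 'sample' and 'group' (tab-delimited, with header)",
      class = "lfqpipe_format_error"
    )
  }
  has_tr <- "tech_rep" %in% names(raw)
  tr <- if (has_tr) suppressWarnings(as.integer(raw$tech_rep)) else rep(NA_integer_, nrow(raw))
  if (has_tr && (any(is.na(tr)) || any(tr < 1))) {
    stop_lfq("tech_rep must be a positive integer for every design row")
  }

  int_cols <- attr(table, "intensity_cols", exact = TRUE)
  itype <- attr(table, "intensity_type", exact = TRUE)
  prefix <- if (itype %in% names(intensity_prefixes)) intensity_prefixes[[itype]] else ""

  resolve_one <- function(sample, tech_rep) {
    cand <- c(sample, if (!is.na(tech_rep)) paste0(sample, "_", tech_rep))
    cand <- c(cand, paste0(prefix, cand))
    hit <- cand[cand %in% int_cols]
    if (length(hit) == 0) {
      stop_lfq(sprintf(
        "design row for sample '%s' does not match any intensity column (tried: %s)",
        sample, paste(unique(cand), collapse = ", ")
      ))
    }
    hit[1]
  }
  labels <- mapply(resolve_one, as.character(raw$sample), tr)

  design <- tibble::tibble(
    column_label = unname(labels),
    sample_id = as.character(raw$sample),
    group = as.character(raw$group),
    tech_rep = tr
  )
  if (anyDuplicated(design$column_label)) {
    stop_lfq("two design rows resolve to the same intensity column")
  }
  key <- paste(design$sample_id, design$tech_rep, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- design[duplicated(key), , drop = FALSE]
    stop_lfq(paste0(
      "duplicate (sample, tech_rep) in design: ",
      paste(unique(paste0(dup$sample_id, "/", dup$tech_rep)), collapse = ", ")
    ))
  }
  if (length(unique(design$group)) < 2) {
    warn_lfq("design lists fewer than 2 groups; differential abundance will not be possible")
  }
  structure(design, class = c("lfq_design", class(tibble::tibble())))
}

#' @noRd
new_protein_groups <- function(x, intensity_cols, intensity_type, has_peptides) {
  structure(
    tibble::as_tibble(x),
    intensity_cols = intensity_cols,
    intensity_type = intensity_type,
    has_peptides = has_peptides,
    class = c("lfq_protein_groups", class(tibble::tibble()))
  )
}

# All columns read as character so that flags ("+") and numerics coexist;
# numeric parsing is explicit and locale-independent.
#' @noRd
read_tsv_text <- function(path) {
  if (!file.exists(path)) stop_lfq(sprintf("file not found: %s", path))
  readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE, na = character(),
    locale = readr::locale(decimal_mark = ".")
  )
}

# Parse selected character columns to doubles; blank -> 0; any other
# unparseable cell is an error with its coordinates.
#' @noRd
parse_numeric_block <- function(raw, cols, path) {
  mat <- matrix(NA_real_, nrow = nrow(raw), ncol = length(cols),
    dimnames = list(NULL, cols)
  )
  for (j in seq_along(cols)) {
    cell <- trimws(raw[[cols[j]]])
    cell[cell == "" | toupper(cell) == "NAN"] <- "0"
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(val) & toupper(cell) != "NA")
    if (length(bad) > 0) {
      stop_lfq(sprintf(
        "unparseable numeric value '%s' at row %d, column '%s' of %s",
        raw[[cols[j]]][bad[1]], bad[1], cols[j], path
      ))
    }
    val[is.na(val)] <- 0
    mat[, j] <- val
  }
  if (any(mat < 0)) stop_lfq("negative intensities are not allowed")
  mat
}
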