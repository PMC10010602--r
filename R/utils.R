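# Internal helpers shared across the pipeline.

#' @noRd
stop_lfq <- function(msg, class = "lfqpipe_error", ...) {
  rlang::abort(msg, class = class, ...)
}

#' @noRd
warn_lfq <- function(msg, class = "lfqpipe_warning") {
  rlang::warn(msg, class = class)
}

# Structured per-stage log line: machine-parseable key=value pairs.
#' @noRd
log_stage <- function(stage, ...) {
  kv <- list(...)
  vals <- vapply(kv, function(v) paste(format(v), collapse = ","), character(1))
  txt <- paste(paste0(names(kv), "=", vals), collapse = " ")
  rlang::inform(paste0("[", stage, "] ", txt), class = "lfqpipe_log")
}

# Intensity column prefixes for the supported MaxQuant dialects.
intensity_prefixes <- c(
  LFQ = "LFQ intensity ",
  iBAQ = "iBAQ ",
  Intensity = "Intensity "
)

# round-half-up, used for the per-class training-set size.
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

# Extract the numeric matrix (proteins x samples) from an intensity tibble.
#' @noRd
im_matrix <- function(m) {
  stopifnot(inherits(m, "lfq_intensity"))
  mat <- as.matrix(m[, setdiff(names(m), "protein_id"), drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- m$protein_id
  mat
}

# Rebuild an intensity tibble from a matrix, carrying design/stage attributes.
#' @noRd
im_rebuild <- function(mat, template, stage = NULL, design = NULL) {
  out <- tibble::as_tibble(as.data.frame(mat, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(protein_id = rownames(mat)), out)
  new_intensity_tbl(
    out,
    stage = stage %||% im_stage(template),
    design = design %||% im_design(template)
  )
}

#' @noRd
new_intensity_tbl <- function(x, stage, design) {
  stopifnot(stage %in% c("raw", "imputed", "normalized"))
  structure(
    tibble::as_tibble(x),
    stage = stage,
    design = design,
    class = c("lfq_intensity", class(tibble::tibble()))
  )
}

#' Stage of an intensity table
#'
#' Intensity tables carry a stage tag (`"raw"`, `"imputed"` or
#' `"normalized"`) recording where in the pipeline they were produced.
#'
#' @param m An intensity table created by [create_intensity_frame()].
#' @return A length-one character vector.
#' @export
im_stage <- function(m) attr(m, "stage", exact = TRUE)

#' Per-column design of an intensity table
#'
#' @param m An intensity table created by [create_intensity_frame()].
#' @return A tibble with one row per intensity column: `column`,
#'   `sample_id`, `group` and (if present) `tech_rep`.
#' @export
im_design <- function(m) attr(m, "design", exact = TRUE)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Subclassed tibbles keep attributes through dplyr verbs poorly; the
# pipeline re-attaches them explicitly, so losing them elsewhere is fine.
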