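# Fixtures are built in code at test time; nothing binary on disk.

# A tiny hand-written proteinGroups file exercising all flag columns.
write_toy_protein_groups <- function(path = tempfile(fileext = ".txt")) {
  lines <- c(
    paste("Majority protein IDs", "LFQ intensity A", "LFQ intensity B",
      "Reverse", "Potential contaminant", "Only identified by site",
      "Unique peptides",
      sep = "\t"
    ),
    paste("P1", "1000", "2000", "", "", "", "5", sep = "\t"),
    paste("P2", "8", "0", "+", "", "", "4", sep = "\t"),
    paste("P3", "300", "", "", "+", "", "3", sep = "\t")
  )
  writeLines(lines, path)
  path
}

# Build an intensity table directly from a matrix (log2 scale),
# bypassing the readers; groups assigns a label per column.
intensity_from_matrix <- function(mat, groups,
                                  stage = "raw", tech_rep = NULL) {
  if (is.null(colnames(mat))) {
    colnames(mat) <- paste0("S", seq_len(ncol(mat)))
  }
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("P%03d", seq_len(nrow(mat)))
  }
  design <- tibble::tibble(
    column = colnames(mat),
    sample_id = colnames(mat),
    group = groups,
    tech_rep = if (is.null(tech_rep)) NA_integer_ else tech_rep
  )
  out <- tibble::as_tibble(as.data.frame(mat, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(protein_id = rownames(mat)), out)
  structure(out,
    stage = stage, design = design,
    class = c("lfq_intensity", class(tibble::tibble()))
  )
}

# Gaussian two-group matrix with optional true effects; returns the
# intensity table plus the truth flags.
gaussian_two_group <- function(n_proteins, n_per_group, effect_ids = integer(0),
                               effect = 0, sigma = 1, base = 25, seed = 1) {
  withr::with_seed(seed, {
    mat <- matrix(rnorm(n_proteins * 2 * n_per_group, base, sigma),
      nrow = n_proteins
    )
    mat[effect_ids, seq_len(n_per_group)] <-
      mat[effect_ids, seq_len(n_per_group)] + effect
    colnames(mat) <- c(
      paste0("A", seq_len(n_per_group)),
      paste0("B", seq_len(n_per_group))
    )
    rownames(mat) <- sprintf("P%04d", seq_len(n_proteins))
    intensity_from_matrix(mat, rep(c("A", "B"), each = n_per_group),
      stage = "imputed"
    )
  })
}

# A linearly separable modeling frame: two classes far apart relative
# to noise.
separable_model_frame <- function(n_per_class = 16, n_features = 5,
                                  gap = 8, sigma = 0.5, seed = 42) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    cls <- rep(c("healthy", "disease"), each = n_per_class)
    X <- matrix(rnorm(n * n_features, 0, sigma), nrow = n)
    X[cls == "disease", ] <- X[cls == "disease", ] + gap
    colnames(X) <- sprintf("FEAT%02d", seq_len(n_features))
    out <- tibble::tibble(
      sample_id = sprintf("s%02d", seq_len(n)),
      class = cls
    )
    out <- dplyr::bind_cols(out, tibble::as_tibble(X))
    structure(out,
      features = tibble::tibble(
        protein_id = colnames(X),
        adj_p_value = seq_len(n_features) * 1e-4
      ),
      classes = c("healthy", "disease"),
      class = c("lfq_model_frame", class(tibble::tibble()))
    )
  })
}

# Brute-force BH step-up straight from the definition (independent of
# the implementation under test).
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}
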