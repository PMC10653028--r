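#' @importFrom rlang .data abort warn
#' @importFrom dplyr %>%
NULL

# Internal: coerce a tidy count table (feature_id + one column per sample)
# to an integer matrix with feature rownames. Validates the CountMatrix
# invariants: non-negative integral counts, no duplicate ids.
counts_to_matrix <- function(counts, id_col = "feature_id") {
  if (!is.data.frame(counts)) {
    abort("`counts` must be a data frame (feature_id + sample columns).")
  }
  if (!id_col %in% names(counts)) {
    abort(sprintf("`counts` must have a `%s` column.", id_col))
  }
  ids <- as.character(counts[[id_col]])
  if (anyDuplicated(ids)) {
    abort("duplicate feature ids in count table.")
  }
  m <- as.matrix(counts[setdiff(names(counts), id_col)])
  if (!is.numeric(m)) abort("count columns must be numeric.")
  if (anyDuplicated(colnames(m))) abort("duplicate sample ids in count table.")
  if (any(is.na(m))) abort("counts must not contain NA.")
  if (any(m < 0)) abort("counts must be non-negative.")
  if (any(abs(m - round(m)) > 1e-8)) abort("counts must be integers.")
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

matrix_to_counts <- function(m, id_col = "feature_id") {
  tibble::as_tibble(m, rownames = id_col)
}

# Internal: validate a sample sheet against the columns a design needs.
check_sample_sheet <- function(samples, require_assay = TRUE) {
  needed <- c("sample_id", "condition", "replicate")
  if (require_assay) needed <- c(needed, "assay")
  missing <- setdiff(needed, names(samples))
  if (length(missing) > 0) {
    abort(sprintf("sample sheet is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (require_assay && !all(samples$assay %in% c("IP", "input"))) {
    abort("`assay` must be 'IP' or 'input'.")
  }
  key <- if ("assay" %in% names(samples)) {
    paste(samples$condition, samples$assay, samples$replicate)
  } else {
    paste(samples$condition, samples$replicate)
  }
  if (anyDuplicated(key)) {
    abort("(condition, assay, replicate) combinations must be unique.")
  }
  invisible(samples)
}

# Internal: align a count matrix's columns to the sample sheet order.
align_samples <- function(m, samples) {
  missing <- setdiff(samples$sample_id, colnames(m))
  if (length(missing) > 0) {
    abort(sprintf("samples absent from count table: %s",
                  paste(missing, collapse = ", ")))
  }
  m[, samples$sample_id, drop = FALSE]
}

# Two-level condition factor; first level is the reference (condition A).
condition_factor <- function(condition) {
  f <- if (is.factor(condition)) droplevels(condition) else factor(condition)
  if (nlevels(f) != 2) {
    abort(sprintf("exactly two conditions required, got: %s",
                  paste(levels(f), collapse = ", ")))
  }
  f
}

LOG2 <- log(2)
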