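# Readers and writers for the plain-text dialects the pipeline speaks:
# TSV count tables and sample sheets, BED / bedGraph (0-based,
# half-open), GMT gene sets, GTF-lite gene models (1-based inclusive on
# disk, converted on read).  All writers produce UTF-8, LF-terminated
# TSV with '.' unused (R NA never reaches canonical outputs), so
# write(read(x)) round-trips byte-identically.

#' Read / write a count table
#'
#' TSV with a `feature_id` first column and one integer column per
#' sample.  Malformed values (negative, non-integer, missing) are
#' rejected with the offending row numbers.
#'
#' @param path File path.
#' @return A count tibble.
#' @export
read_counts <- function(path) {
  x <- suppressWarnings(
    readr::read_tsv(path, show_col_types = FALSE, na = character(),
                    col_types = readr::cols(
                      readr::col_character(),
                      .default = readr::col_double())))
  names(x)[1] <- "feature_id"
  num <- as.matrix(x[-1])
  bad <- which(rowSums(is.na(num) | num < 0 |
                         abs(num - round(num)) > 1e-8) > 0)
  if (length(bad) > 0) {
    abort(sprintf("malformed counts at data row(s): %s",
                  paste(utils::head(bad, 10), collapse = ", ")))
  }
  counts_to_matrix(x)                 # full invariant check
  x
}

#' @rdname read_counts
#' @param x Count tibble.
#' @export
write_counts <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read / write a sample sheet
#'
#' TSV with columns `sample_id`, `condition`, `assay`, `replicate`
#' (plus any extras); missing required columns are named in the error.
#'
#' @param path File path.
#' @param require_assay Whether the `assay` column is required.
#' @return A sample-sheet tibble.
#' @export
read_sample_sheet <- function(path, require_assay = TRUE) {
  x <- readr::read_tsv(path, show_col_types = FALSE, na = character())
  check_sample_sheet(x, require_assay = require_assay)
  x$replicate <- as.integer(x$replicate)
  x
}

#' @rdname read_sample_sheet
#' @param x Sample-sheet tibble.
#' @export
write_sample_sheet <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read / write BED intervals (0-based, half-open)
#'
#' BED3+ with optional `name`, `score`, `strand`.  Rows with
#' `start >= end` or negative coordinates are rejected with their line
#' numbers.
#'
#' @param path File path.
#' @return Tibble with `contig`, `start`, `end` and any further BED
#'   columns present.
#' @export
read_bed <- function(path) {
  cols <- c("contig", "start", "end", "name", "score", "strand")
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       na = character())
  names(x) <- cols[seq_len(min(ncol(x), 6))]
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  bad <- which(x$start < 0 | x$start >= x$end)
  if (length(bad) > 0) {
    abort(sprintf("invalid BED interval at line(s): %s",
                  paste(utils::head(bad, 10), collapse = ", ")))
  }
  x
}

#' @rdname read_bed
#' @param x Interval tibble.
#' @export
write_bed <- function(x, path) {
  readr::write_tsv(x, path, col_names = FALSE)
  invisible(path)
}

#' Read / write bedGraph coverage (0-based, half-open)
#'
#' @param path File path.
#' @return Tibble with `contig`, `start`, `end`, `depth`.
#' @export
read_bedgraph <- function(path) {
  x <- readr::read_tsv(path, col_names = c("contig", "start", "end",
                                           "depth"),
                       show_col_types = FALSE, na = character())
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  bad <- which(x$start < 0 | x$start >= x$end | x$depth < 0)
  if (length(bad) > 0) {
    abort(sprintf("invalid bedGraph row at line(s): %s",
                  paste(utils::head(bad, 10), collapse = ", ")))
  }
  x
}

#' @rdname read_bedgraph
#' @param x Coverage tibble.
#' @export
write_bedgraph <- function(x, path) {
  readr::write_tsv(x[c("contig", "start", "end", "depth")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids.
#'
#' @param path File path.
#' @return Tibble with `set_name`, `gene_id`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  purrr::map_dfr(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort(sprintf("GMT line with fewer than 3 fields: %.40s", ln))
    }
    tibble::tibble(set_name = parts[1], gene_id = parts[-(1:2)])
  })
}

#' Read a GTF-lite gene-model table
#'
#' TSV with columns `transcript_id`, `gene_id`, `feature`, `contig`,
#' `start`, `end`, `strand`; coordinates are 1-based inclusive on disk
#' and converted to 0-based half-open on read (so downstream interval
#' arithmetic matches BED).
#'
#' @param path File path.
#' @return Gene-model tibble in 0-based half-open coordinates.
#' @export
read_gene_models <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, na = character())
  needed <- c("transcript_id", "gene_id", "feature", "contig",
              "start", "end", "strand")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(sprintf("gene-model table missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  x$start <- as.integer(x$start) - 1L   # 1-based inclusive -> 0-based half-open
  x$end <- as.integer(x$end)
  bad <- which(x$start < 0 | x$start >= x$end)
  if (length(bad) > 0) {
    abort(sprintf("invalid gene-model interval at row(s): %s",
                  paste(utils::head(bad, 10), collapse = ", ")))
  }
  x
}
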