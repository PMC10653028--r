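#' Window-based IP-over-input peak calling
#'
#' A lightweight enrichment caller on coverage tracks: the genome is
#' tiled into fixed windows, each window's IP read count is tested
#' against a depth-scaled input expectation with a Poisson upper tail,
#' p-values are BH-adjusted across windows, and significant windows
#' within `merge_gap` of each other are merged into peaks.  The local
#' expectation is floored at the genome-wide mean IP count per window so
#' that zero-input windows cannot produce spurious calls.
#'
#' Coverage tracks are bedGraph-style tibbles (`contig`, `start`, `end`,
#' `depth`; 0-based half-open).  Per-base coverage is converted to
#' approximate read counts by dividing by `read_length`.
#'
#' @param ip,input Coverage tracks for the IP and input libraries (same
#'   contigs).
#' @param window Window width in bp (default 100, matching ~100-nt
#'   methylation-site resolution).
#' @param alpha BH-adjusted significance threshold per window.
#' @param merge_gap Maximum gap (bp) between significant windows merged
#'   into one peak.
#' @param read_length Assumed read/fragment extension length used to
#'   turn summed per-base depth into counts.
#' @return A tibble of peaks: `contig`, `start`, `end`, `peak_id`,
#'   `ip_count`, `expected`, `enrichment`, `p_min`, `score`
#'   (`-10 log10 p_min`), sorted by position.  Empty tracks yield an
#'   empty tibble with a warning.
#' @export
call_enriched_windows <- function(ip, input, window = 100, alpha = 0.05,
                                  merge_gap = 100, read_length = 100) {
  for (tr in list(ip, input)) {
    if (!all(c("contig", "start", "end", "depth") %in% names(tr))) {
      abort("tracks need columns contig, start, end, depth.")
    }
  }
  if (nrow(ip) == 0 || nrow(input) == 0) {
    warn("empty coverage track; no peaks called.")
    return(tibble::tibble(contig = character(), start = integer(),
                          end = integer(), peak_id = character(),
                          ip_count = double(), expected = double(),
                          enrichment = double(), p_min = double(),
                          score = double()))
  }
  if (!setequal(unique(ip$contig), unique(input$contig))) {
    abort("IP and input tracks must cover the same contigs.")
  }
  contigs <- sort(unique(ip$contig))
  win <- purrr::map_dfr(contigs, function(ctg) {
    ip_c <- ip[ip$contig == ctg, ]
    in_c <- input[input$contig == ctg, ]
    L <- max(ip_c$end, in_c$end)
    n_win <- ceiling(L / window)
    tibble::tibble(
      contig = ctg,
      idx = seq_len(n_win) - 1L,
      ip_count = window_counts(ip_c, window, n_win, read_length),
      input_count = window_counts(in_c, window, n_win, read_length))
  })
  total_input <- sum(win$input_count)
  if (total_input <= 0) abort("total input signal must be positive.")
  scale <- sum(win$ip_count) / total_input
  background <- mean(win$ip_count)     # genome-wide IP floor
  win$expected <- pmax(win$input_count * scale, background)
  win$p <- stats::ppois(win$ip_count - 1, win$expected, lower.tail = FALSE)
  win$padj <- bh_adjust(win$p)
  sig <- win[win$padj < alpha & win$ip_count > win$expected, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(tibble::tibble(contig = character(), start = integer(),
                          end = integer(), peak_id = character(),
                          ip_count = double(), expected = double(),
                          enrichment = double(), p_min = double(),
                          score = double()))
  }
  sig$start <- sig$idx * window
  sig$end <- pmin((sig$idx + 1) * window,
                  vapply(sig$contig, function(ctg)
                    max(ip$end[ip$contig == ctg],
                        input$end[input$contig == ctg]), double(1)))
  sig <- dplyr::arrange(sig, .data$contig, .data$start)
  new_peak <- c(TRUE, sig$contig[-1] != sig$contig[-nrow(sig)] |
                  sig$start[-1] - sig$end[-nrow(sig)] > merge_gap)
  sig$peak_grp <- cumsum(new_peak)
  peaks <- sig %>%
    dplyr::group_by(.data$peak_grp) %>%
    dplyr::summarise(
      contig = .data$contig[1],
      start = min(.data$start), end = max(.data$end),
      ip_count = sum(.data$ip_count), expected = sum(.data$expected),
      p_min = min(.data$p), .groups = "drop") %>%
    dplyr::mutate(
      enrichment = .data$ip_count / .data$expected,
      score = -10 * log10(pmax(.data$p_min, 1e-300)),
      peak_id = sprintf("peak_%05d", dplyr::row_number())) %>%
    dplyr::select("contig", "start", "end", "peak_id", "ip_count",
                  "expected", "enrichment", "p_min", "score")
  peaks
}

# Sum per-base depth into fixed windows and convert to counts.
window_counts <- function(track, window, n_win, read_length) {
  L <- n_win * window
  delta <- numeric(L + 1L)
  s <- pmin(track$start, L - 1L)
  e <- pmin(track$end, L)
  add <- rowsum(track$depth, s)
  delta[as.integer(rownames(add)) + 1L] <-
    delta[as.integer(rownames(add)) + 1L] + add[, 1]
  sub <- rowsum(track$depth, e)
  delta[as.integer(rownames(sub)) + 1L] <-
    delta[as.integer(rownames(sub)) + 1L] - sub[, 1]
  depth <- cumsum(delta)[seq_len(L)]
  idx <- rep(seq_len(n_win), each = window)
  round(rowsum(depth, idx)[, 1] / read_length)
}

#' Annotate peaks with host gene and transcript-feature category
#'
#' Assigns each peak the gene with which it shares the largest overlap
#' and a single location category (`5UTR`, `CDS`, `3UTR`, `intron`,
#' `ncRNA`, or `intergenic`).  Within the chosen gene the category with
#' the largest overlap wins; exact ties are broken by the precedence
#' `3UTR > 5UTR > CDS > intron > ncRNA`, reflecting where m6A
#' concentrates.
#'
#' @param peaks Peak tibble with `contig`, `start`, `end` and (ideally)
#'   `peak_id`; 0-based half-open coordinates.
#' @param gene_models Gene-model tibble with `transcript_id`, `gene_id`,
#'   `feature` (one of the categories above, plus optional `transcript`
#'   span rows used for validation), `contig`, `start`, `end`, `strand`;
#'   0-based half-open (see [read_gene_models()]).
#' @param precedence Category precedence, highest first.
#' @return The peaks tibble with `gene_id`, `category` and
#'   `overlap_length` columns added.
#' @export
annotate_peaks <- function(peaks, gene_models,
                           precedence = c("3UTR", "5UTR", "CDS",
                                          "intron", "ncRNA")) {
  if (!"peak_id" %in% names(peaks)) {
    peaks$peak_id <- sprintf("peak_%05d", seq_len(nrow(peaks)))
  }
  feats <- gene_models[gene_models$feature %in% precedence, , drop = FALSE]
  spans <- gene_models[gene_models$feature == "transcript", , drop = FALSE]
  if (nrow(spans) > 0) {
    chk <- dplyr::inner_join(
      feats, spans,
      by = "transcript_id", suffix = c("", ".span"))
    bad <- chk$start < chk$start.span | chk$end > chk$end.span
    if (any(bad)) {
      abort(sprintf("malformed gene model: feature outside transcript %s",
                    paste(unique(chk$transcript_id[bad]), collapse = ", ")))
    }
  }
  ov <- dplyr::inner_join(
    dplyr::select(peaks, "peak_id", "contig", "start", "end"),
    dplyr::select(feats, "gene_id", "feature", "contig",
                  f_start = "start", f_end = "end"),
    by = "contig", relationship = "many-to-many") %>%
    dplyr::mutate(overlap = pmin(.data$end, .data$f_end) -
                    pmax(.data$start, .data$f_start)) %>%
    dplyr::filter(.data$overlap > 0)
  best <- ov %>%
    dplyr::group_by(.data$peak_id, .data$gene_id, .data$feature) %>%
    dplyr::summarise(overlap = sum(.data$overlap), .groups = "drop_last") %>%
    dplyr::mutate(gene_total = sum(.data$overlap)) %>%
    dplyr::ungroup() %>%
    dplyr::group_by(.data$peak_id) %>%
    dplyr::filter(.data$gene_total == max(.data$gene_total)) %>%
    dplyr::arrange(.data$gene_id, .by_group = TRUE) %>%   # stable gene tie-break
    dplyr::filter(.data$gene_id == .data$gene_id[1]) %>%
    dplyr::mutate(prec = match(.data$feature, precedence)) %>%
    dplyr::arrange(dplyr::desc(.data$overlap), .data$prec,
                   .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup() %>%
    dplyr::select("peak_id", "gene_id", category = "feature",
                  overlap_length = "overlap")
  out <- dplyr::left_join(peaks, best, by = "peak_id")
  out$category[is.na(out$category)] <- "intergenic"
  out$overlap_length[is.na(out$overlap_length)] <- 0
  out
}

#' Peak location-category distributions and their comparison
#'
#' Per-group proportions of peaks in each location category, with a
#' chi-square test of whether the distributions differ between groups.
#'
#' @param annotated [annotate_peaks()] output with a `group` column (or
#'   supply `group` as a vector of labels, one per peak).
#' @param group Optional vector of group labels overriding the `group`
#'   column.
#' @return A tibble (`group`, `category`, `n`, `proportion`), with the
#'   chi-square `htest` attached as `attr(, "test")`.  Proportions sum
#'   to 1 within each group.
#' @export
location_distribution <- function(annotated, group = NULL) {
  if (!is.null(group)) annotated$group <- group
  if (!"group" %in% names(annotated)) {
    abort("provide a `group` column or the `group` argument.")
  }
  if (any(table(annotated$group) == 0) || nrow(annotated) == 0) {
    abort("every group needs >= 1 peak.")
  }
  tab <- table(annotated$group, annotated$category)
  if (any(rowSums(tab) == 0)) abort("every group needs >= 1 peak.")
  out <- tibble::as_tibble(tab, .name_repair = "minimal")
  names(out) <- c("group", "category", "n")
  out <- out %>%
    dplyr::group_by(.data$group) %>%
    dplyr::mutate(proportion = .data$n / sum(.data$n)) %>%
    dplyr::ungroup()
  test <- if (nrow(tab) > 1 && ncol(tab) > 1) {
    suppressWarnings(stats::chisq.test(tab))
  } else {
    NULL
  }
  attr(out, "test") <- test
  out
}
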