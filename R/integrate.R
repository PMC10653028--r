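#' Intersect differential methylation with differential expression
#'
#' Candidates are genes carrying at least one directional differentially
#' methylated peak (from the consensus cascade) that are also retained
#' as differentially expressed.  Each candidate is classified into a
#' regulatory quadrant from the signs of its corrected methylation LFC
#' and its expression LFC: `hypo-up` (e.g. a transcript losing m6A and
#' gaining expression), `hypo-down`, `hyper-up`, `hyper-down`.
#'
#' @param dm A [consensus_and_filter()] result.
#' @param de A [run_diffexpr()] result.
#' @return A tibble with one row per candidate gene: `gene_id`,
#'   `peak_ids` (semicolon-collapsed), `n_peaks`, `lfc_meth_corrected`
#'   (the directional peak with the largest absolute corrected LFC),
#'   `lfc_expr` (shrunk), `quadrant`.  Per-peak and per-gene counts of
#'   the DM-and-DE overlap are attached as `attr(, "overlap_counts")`.
#' @export
overlap_and_classify <- function(dm, de) {
  directional <- dm[dm$direction != "none" & !is.na(dm$gene_id), ,
                    drop = FALSE]
  retained <- de[de$retained, , drop = FALSE]
  merged <- dplyr::inner_join(
    directional, dplyr::select(retained, "gene_id",
                               lfc_expr = "lfc_shrunk"),
    by = "gene_id")
  cand <- merged %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::arrange(dplyr::desc(abs(.data$lfc_meth_corrected)),
                   .data$peak_id, .by_group = TRUE) %>%
    dplyr::summarise(
      peak_ids = paste(sort(.data$peak_id), collapse = ";"),
      n_peaks = dplyr::n(),
      lfc_meth_corrected = .data$lfc_meth_corrected[1],
      lfc_expr = .data$lfc_expr[1],
      .groups = "drop") %>%
    dplyr::mutate(
      quadrant = paste0(
        ifelse(.data$lfc_meth_corrected >= 0, "hyper", "hypo"),
        "-",
        ifelse(.data$lfc_expr >= 0, "up", "down"))) %>%
    dplyr::arrange(.data$gene_id)
  attr(cand, "overlap_counts") <- tibble::tibble(
    dm_peaks_directional = nrow(directional),
    dm_genes = dplyr::n_distinct(directional$gene_id),
    de_genes_retained = nrow(retained),
    candidate_genes = nrow(cand),
    candidate_peaks = nrow(merged))
  cand
}

#' Hypergeometric gene-set over-representation
#'
#' One-sided upper-tail hypergeometric test of each gene set's overlap
#' with the candidate list against a stated gene universe, BH-adjusted
#' across sets.  This is the over-representation form of a gene-set
#' membership filter: for a fixed candidate list (rather than a ranked
#' genome-wide list) it is the appropriate enrichment statistic.
#'
#' @param candidates Candidate gene ids (character vector or a tibble
#'   with a `gene_id` column, e.g. [overlap_and_classify()] output).
#' @param universe All gene ids eligible to be candidates (typically the
#'   genes tested for differential expression).
#' @param gene_sets Named list of gene-id vectors, or a tibble with
#'   `set_name` and `gene_id` columns (see [read_gmt()]).
#' @return A tibble per set: `set_name`, `overlap` (k), `set_size` (K,
#'   after intersection with the universe), `n_candidates` (n),
#'   `universe_size` (N), `p`, `padj`, `genes` (overlapping ids,
#'   semicolon-collapsed).
#' @export
ora_gene_sets <- function(candidates, universe, gene_sets) {
  if (is.data.frame(candidates)) candidates <- candidates$gene_id
  candidates <- unique(as.character(candidates))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort("empty universe.")
  if (length(candidates) == 0) abort("empty candidate list.")
  stray <- setdiff(candidates, universe)
  if (length(stray) > 0) {
    abort(sprintf("candidates outside the universe: %s",
                  paste(utils::head(stray, 5), collapse = ", ")))
  }
  if (is.data.frame(gene_sets)) {
    gene_sets <- split(gene_sets$gene_id, gene_sets$set_name)
  }
  n <- length(candidates)
  N <- length(universe)
  purrr::imap_dfr(gene_sets, function(genes, nm) {
    set_u <- intersect(unique(genes), universe)
    K <- length(set_u)
    hit <- intersect(candidates, set_u)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(set_name = nm, overlap = k, set_size = K,
                   n_candidates = n, universe_size = N, p = p,
                   genes = paste(sort(hit), collapse = ";"))
  }) %>%
    dplyr::mutate(padj = bh_adjust(.data$p), .after = "p")
}

#' Deterministic candidate ranking
#'
#' Total order over candidates: primary key a weighted combined
#' effect-size score `w_meth * |lfc_meth_corrected| + w_expr *
#' |lfc_expr|`; ties broken by the number of significant gene-set
#' memberships, then by user-supplied annotation flags (e.g. literature
#' or clinical-database relevance, which cannot be computed), and
#' finally by gene id so the order is reproducible under any input
#' permutation.
#'
#' @param candidates [overlap_and_classify()] output.
#' @param w_meth,w_expr Non-negative weights on the two absolute LFCs.
#' @param memberships Optional tibble (`gene_id`, `set_name`) of
#'   significant set memberships used as the secondary key; also stored
#'   in the output.
#' @param annotation_flags Optional tibble (`gene_id`, `flag` numeric)
#'   of manual relevance marks, the tertiary key.
#' @param top_k Optionally keep only the first `top_k` rows.
#' @return The candidate tibble with `score`, `n_sets`, `flag`, `rank`
#'   columns, sorted by rank.
#' @export
rank_candidates <- function(candidates, w_meth = 1, w_expr = 1,
                            memberships = NULL, annotation_flags = NULL,
                            top_k = NULL) {
  if (w_meth < 0 || w_expr < 0) abort("weights must be non-negative.")
  out <- candidates
  out$score <- w_meth * abs(out$lfc_meth_corrected) +
    w_expr * abs(out$lfc_expr)
  out$n_sets <- if (is.null(memberships)) 0L else {
    cnt <- memberships %>%
      dplyr::distinct(.data$gene_id, .data$set_name) %>%
      dplyr::count(.data$gene_id)
    tidyr::replace_na(cnt$n[match(out$gene_id, cnt$gene_id)], 0L)
  }
  out$flag <- if (is.null(annotation_flags)) 0 else {
    tidyr::replace_na(
      annotation_flags$flag[match(out$gene_id,
                                  annotation_flags$gene_id)], 0)
  }
  out <- out %>%
    dplyr::arrange(dplyr::desc(.data$score), dplyr::desc(.data$n_sets),
                   dplyr::desc(.data$flag), .data$gene_id) %>%
    dplyr::mutate(rank = dplyr::row_number())
  if (!is.null(top_k)) out <- dplyr::slice_head(out, n = top_k)
  out
}
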