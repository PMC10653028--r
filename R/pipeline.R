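#' Pipeline configuration
#'
#' All thresholds of the discovery cascade in one object.  Defaults are
#' the published pipeline's printed values: consensus and DE
#' significance at adjusted p < 0.05, DE retention at |log2FC| > 0.5,
#' confounding filter at |ΔLFC| >= 1, low-count filter at mean IP count
#' >= 10, direction threshold 1, over-representation at adjusted
#' p < 0.05, top 15 ranked candidates.
#'
#' @param alpha Consensus / DE adjusted-p threshold.
#' @param de_lfc DE retention threshold on `|lfc_shrunk|`.
#' @param confound_delta Confounding-filter threshold (log2).
#' @param min_count Low-count filter threshold on raw IP counts.
#' @param count_stat Aggregation for the count filter (`"mean"`,
#'   `"min"`, `"sum"`).
#' @param direction_delta Direction-call threshold (log2).
#' @param ora_alpha Over-representation adjusted-p threshold.
#' @param top_k Number of ranked candidates to keep (`NULL` = all).
#' @param w_meth,w_expr Ranking weights.
#' @param cdi_mode CDI formula variant for downstream validation
#'   calculators.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alpha = 0.05, de_lfc = 0.5,
                            confound_delta = 1, min_count = 10,
                            count_stat = "mean", direction_delta = 1,
                            ora_alpha = 0.05, top_k = 15,
                            w_meth = 1, w_expr = 1,
                            cdi_mode = "standard") {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full discovery pipeline
#'
#' Executes, on one set of inputs: differential expression on the input
#' libraries; the three differential-methylation tests on the paired
#' peak counts; the consensus-and-filter cascade; candidate overlap and
#' quadrant classification; optional gene-set over-representation; and
#' deterministic ranking.  The run is fully deterministic given the
#' inputs and configuration -- no stage draws random numbers.
#'
#' @param data A list (e.g. a [simulate_merip_counts()] result)
#'   providing `gene_input`, `peak_ip`, `peak_input`, `samples`,
#'   `peak_gene_map`.
#' @param gene_sets Optional gene sets for [ora_gene_sets()] (named list
#'   or `set_name`/`gene_id` tibble).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every stage table, the
#'   configuration (YAML) and the run summary (JSON) are written there.
#' @return A `merip_run` list: `de`, `dm_tests` (list of three),
#'   `dm`, `candidates`, `enrichment` (or `NULL`), `ranked`, `summary`
#'   (per-stage record counts), `config`.
#' @export
run_full_pipeline <- function(data, gene_sets = NULL,
                              config = pipeline_config(),
                              out_dir = NULL) {
  needed <- c("gene_input", "peak_ip", "peak_input", "samples",
              "peak_gene_map")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(sprintf("`data` is missing element(s): %s",
                  paste(missing, collapse = ", ")))
  }
  input_samples <- data$samples[data$samples$assay == "input", ]

  de <- run_diffexpr(data$gene_input, input_samples,
                     lfc_threshold = config$de_lfc, alpha = config$alpha)
  dm_tests <- purrr::map(
    stats::setNames(nm = c("wald_interaction", "ql_ftest", "ratio_lrt")),
    function(mth) run_diffmeth_test(data$peak_ip, data$peak_input,
                                    data$samples, method = mth))
  dm <- consensus_and_filter(
    dm_tests$wald_interaction, dm_tests$ql_ftest, dm_tests$ratio_lrt,
    de, data$peak_gene_map,
    alpha = config$alpha, delta = config$confound_delta,
    min_count = config$min_count, count_stat = config$count_stat,
    direction_delta = config$direction_delta)
  candidates <- overlap_and_classify(dm, de)
  enrichment <- NULL
  memberships <- NULL
  if (!is.null(gene_sets) && nrow(candidates) > 0) {
    enrichment <- ora_gene_sets(candidates, de$gene_id, gene_sets)
    sig_sets <- enrichment[!is.na(enrichment$padj) &
                             enrichment$padj < config$ora_alpha, ]
    if (nrow(sig_sets) > 0) {
      memberships <- sig_sets %>%
        dplyr::select("set_name", "genes") %>%
        tidyr::separate_rows("genes", sep = ";") %>%
        dplyr::filter(nzchar(.data$genes)) %>%
        dplyr::rename(gene_id = "genes")
    }
  }
  ranked <- rank_candidates(candidates, w_meth = config$w_meth,
                            w_expr = config$w_expr,
                            memberships = memberships,
                            top_k = config$top_k)
  cascade <- cascade_summary(dm)
  summary <- dplyr::bind_rows(
    tibble::tibble(stage = "genes_tested", n = nrow(de)),
    tibble::tibble(stage = "genes_retained_de", n = sum(de$retained)),
    tibble::tibble(stage = paste0("peaks_", cascade$stage),
                   n = cascade$n_peaks),
    tibble::tibble(stage = "candidate_genes", n = nrow(candidates)),
    tibble::tibble(stage = "ranked_candidates", n = nrow(ranked)))
  run <- structure(list(de = de, dm_tests = dm_tests, dm = dm,
                        candidates = candidates, enrichment = enrichment,
                        ranked = ranked, summary = summary,
                        config = config),
                   class = "merip_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# Persist a pipeline run: stage tables as TSV, config as YAML, summary
# as JSON -- the reproducibility contract that every output directory
# carries the exact configuration that produced it.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$de, file.path(out_dir, "diffexpr.tsv"))
  for (nm in names(run$dm_tests)) {
    readr::write_tsv(run$dm_tests[[nm]],
                     file.path(out_dir, paste0("diffmeth_", nm, ".tsv")))
  }
  readr::write_tsv(run$dm, file.path(out_dir, "diffmeth_consensus.tsv"))
  readr::write_tsv(cascade_summary(run$dm),
                   file.path(out_dir, "cascade.tsv"))
  readr::write_tsv(run$candidates, file.path(out_dir, "candidates.tsv"))
  if (!is.null(run$enrichment)) {
    readr::write_tsv(run$enrichment, file.path(out_dir, "enrichment.tsv"))
  }
  readr::write_tsv(run$ranked, file.path(out_dir, "ranked.tsv"))
  writeLines(yaml::as.yaml(unclass(run$config)),
             file.path(out_dir, "config.yaml"))
  jsonlite::write_json(
    stats::setNames(as.list(run$summary$n), run$summary$stage),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' @export
print.merip_run <- function(x, ...) {
  cat("MeRIP-seq discovery pipeline run\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-28s %6d\n", x$summary$stage[i], x$summary$n[i]))
  }
  invisible(x)
}
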