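#' Differential expression on input (RNA-seq) libraries
#'
#' Per-gene negative-binomial Wald test of the condition effect on the
#' input libraries: median-of-ratios normalization, trended dispersion
#' shrinkage, NB GLM fit, BH adjustment and ridge LFC shrinkage.  A gene
#' is `retained` when `|lfc_shrunk| > lfc_threshold` and
#' `padj < alpha` (defaults 0.5 and 0.05).
#'
#' @param gene_counts Gene count table (`feature_id` + sample columns),
#'   input-assay libraries only.
#' @param samples Sample sheet with `sample_id`, `condition`, `replicate`
#'   and optionally `assay` (all rows must then be `input`; passing IP
#'   libraries is an error -- differential expression is defined on the
#'   un-enriched libraries).
#' @param lfc_threshold,alpha Retention thresholds on `|lfc_shrunk|` and
#'   `padj`.
#' @param shrink_prior_scale Prior scale for [shrink_lfc()]; `NULL`
#'   estimates it from the data.
#' @return A tibble with one row per gene: `gene_id`, `baseMean`,
#'   `lfc_raw`, `lfc_shrunk`, `se`, `stat`, `p`, `padj`, `retained`.
#'   LFCs are log2.
#' @export
run_diffexpr <- function(gene_counts, samples, lfc_threshold = 0.5,
                         alpha = 0.05, shrink_prior_scale = NULL) {
  check_sample_sheet(samples, require_assay = FALSE)
  if ("assay" %in% names(samples) && any(samples$assay != "input")) {
    abort("run_diffexpr() accepts input libraries only; IP samples found.")
  }
  cond <- condition_factor(samples$condition)
  if (any(table(cond) < 2)) abort(">= 2 replicates per condition required.")
  m <- align_samples(counts_to_matrix(gene_counts), samples)
  sf <- size_factors_matrix(m)
  disp <- dispersions_matrix(m, cond, sf)
  X <- stats::model.matrix(~cond)
  colnames(X) <- c("intercept", "condition")
  off <- log(sf)
  res <- nb_wald_table(m, X, off, disp$phi_shrunk, contrast = c(0, 1))
  base_mean <- rowMeans(sweep(m, 2, sf, "/"))
  lfc_shrunk <- shrink_lfc(res$lfc, res$se, shrink_prior_scale)
  padj <- bh_adjust(res$p)
  tibble::tibble(
    gene_id = rownames(m), baseMean = base_mean,
    lfc_raw = res$lfc, lfc_shrunk = lfc_shrunk, se = res$se,
    stat = res$stat, p = res$p, padj = padj,
    retained = !is.na(padj) & abs(lfc_shrunk) > lfc_threshold & padj < alpha
  )
}

# Vectorized-over-features Wald testing helper: fits one NB GLM per row
# of m and tests `contrast`.
nb_wald_table <- function(m, X, off, phi, contrast) {
  n <- nrow(m)
  lfc <- se <- stat <- p <- rep(NA_real_, n)
  conv <- rep(NA, n)
  for (i in seq_len(n)) {
    fit <- fit_nb_glm(m[i, ], X, off, phi[i])
    conv[i] <- fit$converged
    if (!isTRUE(fit$converged)) next
    w <- wald_test(fit, contrast)
    lfc[i] <- w$estimate
    se[i] <- w$se
    stat[i] <- w$statistic
    p[i] <- w$p
  }
  list(lfc = lfc, se = se, stat = stat, p = p, converged = conv)
}

#' Differential methylation test on paired IP/input peak counts
#'
#' Fits, per peak, a joint NB GLM to the stacked IP and input counts with
#' mean \eqn{\exp(\mathrm{offset} + \alpha + a\,\mathrm{assay} +
#' c\,\mathrm{condition} + b\,\mathrm{assay}\times\mathrm{condition})}.
#' The interaction coefficient \eqn{b} is the change in IP-over-input
#' enrichment between conditions -- the methylation change, already free
#' of the expression change \eqn{c} that confounds naive IP-only
#' comparisons.  Size factors are estimated separately within the IP and
#' the input libraries.
#'
#' Three inference variants on \eqn{b} are provided and are combined by
#' [consensus_and_filter()]:
#' \describe{
#'   \item{`wald_interaction`}{Wald z from the Fisher information.}
#'   \item{`ql_ftest`}{Quasi-likelihood F: the Wald chi-square scaled by
#'     a moderated Pearson overdispersion, referred to an F
#'     distribution.}
#'   \item{`ratio_lrt`}{Likelihood ratio of the full model against the
#'     no-interaction reduction, referred to chi-square(1).}
#' }
#'
#' @param peak_ip,peak_input Peak count tables over the same peak ids;
#'   columns are the IP and input sample ids respectively.
#' @param samples Sample sheet covering both assays with >= 2 replicates
#'   per (condition, assay).
#' @param method One of `"wald_interaction"`, `"ql_ftest"`,
#'   `"ratio_lrt"`.
#' @param ql_prior_df Prior degrees of freedom moderating the per-peak
#'   quasi-dispersion toward the across-peak mean (`ql_ftest` only).
#' @return A tibble per peak: `peak_id`, `method`, `lfc_interaction`
#'   (log2 methylation change), `lfc_peak_ip` (log2 condition change in
#'   the IP libraries), `lfc_peak_input`, `se`, `stat`, `p`, `padj`,
#'   `mean_ip_count`, `min_ip_count`, `sum_ip_count`, `converged`.
#' @export
run_diffmeth_test <- function(peak_ip, peak_input, samples,
                              method = c("wald_interaction", "ql_ftest",
                                         "ratio_lrt"),
                              ql_prior_df = 10) {
  method <- match.arg(method)
  check_sample_sheet(samples)
  ip_samples <- samples[samples$assay == "IP", , drop = FALSE]
  in_samples <- samples[samples$assay == "input", , drop = FALSE]
  if (nrow(ip_samples) == 0 || nrow(in_samples) == 0) {
    abort("paired design requires both IP and input samples.")
  }
  cond_all <- condition_factor(samples$condition)
  if (any(table(samples$condition, samples$assay) < 2)) {
    abort(">= 2 replicates per (condition, assay) required.")
  }
  m_ip <- counts_to_matrix(peak_ip)
  m_in <- counts_to_matrix(peak_input)
  only_ip <- setdiff(rownames(m_ip), rownames(m_in))
  only_in <- setdiff(rownames(m_in), rownames(m_ip))
  if (length(only_ip) || length(only_in)) {
    abort(sprintf(
      "peak ids must match between IP and input tables; unmatched: %s",
      paste(utils::head(c(only_ip, only_in), 10), collapse = ", ")))
  }
  m_in <- m_in[rownames(m_ip), , drop = FALSE]
  m_ip <- align_samples(m_ip, ip_samples)
  m_in <- align_samples(m_in, in_samples)

  # Assay-specific size factors: IP enrichment changes count composition.
  sf_ip <- size_factors_matrix(m_ip)
  sf_in <- size_factors_matrix(m_in)
  m <- cbind(m_ip, m_in)
  sf <- c(sf_ip, sf_in)
  stacked <- rbind(ip_samples, in_samples)
  cond <- condition_factor(stacked$condition)
  is_ip <- as.numeric(stacked$assay == "IP")
  cells <- interaction(cond, stacked$assay, drop = TRUE)
  disp <- dispersions_matrix(m, cells, sf)
  phi <- disp$phi_shrunk

  cond_num <- as.numeric(cond) - 1     # 0 = reference condition (A)
  X <- cbind(intercept = 1, assayIP = is_ip, condition = cond_num,
             interaction = is_ip * cond_num)
  X_red <- X[, 1:3, drop = FALSE]
  off <- log(sf)
  n_pk <- nrow(m)
  b <- c_main <- se <- stat <- p <- s2 <- rep(NA_real_, n_pk)
  conv <- rep(NA, n_pk)
  df_res <- nrow(X) - ncol(X)
  ll_full <- ll_red <- rep(NA_real_, n_pk)
  for (i in seq_len(n_pk)) {
    fit <- fit_nb_glm(m[i, ], X, off, phi[i])
    conv[i] <- fit$converged
    if (!isTRUE(fit$converged)) next
    b[i] <- fit$coefficients[["interaction"]]
    c_main[i] <- fit$coefficients[["condition"]]
    v <- fit$vcov["interaction", "interaction"]
    if (is.finite(v) && v > 0) se[i] <- sqrt(v)
    if (method == "ql_ftest") {
      pr <- (m[i, ] - fit$fitted) /
        sqrt(fit$fitted * (1 + phi[i] * fit$fitted))
      s2[i] <- sum(pr^2) / df_res
    }
    if (method == "ratio_lrt") {
      ll_full[i] <- fit$loglik
      red <- fit_nb_glm(m[i, ], X_red, off, phi[i])
      if (isTRUE(red$converged)) ll_red[i] <- red$loglik
    }
  }
  z <- b / se
  if (method == "wald_interaction") {
    stat <- z
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  } else if (method == "ql_ftest") {
    s2_prior <- mean(s2, na.rm = TRUE)
    s2_mod <- (df_res * s2 + ql_prior_df * s2_prior) /
      (df_res + ql_prior_df)
    stat <- z^2 / pmax(s2_mod, 1e-8)
    p <- stats::pf(stat, 1, df_res + ql_prior_df, lower.tail = FALSE)
  } else {
    stat <- 2 * (ll_full - ll_red)
    stat <- pmax(stat, 0)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  tibble::tibble(
    peak_id = rownames(m), method = method,
    lfc_interaction = b / LOG2,
    lfc_peak_ip = (c_main + b) / LOG2,
    lfc_peak_input = c_main / LOG2,
    se = se / LOG2, stat = stat, p = p, padj = bh_adjust(p),
    mean_ip_count = rowMeans(m_ip),
    min_ip_count = apply(m_ip, 1, min),
    sum_ip_count = rowSums(m_ip),
    converged = conv
  )
}

#' Three-test consensus and the filtering cascade
#'
#' Combines the three differential-methylation tests and applies, in
#' order: (1) the consensus rule -- significant at `padj < alpha` in all
#' three tests; (2) the expression-confounding filter
#' `|lfc_peak_ip - lfc_gene_input| >= delta`; (3) the low-count filter
#' on raw IP counts; then classifies surviving peaks as hypermethylated
#' in one condition or the other by the sign of the corrected
#' methylation LFC.  The stage-by-stage peak counts (the filtering
#' cascade) are attached as `attr(result, "cascade")` and available via
#' [cascade_summary()].
#'
#' @param wald,ql,lrt Result tibbles of [run_diffmeth_test()] for the
#'   three methods (any order; the `method` column is checked).
#' @param diffexpr [run_diffexpr()] result, supplying the matched gene
#'   input LFC.
#' @param peak_gene_map Tibble with `peak_id`, `gene_id`.  Peaks missing
#'   from the map (intergenic) are kept, corrected against a gene LFC of
#'   0, and flagged `unmapped`.
#' @param alpha Consensus significance threshold on each test's `padj`.
#' @param delta Confounding-filter threshold on
#'   `|lfc_peak_ip - lfc_gene_input|` (log2).
#' @param min_count Low-count threshold on the raw IP count aggregate.
#' @param count_stat Aggregation for the count filter: `"mean"` (default),
#'   `"min"` or `"sum"` of raw IP counts across samples.
#' @param direction_delta Threshold on `|lfc_meth_corrected|` for the
#'   direction call; defaults to `delta` so the cascade's final count
#'   equals the sum of the two direction classes.
#' @param use_shrunk_de Use the shrunk gene LFC for the correction
#'   instead of the raw one (default `FALSE`: raw-vs-raw keeps the two
#'   LFCs on the same estimation footing).
#' @return A tibble with one row per peak: `peak_id`, `gene_id`,
#'   `lfc_peak_ip`, `lfc_gene_input`, `lfc_meth_corrected`, per-test
#'   `p`/`padj` columns, `mean_ip_count`, `consensus`,
#'   `passed_confound_filter`, `passed_count_filter`, `direction`
#'   (`hyper_condB`, `hyper_condA` or `none`), `unmapped`.
#' @export
consensus_and_filter <- function(wald, ql, lrt, diffexpr, peak_gene_map,
                                 alpha = 0.05, delta = 1, min_count = 10,
                                 count_stat = c("mean", "min", "sum"),
                                 direction_delta = delta,
                                 use_shrunk_de = FALSE) {
  count_stat <- match.arg(count_stat)
  tabs <- list(wald = wald, ql = ql, lrt = lrt)
  methods <- vapply(tabs, function(t) t$method[1], character(1))
  expected <- c("wald_interaction", "ql_ftest", "ratio_lrt")
  reorder <- match(expected, methods)
  if (any(is.na(reorder))) {
    abort("need one result table per method: wald_interaction, ql_ftest, ratio_lrt.")
  }
  tabs <- tabs[reorder]
  ids <- tabs[[1]]$peak_id
  if (!all(vapply(tabs, function(t) identical(t$peak_id, ids), logical(1)))) {
    abort("peak ids must be identical (same order) across the three tables.")
  }
  de_lfc_col <- if (use_shrunk_de) "lfc_shrunk" else "lfc_raw"
  map <- peak_gene_map[match(ids, peak_gene_map$peak_id), ]
  gene_id <- map$gene_id
  de_lfc <- diffexpr[[de_lfc_col]][match(gene_id, diffexpr$gene_id)]
  unmapped <- is.na(gene_id) | is.na(de_lfc)
  de_lfc[unmapped] <- 0

  count_col <- paste0(count_stat, "_ip_count")
  res <- tibble::tibble(
    peak_id = ids,
    gene_id = gene_id,
    lfc_peak_ip = tabs[[1]]$lfc_peak_ip,
    lfc_gene_input = de_lfc,
    lfc_meth_corrected = tabs[[1]]$lfc_peak_ip - de_lfc,
    lfc_interaction = tabs[[1]]$lfc_interaction,
    p_wald = tabs[[1]]$p, padj_wald = tabs[[1]]$padj,
    p_ql = tabs[[2]]$p, padj_ql = tabs[[2]]$padj,
    p_lrt = tabs[[3]]$p, padj_lrt = tabs[[3]]$padj,
    mean_ip_count = tabs[[1]][[count_col]],
    unmapped = unmapped
  )
  sig <- function(x) !is.na(x) & x < alpha
  res$consensus <- sig(res$padj_wald) & sig(res$padj_ql) & sig(res$padj_lrt)
  res$passed_confound_filter <- res$consensus &
    abs(res$lfc_meth_corrected) >= delta
  res$passed_count_filter <- res$passed_confound_filter &
    res$mean_ip_count >= min_count
  res$direction <- ifelse(
    res$passed_count_filter & res$lfc_meth_corrected >= direction_delta,
    "hyper_condB",
    ifelse(res$passed_count_filter &
             res$lfc_meth_corrected <= -direction_delta,
           "hyper_condA", "none"))
  cascade <- tibble::tibble(
    stage = c("tested", "consensus", "after_confound_filter",
              "after_count_filter", "hyper_condA", "hyper_condB"),
    n_peaks = c(nrow(res), sum(res$consensus),
                sum(res$passed_confound_filter),
                sum(res$passed_count_filter),
                sum(res$direction == "hyper_condA"),
                sum(res$direction == "hyper_condB"))
  )
  attr(res, "cascade") <- cascade
  res
}

#' Filtering-cascade summary of a consensus result
#'
#' @param dm A [consensus_and_filter()] result.
#' @return Tibble of stage names and peak counts, non-increasing through
#'   the filter stages.
#' @export
cascade_summary <- function(dm) {
  cascade <- attr(dm, "cascade")
  if (is.null(cascade)) abort("no cascade attribute; not a consensus result?")
  cascade
}

#' Principal-component QC of peak IP counts
#'
#' PCA of `log2(normalized count + 1)` with samples as observations,
#' plus a condition-separation score (mean silhouette width on the first
#' two PCs, conditions as clusters).
#'
#' @param counts Peak IP count table.
#' @param samples Sample sheet (>= 3 samples).
#' @param n_pcs Number of PCs to keep; reduced with a warning when it
#'   exceeds what the data support.
#' @return A `merip_pca` object: `$scores` (per-sample coordinates),
#'   `$variance` (per-PC variance fractions), `$silhouette`,
#'   `$degenerate`.  `tidy()` returns the scores, `glance()` the
#'   one-row summary; `autoplot()` draws the PC1--PC2 plot.
#' @export
pca_qc <- function(counts, samples, n_pcs = 10) {
  check_sample_sheet(samples, require_assay = FALSE)
  m <- align_samples(counts_to_matrix(counts), samples)
  if (ncol(m) < 3) abort("PCA QC needs >= 3 samples.")
  sf <- size_factors_matrix(m)
  lg <- t(log2(sweep(m, 2, sf, "/") + 1))
  max_pcs <- min(nrow(lg) - 1, ncol(lg))
  if (n_pcs > max_pcs) {
    warn(sprintf("reducing n_pcs from %d to %d (limited by data).",
                 n_pcs, max_pcs))
    n_pcs <- max_pcs
  }
  total_var <- sum(apply(lg, 2, stats::var))
  if (total_var < 1e-12) {
    scores <- matrix(0, nrow(lg), n_pcs,
                     dimnames = list(NULL, paste0("PC", seq_len(n_pcs))))
    out <- list(
      scores = dplyr::bind_cols(
        tibble::as_tibble(samples[c("sample_id", "condition")]),
        tibble::as_tibble(scores)),
      variance = tibble::tibble(pc = paste0("PC", seq_len(n_pcs)),
                                var_fraction = rep(0, n_pcs)),
      silhouette = NA_real_, degenerate = TRUE)
    return(structure(out, class = "merip_pca"))
  }
  pr <- stats::prcomp(lg, center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pr$x))
  var_frac <- pr$sdev^2 / sum(pr$sdev^2)
  scores <- pr$x[, seq_len(k), drop = FALSE]
  cond <- condition_factor(samples$condition)
  sil <- NA_real_
  if (nlevels(cond) == 2 && all(table(cond) >= 1)) {
    xy <- pr$x[, seq_len(min(2, ncol(pr$x))), drop = FALSE]
    sw <- cluster::silhouette(as.integer(cond), stats::dist(xy))
    if (!is.null(dim(sw))) sil <- mean(sw[, "sil_width"])
  }
  out <- list(
    scores = dplyr::bind_cols(
      tibble::as_tibble(samples[intersect(c("sample_id", "condition", "assay"),
                                          names(samples))]),
      tibble::as_tibble(scores)),
    variance = tibble::tibble(pc = colnames(pr$x)[seq_len(k)],
                              var_fraction = var_frac[seq_len(k)]),
    silhouette = sil, degenerate = FALSE)
  structure(out, class = "merip_pca")
}

#' @export
print.merip_pca <- function(x, ...) {
  cat("PCA QC:",
      if (x$degenerate) "degenerate (zero variance)\n" else
        sprintf("PC1 %.1f%%, PC2 %.1f%%; condition silhouette %.2f\n",
                100 * x$variance$var_fraction[1],
                100 * ifelse(nrow(x$variance) > 1,
                             x$variance$var_fraction[2], 0),
                x$silhouette))
  invisible(x)
}

#' @rdname pca_qc
#' @param x A `merip_pca` object.
#' @param ... Unused.
#' @export
tidy.merip_pca <- function(x, ...) x$scores

#' @rdname pca_qc
#' @export
glance.merip_pca <- function(x, ...) {
  tibble::tibble(
    pc1_var_fraction = x$variance$var_fraction[1],
    pc2_var_fraction = if (nrow(x$variance) > 1)
      x$variance$var_fraction[2] else NA_real_,
    silhouette = x$silhouette,
    degenerate = x$degenerate)
}
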