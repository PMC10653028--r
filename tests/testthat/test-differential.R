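# Differential expression and the three-test differential-methylation
# machinery, checked against the planted truth of the synthetic
# generator.

sim_de <- simulate_merip_counts(
  sim_config(n_genes = 600, peaks_per_gene = 1, frac_de = 0.1,
             frac_dm = 0), seed = 101)
input_samples <- sim_de$samples[sim_de$samples$assay == "input", ]

test_that("diffexpr recovers planted expression changes with controlled FDR", {
  de <- run_diffexpr(sim_de$gene_input, input_samples)
  truth <- sim_de$truth_genes
  hit <- de$retained[match(truth$gene_id, de$gene_id)]
  sens <- sum(hit & truth$is_de) / sum(truth$is_de)
  fdr <- if (sum(hit) > 0) sum(hit & !truth$is_de) / sum(hit) else 0
  expect_gte(sens, 0.9)
  expect_lte(fdr, 0.10)
})

test_that("diffexpr retains nothing under the null", {
  cfg <- sim_config(n_genes = 500, peaks_per_gene = 1, frac_de = 0,
                    frac_dm = 0)
  n_retained <- vapply(1:10, function(s) {
    sim0 <- simulate_merip_counts(cfg, seed = s)
    de0 <- run_diffexpr(sim0$gene_input,
                        sim0$samples[sim0$samples$assay == "input", ])
    sum(de0$retained)
  }, double(1))
  # an occasional false retention is expected under BH; emptiness must
  # hold in the overwhelming majority of replicates
  expect_gte(mean(n_retained == 0), 0.9)
})

test_that("diffexpr threshold logic and input-only contract", {
  de <- run_diffexpr(sim_de$gene_input, input_samples)
  # the retained flag is exactly the conjunction of the two thresholds
  expect_equal(de$retained,
               !is.na(de$padj) & abs(de$lfc_shrunk) > 0.5 & de$padj < 0.05)
  expect_error(run_diffexpr(sim_de$gene_input, sim_de$samples),
               "input libraries only")
})

sim_mix <- simulate_merip_counts(
  sim_config(n_genes = 400, peaks_per_gene = 2, frac_de = 0.2,
             frac_dm = 0.15, lfc_dm = 2), seed = 202)

dm_tabs <- lapply(
  c("wald_interaction", "ql_ftest", "ratio_lrt"),
  function(m) run_diffmeth_test(sim_mix$peak_ip, sim_mix$peak_input,
                                sim_mix$samples, method = m))
names(dm_tabs) <- c("wald", "ql", "lrt")

test_that("interaction LFC recovers planted methylation effects", {
  # planted methylation changes without any expression changes
  sim_b <- simulate_merip_counts(
    sim_config(n_genes = 600, peaks_per_gene = 1, frac_de = 0,
               frac_dm = 0.3, lfc_dm = 2), seed = 210)
  tab <- run_diffmeth_test(sim_b$peak_ip, sim_b$peak_input,
                           sim_b$samples, "wald_interaction")
  joined <- dplyr::left_join(tab, sim_b$truth_peaks, by = "peak_id")
  up <- joined$beta == 2
  dn <- joined$beta == -2
  expect_lt(abs(median(joined$lfc_interaction[up], na.rm = TRUE) - 2), 0.3)
  expect_lt(abs(median(joined$lfc_interaction[dn], na.rm = TRUE) + 2), 0.3)
})

test_that("confounding: naive IP LFC tracks expression, interaction does not", {
  sim_conf <- simulate_merip_counts(
    sim_config(n_genes = 400, peaks_per_gene = 2, frac_de = 0.25,
               frac_dm = 0), seed = 303)
  tab <- run_diffmeth_test(sim_conf$peak_ip, sim_conf$peak_input,
                           sim_conf$samples, "wald_interaction")
  truth_g <- sim_conf$truth_genes
  joined <- dplyr::left_join(tab, sim_conf$truth_peaks, by = "peak_id") %>%
    dplyr::left_join(truth_g, by = "gene_id")
  de_up <- joined$delta == 2
  # naive IP-only comparison inherits the planted expression change ...
  expect_lt(abs(median(joined$lfc_peak_ip[de_up], na.rm = TRUE) - 2), 0.3)
  # ... while the interaction self-corrects to ~0
  expect_lt(abs(median(joined$lfc_interaction[de_up], na.rm = TRUE)), 0.3)
})

test_that("each test is calibrated on null peaks", {
  sim0 <- simulate_merip_counts(
    sim_config(n_genes = 400, peaks_per_gene = 2, frac_de = 0.2,
               frac_dm = 0), seed = 404)
  for (m in c("wald_interaction", "ql_ftest", "ratio_lrt")) {
    tab <- run_diffmeth_test(sim0$peak_ip, sim0$peak_input,
                             sim0$samples, method = m)
    expect_lte(mean(tab$p < 0.05, na.rm = TRUE), 0.08)
  }
})

test_that("diffmeth input contracts: pairing and matching peak ids", {
  expect_error(
    run_diffmeth_test(sim_mix$peak_ip, sim_mix$peak_input,
                      sim_mix$samples[sim_mix$samples$assay == "IP", ]),
    "both IP and input")
  expect_error(
    run_diffmeth_test(sim_mix$peak_ip[-1, ], sim_mix$peak_input,
                      sim_mix$samples),
    "unmatched")
})

test_that("consensus rule, filters and direction classification", {
  de <- run_diffexpr(sim_mix$gene_input,
                     sim_mix$samples[sim_mix$samples$assay == "input", ])
  dm <- consensus_and_filter(dm_tabs$wald, dm_tabs$ql, dm_tabs$lrt, de,
                             sim_mix$peak_gene_map)
  # consensus requires all three padj < alpha
  expect_equal(dm$consensus,
               dm$padj_wald < 0.05 & dm$padj_ql < 0.05 &
                 dm$padj_lrt < 0.05)
  # consensus set within each single-test significant set
  expect_true(all(dm$padj_wald[dm$consensus] < 0.05))
  expect_true(all(dm$padj_ql[dm$consensus] < 0.05))
  expect_true(all(dm$padj_lrt[dm$consensus] < 0.05))
  # cascade monotone, and final count splits into the two directions
  casc <- cascade_summary(dm)
  n <- setNames(casc$n_peaks, casc$stage)
  expect_true(n["consensus"] >= n["after_confound_filter"])
  expect_true(n["after_confound_filter"] >= n["after_count_filter"])
  expect_equal(unname(n["after_count_filter"]),
               unname(n["hyper_condA"] + n["hyper_condB"]))
  # direction implies consensus and both filters
  dir_peaks <- dm[dm$direction != "none", ]
  expect_true(all(dir_peaks$consensus & dir_peaks$passed_confound_filter &
                    dir_peaks$passed_count_filter))
})

test_that("confound and count filter arithmetic on constructed records", {
  mk <- function(lfc_ip, method, p = 0.001, mean_ip = 50) {
    tibble::tibble(peak_id = c("p1", "p2"), method = method,
                   lfc_interaction = lfc_ip, lfc_peak_ip = lfc_ip,
                   lfc_peak_input = 0, se = 0.1, stat = 5, p = p,
                   padj = p, mean_ip_count = mean_ip,
                   min_ip_count = mean_ip, sum_ip_count = mean_ip * 10,
                   converged = TRUE)
  }
  de <- tibble::tibble(gene_id = c("gA", "gB"), baseMean = 100,
                       lfc_raw = c(0.5, 0.8), lfc_shrunk = c(0.5, 0.8),
                       se = 0.1, stat = 1, p = 0.5, padj = 0.5,
                       retained = FALSE)
  map <- tibble::tibble(peak_id = c("p1", "p2"), gene_id = c("gA", "gB"))
  dm <- consensus_and_filter(
    mk(c(2.0, 1.2), "wald_interaction"), mk(c(2.0, 1.2), "ql_ftest"),
    mk(c(2.0, 1.2), "ratio_lrt"), de, map)
  # |2.0 - 0.5| = 1.5 passes; |1.2 - 0.8| = 0.4 removed
  expect_equal(dm$passed_confound_filter, c(TRUE, FALSE))
  expect_equal(dm$direction, c("hyper_condB", "none"))

  # a padj triple failing one test is not consensus
  dm2 <- consensus_and_filter(
    mk(c(2, 2), "wald_interaction", p = 0.01),
    mk(c(2, 2), "ql_ftest", p = 0.03),
    mk(c(2, 2), "ratio_lrt", p = 0.20), de, map)
  expect_false(any(dm2$consensus))

  # unmapped peak corrected against zero and flagged
  map3 <- tibble::tibble(peak_id = "p1", gene_id = "gA")
  dm3 <- consensus_and_filter(
    mk(c(2, 2), "wald_interaction"), mk(c(2, 2), "ql_ftest"),
    mk(c(2, 2), "ratio_lrt"), de, map3)
  expect_true(dm3$unmapped[dm3$peak_id == "p2"])
  expect_equal(dm3$lfc_gene_input[dm3$peak_id == "p2"], 0)
})

test_that("cascade keeps true DM peaks and discards expression-only peaks", {
  sim4 <- simulate_merip_counts(
    sim_config(n_genes = 500, peaks_per_gene = 2, frac_de = 0.25,
               frac_dm = 0.15, lfc_dm = 2), seed = 505)
  de <- run_diffexpr(sim4$gene_input,
                     sim4$samples[sim4$samples$assay == "input", ])
  tabs <- lapply(c("wald_interaction", "ql_ftest", "ratio_lrt"),
                 function(m) run_diffmeth_test(sim4$peak_ip,
                                               sim4$peak_input,
                                               sim4$samples, m))
  dm <- consensus_and_filter(tabs[[1]], tabs[[2]], tabs[[3]], de,
                             sim4$peak_gene_map)
  joined <- dplyr::left_join(dm, sim4$truth_peaks, by = "peak_id")
  surv <- joined[joined$direction != "none", ]
  expect_gte(mean(surv$is_dm), 0.9)
  de_only <- joined[joined$class == "de_only", ]
  expect_lte(mean(de_only$direction != "none"), 0.05)
})

test_that("PCA QC separates conditions and handles degenerate input", {
  m <- cbind(matrix(rep(c(10, 50, 90), 3), ncol = 3),
             matrix(rep(c(90, 50, 10), 3), ncol = 3))
  samples <- make_input_samples(3)
  p <- pca_qc(make_counts(m), samples, n_pcs = 2)
  expect_gt(p$variance$var_fraction[1], 0.9)
  expect_gt(p$silhouette, 0.9)

  sim_pc <- simulate_merip_counts(
    sim_config(n_genes = 300, peaks_per_gene = 1, frac_de = 0.3,
               frac_dm = 0), seed = 606)
  ip_samples <- sim_pc$samples[sim_pc$samples$assay == "input", ]
  expect_warning(p2 <- pca_qc(sim_pc$gene_input, ip_samples), "n_pcs")
  expect_gt(p2$silhouette, 0.5)
  expect_true(all(diff(p2$variance$var_fraction) <= 1e-12))
  expect_lte(sum(p2$variance$var_fraction), 1 + 1e-8)

  const <- make_counts(matrix(5, nrow = 4, ncol = 6))
  p3 <- pca_qc(const, samples, n_pcs = 2)
  expect_true(p3$degenerate)
  expect_true(all(p3$variance$var_fraction == 0))
})
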