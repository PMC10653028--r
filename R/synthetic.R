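#' Configuration for the synthetic MeRIP-seq generator
#'
#' Collects the generative parameters of [simulate_merip_counts()] in
#' one validated object.  Defaults emulate the study design the package
#' targets: two conditions with five IP and five input replicates each,
#' ~100-count log-normal baseline expression, global NB dispersion 0.2,
#' 10% of genes differentially expressed at |log2FC| = 2, and 10% of
#' peaks differentially methylated at |log2FC| drawn from
#' \{1, 1.5, 2\} so planted effects straddle the |ΔLFC| >= 1
#' confounding filter.
#'
#' @param n_genes Number of genes.
#' @param peaks_per_gene Peaks per gene (fixed integer).
#' @param n_reps Replicates per (condition, assay).
#' @param baseline_meanlog,baseline_sdlog Log-normal law of the per-gene
#'   baseline expression rate `q_g`.
#' @param phi Global marginal NB dispersion (`Var = mu + phi mu^2`).
#' @param phi_technical Technical (assay-level) share of `phi`.  IP,
#'   input and gene libraries of one replicate measure the same RNA
#'   pool, so the biological component `phi - phi_technical` is drawn
#'   once per (gene, replicate) and shared across the three count
#'   matrices; only `phi_technical` is independent between assays.
#'   The marginal dispersion of every matrix stays ~`phi`.  Set
#'   `phi_technical = phi` for fully independent draws.
#' @param rho_log2_range Range of `log2(rho_p)`, the baseline
#'   IP-over-input enrichment of each peak.
#' @param frac_de,lfc_de Fraction of genes with a planted expression
#'   effect and its magnitude `|delta_g|` (log2; sign random).
#' @param frac_dm,lfc_dm Fraction of peaks with a planted methylation
#'   effect and the magnitudes `|beta_p|` is drawn from (log2).
#' @param peak_len_ratio Peak-to-gene length ratio scaling peak-level
#'   input counts off the host-gene rate.
#' @param libsize_sdlog Log-normal spread of the true per-sample
#'   library-size factors `s_j`.
#' @param conditions Names of the two conditions (reference first).
#' @param truth_seed Seed of the ground-truth draw (baselines, effect
#'   assignments, size factors).  Part of the configuration so that the
#'   planted truth is a property of the study design: re-simulating with
#'   a different noise `seed` changes the counts but not the truth.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000, peaks_per_gene = 2, n_reps = 5,
                       baseline_meanlog = log(100), baseline_sdlog = 1,
                       phi = 0.2, phi_technical = 0.05,
                       rho_log2_range = c(1, 3),
                       frac_de = 0.1, lfc_de = 2,
                       frac_dm = 0.1, lfc_dm = c(1, 1.5, 2),
                       peak_len_ratio = 0.2, libsize_sdlog = 0.1,
                       conditions = c("A", "B"), truth_seed = 1003) {
  stopifnot(n_genes >= 1, peaks_per_gene >= 1, n_reps >= 2,
            phi >= 0, phi_technical >= 0,
            frac_de >= 0, frac_de <= 1,
            frac_dm >= 0, frac_dm <= 1,
            all(is.finite(c(lfc_de, lfc_dm))),
            peak_len_ratio > 0, length(conditions) == 2)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate MeRIP-seq count matrices with planted ground truth
#'
#' Generates paired gene-input, peak-IP and peak-input count tables for
#' a two-condition design with known per-gene expression effects
#' `delta_g` and per-peak methylation effects `beta_p`:
#' \deqn{y_{gj} \sim NB(s_j q_g 2^{\delta_g x_j},\ \phi)}
#' \deqn{k_{pj} \sim NB(s_j q_{g(p)} L 2^{\delta_g x_j} \rho_p
#'   2^{\beta_p x_j},\ \phi)}
#' with `x_j` the condition indicator and `L` the peak/gene length
#' ratio.  Peak input counts follow the host-gene rate without `beta`,
#' so methylation changes are invisible in the input -- exactly the
#' structure that makes naive IP-only comparisons conflate expression
#' and methylation, and that the interaction model corrects.
#'
#' Each gene/peak falls into one of four planted classes (`null`,
#' `de_only`, `dm_only`, `de_dm`), recorded in the truth tables.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; mandatory, the same seed reproduces the
#'   output byte for byte.
#' @return A list of class `merip_sim`: `gene_input`, `peak_ip`,
#'   `peak_input` (count tibbles), `samples` (sample sheet covering both
#'   assays), `peak_gene_map`, `truth_genes` (`gene_id`, `q`, `delta`,
#'   `is_de`), `truth_peaks` (`peak_id`, `gene_id`, `rho`, `beta`,
#'   `is_dm`, `class`).
#' @export
simulate_merip_counts <- function(config = sim_config(), seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  cf <- config
  n_g <- cf$n_genes
  n_p <- n_g * cf$peaks_per_gene

  # Ground truth comes from the config-owned seed so that different
  # noise seeds re-draw the counts around the same planted truth.
  set.seed(cf$truth_seed)
  q <- stats::rlnorm(n_g, cf$baseline_meanlog, cf$baseline_sdlog)
  is_de <- stats::runif(n_g) < cf$frac_de
  delta <- ifelse(is_de, sample(c(-1, 1), n_g, replace = TRUE) * cf$lfc_de, 0)

  gene_of_peak <- rep(seq_len(n_g), each = cf$peaks_per_gene)
  rho <- 2^stats::runif(n_p, cf$rho_log2_range[1], cf$rho_log2_range[2])
  is_dm <- stats::runif(n_p) < cf$frac_dm
  beta <- ifelse(is_dm,
                 sample(c(-1, 1), n_p, replace = TRUE) *
                   sample(rep(cf$lfc_dm, length.out = n_p)),
                 0)

  n_per <- cf$n_reps
  samples <- tidyr::expand_grid(
    condition = cf$conditions, assay = c("IP", "input"),
    replicate = seq_len(n_per)) %>%
    dplyr::mutate(sample_id = paste(.data$condition, .data$assay,
                                    .data$replicate, sep = "_")) %>%
    dplyr::select("sample_id", "condition", "assay", "replicate")
  s_j <- stats::setNames(
    stats::rlnorm(nrow(samples), 0, cf$libsize_sdlog), samples$sample_id)

  set.seed(seed)                       # noise stream for the count draws
  x_j <- as.numeric(samples$condition == cf$conditions[2])

  # Dispersion decomposition: the biological component is a mean-1 gamma
  # per-(gene, condition, replicate) factor shared by the gene input,
  # peak input and peak IP measurements of that replicate's RNA pool;
  # the technical component is independent NB noise per assay.  A gamma
  # factor keeps every matrix's marginal law (gamma-Poisson) at the
  # stated NB dispersion ~phi.
  phi_tech <- min(cf$phi_technical, cf$phi)
  phi_bio <- max(0, (cf$phi - phi_tech) / (1 + phi_tech))
  rep_key <- paste(samples$condition, samples$replicate)  # pairs IP/input
  rep_levels <- unique(rep_key)
  u <- if (phi_bio > 0) {
    matrix(stats::rgamma(n_g * length(rep_levels), shape = 1 / phi_bio,
                         rate = 1 / phi_bio),
           nrow = n_g, dimnames = list(NULL, rep_levels))
  } else {
    matrix(1, nrow = n_g, dimnames = list(NULL, rep_levels))
  }
  bio <- u[, rep_key, drop = FALSE]        # genes x samples multiplier
  colnames(bio) <- samples$sample_id
  draw <- function(mu_mat, gene_idx) {
    mu_mat <- mu_mat * bio[gene_idx, colnames(mu_mat), drop = FALSE]
    v <- if (phi_tech > 0) {
      stats::rnbinom(length(mu_mat), size = 1 / phi_tech, mu = mu_mat)
    } else {
      stats::rpois(length(mu_mat), mu_mat)
    }
    matrix(v, nrow = nrow(mu_mat), dimnames = dimnames(mu_mat))
  }

  gene_ids <- sprintf("gene_%04d", seq_len(n_g))
  peak_ids <- sprintf("peak_%05d", seq_len(n_p))
  input_idx <- samples$assay == "input"
  ip_idx <- samples$assay == "IP"

  mu_gene <- outer(q, s_j[input_idx]) *
    2^outer(delta, x_j[input_idx])
  dimnames(mu_gene) <- list(gene_ids, samples$sample_id[input_idx])
  gene_input <- draw(mu_gene, seq_len(n_g))

  base_peak <- q[gene_of_peak] * cf$peak_len_ratio
  mu_peak_in <- outer(base_peak, s_j[input_idx]) *
    2^outer(delta[gene_of_peak], x_j[input_idx])
  dimnames(mu_peak_in) <- list(peak_ids, samples$sample_id[input_idx])
  peak_input <- draw(mu_peak_in, gene_of_peak)

  mu_peak_ip <- outer(base_peak * rho, s_j[ip_idx]) *
    2^outer(delta[gene_of_peak] + beta, x_j[ip_idx])
  dimnames(mu_peak_ip) <- list(peak_ids, samples$sample_id[ip_idx])
  peak_ip <- draw(mu_peak_ip, gene_of_peak)

  cls <- dplyr::case_when(
    is_de[gene_of_peak] & is_dm ~ "de_dm",
    is_de[gene_of_peak] ~ "de_only",
    is_dm ~ "dm_only",
    TRUE ~ "null")
  structure(list(
    gene_input = matrix_to_counts(gene_input),
    peak_ip = matrix_to_counts(peak_ip),
    peak_input = matrix_to_counts(peak_input),
    samples = samples,
    peak_gene_map = tibble::tibble(peak_id = peak_ids,
                                   gene_id = gene_ids[gene_of_peak]),
    truth_genes = tibble::tibble(gene_id = gene_ids, q = q,
                                 delta = delta, is_de = is_de),
    truth_peaks = tibble::tibble(peak_id = peak_ids,
                                 gene_id = gene_ids[gene_of_peak],
                                 rho = rho, beta = beta, is_dm = is_dm,
                                 class = cls),
    size_factors_true = tibble::tibble(sample_id = samples$sample_id,
                                       size_factor = unname(s_j)),
    config = cf, seed = seed
  ), class = "merip_sim")
}

#' @export
print.merip_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic MeRIP-seq data: %d genes, %d peaks, %d x 2 x 2 samples (seed %d)\n",
    nrow(x$truth_genes), nrow(x$truth_peaks), x$config$n_reps, x$seed))
  cat(sprintf("  planted: %d DE genes, %d DM peaks\n",
              sum(x$truth_genes$is_de), sum(x$truth_peaks$is_dm)))
  invisible(x)
}

#' Simulate IP/input coverage tracks with planted enrichment blocks
#'
#' Flat Poisson input background with ~200-nt IP enrichment blocks at a
#' chosen fold, emitted as run-length-compressed bedGraph tibbles plus
#' the truth intervals, for benchmarking [call_enriched_windows()].
#'
#' @param seed Integer seed (mandatory).
#' @param n_peaks Number of planted enrichment blocks.
#' @param contig_length Contig length (bp).
#' @param background_depth Mean per-base depth of the input (and of the
#'   IP outside peaks).
#' @param fold IP enrichment fold inside planted blocks.
#' @param peak_width Width of each planted block (bp; the ~200-nt
#'   fragment scale).
#' @param min_spacing Minimum distance between planted block starts.
#' @param contig Contig name.
#' @return List with `ip`, `input` (bedGraph tibbles: `contig`, `start`,
#'   `end`, `depth`) and `truth` (planted intervals with `name`).
#' @export
simulate_coverage_tracks <- function(seed, n_peaks = 50,
                                     contig_length = 200000,
                                     background_depth = 20, fold = 6,
                                     peak_width = 200,
                                     min_spacing = 1000,
                                     contig = "chrS") {
  if (missing(seed)) abort("`seed` is mandatory.")
  set.seed(seed)
  n_slots <- floor(contig_length / min_spacing) - 1
  if (n_peaks > n_slots) abort("contig too short for that many peaks.")
  slots <- sort(sample(seq_len(n_slots), n_peaks))
  starts <- slots * min_spacing
  truth <- tibble::tibble(contig = contig, start = starts,
                          end = starts + peak_width,
                          name = sprintf("true_%03d", seq_len(n_peaks)))
  base_ip <- rep(background_depth, contig_length)
  for (i in seq_len(n_peaks)) {
    base_ip[(starts[i] + 1):(starts[i] + peak_width)] <-
      background_depth * fold
  }
  ip_depth <- stats::rpois(contig_length, base_ip)
  in_depth <- stats::rpois(contig_length, background_depth)
  list(ip = rle_track(ip_depth, contig),
       input = rle_track(in_depth, contig),
       truth = truth)
}

# Run-length compress a per-base depth vector into a bedGraph tibble.
rle_track <- function(depth, contig) {
  r <- rle(depth)
  ends <- cumsum(r$lengths)
  tibble::tibble(contig = contig,
                 start = c(0L, ends[-length(ends)]),
                 end = ends, depth = r$values)
}

#' Simulate a qPCR plate from true abundances
#'
#' Inverse of the qPCR arithmetic: `Ct = offset - log2(abundance * f) +
#' N(0, noise_sd_ct)`, so at zero noise every 2-fold abundance ratio is
#' exactly one cycle and the enrichment calculators recover the planted
#' values exactly.
#'
#' @param plate Tibble with columns `target`, `fraction`, `abundance`
#'   (> 0) and `dilution_fraction`.
#' @param noise_sd_ct Gaussian Ct noise (cycles).
#' @param seed Integer seed (mandatory when `noise_sd_ct > 0`).
#' @param offset Instrument offset (cycles at unit template).
#' @return The plate tibble with a `ct` column added.
#' @export
simulate_qpcr_plate <- function(plate, noise_sd_ct = 0, seed = NULL,
                                offset = 30) {
  if (!all(c("target", "fraction", "abundance",
             "dilution_fraction") %in% names(plate))) {
    abort("`plate` needs target, fraction, abundance, dilution_fraction.")
  }
  if (any(plate$abundance <= 0)) abort("abundances must be positive.")
  if (noise_sd_ct > 0) {
    if (is.null(seed)) abort("`seed` is mandatory for noisy simulation.")
    set.seed(seed)
  }
  noise <- if (noise_sd_ct > 0) {
    stats::rnorm(nrow(plate), 0, noise_sd_ct)
  } else 0
  plate$ct <- offset - log2(plate$abundance * plate$dilution_fraction) +
    noise
  plate
}

#' Simulate an actinomycin-D decay series
#'
#' `fraction(t) = 2^(-t / t_half)` with multiplicative log-normal noise
#' at the sampled timepoints; t = 0 is fixed at 1.
#'
#' @param t_half True half-life (h, > 0).
#' @param timepoints Sampling times (h), the bench default
#'   `c(0, 2, 4, 6)`.
#' @param noise_sd Log-normal noise scale (0 = exact).
#' @param seed Integer seed (mandatory when `noise_sd > 0`).
#' @return Tibble with `time_h`, `fraction`.
#' @export
simulate_decay_series <- function(t_half, timepoints = c(0, 2, 4, 6),
                                  noise_sd = 0, seed = NULL) {
  if (t_half <= 0) abort("`t_half` must be positive.")
  if (noise_sd > 0) {
    if (is.null(seed)) abort("`seed` is mandatory for noisy simulation.")
    set.seed(seed)
  }
  f <- 2^(-timepoints / t_half)
  if (noise_sd > 0) {
    noisy <- timepoints > 0
    f[noisy] <- f[noisy] * exp(stats::rnorm(sum(noisy), 0, noise_sd))
  }
  tibble::tibble(time_h = timepoints, fraction = f)
}
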