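---
title: "Differential m6A analysis with meripdm: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential m6A analysis with meripdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meripdm)
```

# The measurement and its confounder

MeRIP-seq quantifies m⁶A as coverage peaks in an antibody-enriched (IP)
library over a matched input library, per biological replicate. Because
the IP fraction is drawn from the same RNA pool as the input, any
change in a transcript's expression propagates one-for-one into its IP
counts. A naive condition comparison of IP counts therefore reports
expression changes as "methylation" changes; on data where only
expression differs, naive peak LFCs line up with gene LFCs along the
diagonal. Methylation, properly defined, is the *ratio* of IP to input
signal, and a methylation change is a change in that ratio between
conditions — an interaction effect.

# The count model

All testing is built on a negative-binomial GLM with log link and
variance $\mu + \phi\mu^2$, fitted by IRLS (`fit_nb_glm()`). For
differential methylation the IP and input counts of one peak are
stacked and modelled as

$$\log \mu_{pj} = \mathrm{offset}_j + \alpha_p + a\,\mathrm{IP}_j +
c\,\mathrm{cond}_j + b\,(\mathrm{IP}_j\times\mathrm{cond}_j)$$

so that $c$ absorbs the host transcript's expression change and $b$ is
the methylation change, reported as `lfc_interaction` in log2 units.
The filter quantity `lfc_meth_corrected = lfc_peak_ip −
lfc_gene_input` is the same idea computed from two marginal fits, as
the published filter rule is stated; the correction subtracts the raw
(unshrunk) gene LFC so both terms sit on the same estimation footing.

Size factors are median-of-ratios, estimated separately within IP and
within input libraries: antibody enrichment concentrates reads into a
minority of regions, so a joint estimate would be biased by
composition. Dispersions are method-of-moments per feature within
design cells, then shrunk toward a mean–dispersion trend
$\phi_{tr}(\mu) = a/\mu + b$ fitted across features by least squares;
the shrinkage weight is $d/(d + d_0)$ with $d$ the residual degrees of
freedom and prior weight $d_0 = 20$. This is intentionally simpler than
the empirical-Bayes machinery of the large count-model packages; it
recovers the dispersion scale (Poisson data yield $\tilde\phi$ near 0,
$\phi = 0.5$ data yield estimates centred near 0.5) and its residual
error is absorbed into the conservative side of the tests.

## Three tests and the consensus

Mirroring the practice of requiring agreement across independent
packages, the interaction is tested three ways:

* **Wald**: $z = \hat b / \widehat{se}(\hat b)$ from the Fisher
  information, two-sided normal.
* **Quasi-likelihood F**: the Wald chi-square scaled by a per-peak
  Pearson overdispersion, moderated toward the across-peak mean with 10
  prior degrees of freedom, referred to $F(1, d + 10)$. This test
  trades power for robustness to dispersion misspecification.
* **Likelihood ratio**: full model versus the no-interaction reduction,
  $\chi^2_1$.

Each test is Benjamini–Hochberg adjusted separately; *consensus*
requires `padj < alpha` in all three. The three statistics are computed
from the same counts and are strongly correlated, so the consensus
behaves like the weakest test (in practice the QL F), not like an
intersection of independent screens — that is the intended
conservatism.

## The filtering cascade

Filters are applied in a fixed order, and every stage count is recorded
(`cascade_summary()`):

1. consensus significance (`alpha = 0.05`);
2. confounding filter `|lfc_peak_ip − lfc_gene_input| ≥ delta`
   (`delta = 1` log2 units);
3. low-coverage filter on raw IP counts (`min_count = 10`); the
   aggregation is the mean across samples by default, with `min` and
   `sum` available because the published rule does not state one;
4. direction call: corrected LFC ≥ +1 → hypermethylated in condition B,
   ≤ −1 → hypermethylated in condition A.

The direction threshold defaults to the confounding `delta`, which
makes the final stage count split exactly into the two direction
classes. Peaks with no mapped gene are kept, corrected against a gene
LFC of 0, and flagged `unmapped` rather than dropped — intergenic peaks
are information, not errors. Whether the published direction rule
applies to the corrected or the raw LFC is not decidable from its
wording; we apply it to the corrected LFC and expose
`direction_delta` separately.

# Thresholds

| Parameter | Default | Units | Where |
|---|---|---|---|
| `alpha` | 0.05 | adjusted p | consensus, DE |
| `de_lfc` | 0.5 | log2 | DE retention on shrunk LFC |
| `confound_delta` | 1 | log2 | confounding filter |
| `min_count` | 10 | raw IP reads | coverage filter |
| `direction_delta` | 1 | log2 | direction call |
| `ora_alpha` | 0.05 | adjusted p | gene-set ORA |
| `top_k` | 15 | genes | ranked shortlist |

All of these live in `pipeline_config()` and are serialized (YAML) next
to every pipeline output, so a result directory always carries the
exact configuration that produced it.

# The synthetic generator

`simulate_merip_counts()` emulates the target study design: two
conditions, five IP and five input replicates each, log-normal baseline
expression (median ≈ 100 counts, sdlog 1), global marginal dispersion
$\phi = 0.2$, baseline IP enrichment $\rho_p$ log-uniform between 2×
and 8×, 10% of genes differentially expressed at $|\delta| = 2$ log2,
10% of peaks differentially methylated with $|\beta| \in \{1, 1.5,
2\}$ — magnitudes chosen to straddle the $|\Delta LFC| \ge 1$ filter.
Peak input counts follow the host gene's rate scaled by a peak/gene
length ratio (0.2) *without* $\beta$: methylation is invisible in the
input, as the assay requires.

Two structural choices matter:

* **Paired biological noise.** The IP, input and gene-level libraries
  of one replicate measure the same RNA pool. The generator therefore
  decomposes $\phi$ into a mean-1 gamma biological factor drawn once
  per (gene, replicate) and shared across the three matrices, plus
  independent technical NB noise (`phi_technical = 0.05`, a typical
  library-level overdispersion). Each matrix's marginal law remains
  gamma-Poisson ≈ NB($\phi = 0.2$). Without this pairing the
  subtraction-based correction would *add* independent noise instead of
  cancelling shared noise, and the assay's central property — that
  correcting for expression removes the confounding — could not be
  reproduced by any analysis.
* **Truth is part of the design.** Baselines, effect assignments and
  true size factors are drawn from a configuration-owned `truth_seed`;
  the user-facing `seed` drives only the count noise. Re-simulating
  with a new seed changes the data but not the planted truth, so
  power and FDR estimates average over noise, not over designs.

What the generator does **not** emulate: read-level artifacts (GC and
positional bias, duplicates), fragment sampling, isoforms, batch
effects, varying per-gene dispersions, and antibody-specificity
artifacts (m⁶Am cross-reactivity). Tests that pass on this generator
demonstrate the statistical machinery under its stated model; they do
not certify robustness to those real-data pathologies.

`simulate_coverage_tracks()` plants ~200-nt 6× enrichment blocks (the
chemical fragmentation scale) on a flat Poisson background for
benchmarking the window caller, and `simulate_qpcr_plate()` /
`simulate_decay_series()` invert the qPCR and decay arithmetic so the
calculators can be round-trip tested exactly at zero noise.

# Peak calling and annotation

The window caller tiles contigs into 100-bp windows (the extension
scale of the fragment-based callers used upstream of analyses like
this), converts summed per-base depth to approximate read counts, and
tests each window's IP count against a depth-scaled input expectation
with a Poisson upper tail, floored at the genome-wide mean IP count per
window so zero-input windows cannot be called. Window p-values are
BH-adjusted; significant windows within `merge_gap = 100` bp merge into
peaks scored `-10·log10(p_min)`. This deliberately omits the fragment
model, duplicate handling and multi-level local background of full
callers; on planted-signal benchmarks it recovers 6× blocks with
recall ≥ 0.95 and precision ≥ 0.9, which is the regime the downstream
count-based testing needs.

Annotation assigns each peak the gene with maximal overlap and one
category per peak; ties break by `3UTR > 5UTR > CDS > intron > ncRNA`,
reflecting where m⁶A concentrates (stop-codon-proximal 3′UTR and
5′UTR), and the precedence is configurable. Coordinates are 0-based
half-open throughout; gene-model tables are converted from 1-based
inclusive on read. Calling is strand-unaware because the coverage is;
strand enters only through the UTR identities of the models.

# Integration and ranking

Gene-set screening of the candidate list is implemented as
hypergeometric over-representation (ORA) rather than a ranked-list
running-sum enrichment: the object being filtered is a fixed candidate
list, which is exactly the ORA setting. The universe is the set of
genes tested for differential expression — detection-conditioned, not
the whole genome. Ranking is a deterministic total order: combined
weighted absolute LFC (weights 1/1 by default), then count of
significant set memberships, then user-supplied annotation flags
(literature and clinical-database relevance cannot be computed and are
accepted as data), then gene id. Permuting the input rows cannot change
the output.

# Validation calculators

All closed forms are implemented exactly as used at the bench, with two
decisions worth stating:

* **CDI modes.** The printed form of the drug-interaction coefficient
  divides the combined-treatment viability by
  `v(cond − drug) · v(NC − drug)`; since viabilities are normalized to
  the untreated control, the second term is identically 1 and the
  formula degenerates to a simple ratio. The conventional Bliss-style
  form divides by `v(cond − drug) · v(NC + drug)`. We default to the
  conventional form (`mode = "standard"`) and ship the printed form as
  `mode = "printed"`; the choice is logged in the output, never silent.
  Classification thresholds (synergy below 1.0, significant synergy
  below 0.7) are boundary-inclusive on the stronger side.
* **Decay model.** Transcript stability after transcription shut-off is
  fitted as a single exponential with the intercept fixed at the t = 0
  fraction: least squares of $\ln f = -kt$ through the origin,
  $t_{1/2} = \ln 2 / k$. Non-positive fitted rates are reported as
  "stable" ($t_{1/2} = \infty$) rather than as negative half-lives, and
  non-positive fractions are rejected with a pointer to detection-floor
  handling rather than silently dropped.

The RIP enrichment chain applies the dilution corrections
($\mathrm{Ct} - \log_2 f$) before any ΔCt, defaulting to the bench
protocol's fractions (8/14 for the IP eluate; 10% × 1/14 for input).

# Numerical choices

* IRLS convergence: relative deviance change < 1e-8 or 100 iterations;
  non-convergence is returned as a flag, never raised as an error, and
  downstream tests propagate NA.
* All-zero features get NA fits; NA p-values are excluded from the BH
  divisor and propagated.
* Linear predictors are clamped to ±30 on the log scale to prevent
  overflow in degenerate fits.
* Coefficients are fitted in natural log and reported in log2
  everywhere user-facing.
* LFC shrinkage is a zero-centred normal prior (posterior mode
  $\hat\beta \cdot s^2/(s^2 + se^2)$) with $s$ estimated from the 95th
  percentile of the raw |LFC|s when not supplied — large effects are
  barely shrunk, noisy small-count estimates strongly.
* PCA on fewer samples than requested components reduces the component
  count with a warning; an all-identical matrix returns an explicit
  degenerate result rather than erroring.

# Problem sizes and runtime

The test suite and the acceptance script run the full design at 1,000
genes / 2,000 peaks / 5 + 5 replicates per condition — enough for
stable operating-characteristic estimates while keeping a complete run
in tens of seconds on one core. Module tests use 300–600 features.

# Known limitations

* **Power of the interaction test.** With marginal dispersion 0.2 and
  five replicates, the standard error of the interaction is bounded
  below by $\sqrt{4\phi/n} \approx 0.4$ (natural log) regardless of
  depth, so a $|\beta| = 2$ (log2) methylation change sits near
  $z \approx 3.5$. After BH adjustment and the three-test consensus,
  the cascade recovers roughly two-thirds of such peaks — the exact
  sensitivity under the default design is computed by
  `scripts/acceptance.R`. A replicate-blocked (paired) model would
  exploit the shared biological noise and detect substantially more,
  but the stacked four-coefficient model implemented here is the one
  the consensus packages fit.
* The confounding filter subtracts an *estimated* gene LFC; for genes
  with few input reads this injects noise into the corrected LFC (a
  small negative correlation with the gene LFC is expected and
  observed).
* The window caller resolves methylation to ~100 nt; single-nucleotide
  site calling is out of scope.
* The QNB-style third test is represented by the NB likelihood-ratio
  test: the consensus needs three statistically distinct tests of the
  same interaction, and the LRT fills that role; it is pluggable.
* Survival analysis, ranked-list GSEA and isoform-level effects are out
  of scope.
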