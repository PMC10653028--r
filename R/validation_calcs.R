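#' RT-qPCR relative expression against a housekeeping gene
#'
#' `2^(Ct_housekeeping - Ct_target)`: one cycle earlier than the
#' housekeeping gene means twice the relative abundance.
#'
#' @param ct_target,ct_housekeeping Cycle-threshold values (vectorized).
#' @return Relative expression ratio(s).
#' @export
relative_expression <- function(ct_target, ct_housekeeping) {
  stopifnot(is.finite(ct_target), is.finite(ct_housekeeping))
  2^(ct_housekeeping - ct_target)
}

#' MeRIP-qPCR percent input
#'
#' `100 * 2^(Ct_input - Ct_RIP)`: the fraction of a transcript
#' recovered by immunoprecipitation relative to the input material.
#'
#' @param ct_input,ct_rip Cycle thresholds in the input control and the
#'   RIP fraction.
#' @return Percent of input (vectorized).
#' @export
merip_percent_input <- function(ct_input, ct_rip) {
  stopifnot(is.finite(ct_input), is.finite(ct_rip))
  100 * 2^(ct_input - ct_rip)
}

#' MeRIP efficiency gate
#'
#' Pull-down efficiency check on a constitutively methylated positive
#' control (SETD7) against an unmethylated one (GAPDH): the pull-down
#' passes when the enrichment ratio reaches the threshold (default
#' 100-fold; the boundary itself passes).
#'
#' @param setd7_enrichment,gapdh_enrichment Positive enrichment values
#'   (e.g. percent input) for the two control transcripts.
#' @param threshold Required fold ratio.
#' @return Logical: `TRUE` when `setd7 / gapdh >= threshold`.
#' @export
merip_efficiency_gate <- function(setd7_enrichment, gapdh_enrichment,
                                  threshold = 100) {
  stopifnot(setd7_enrichment > 0, gapdh_enrichment > 0)
  setd7_enrichment / gapdh_enrichment >= threshold
}

#' Dilution-normalized RIP-qPCR ΔCt
#'
#' `(Ct_fraction - log2 f_fraction) - (Ct_input - log2 f_input)`, where
#' each `f` is the fraction of material carried into cDNA synthesis /
#' qPCR; subtracting `log2 f` converts the observed Ct to the Ct the
#' undiluted material would give.
#'
#' @param ct,f Cycle threshold and dilution fraction of the IP (RIP or
#'   IgG) reaction.
#' @param ct_input,f_input Same for the input control.
#' @return Normalized ΔCt.
#' @export
rip_normalized_dct <- function(ct, f, ct_input, f_input) {
  (ct - log2(f)) - (ct_input - log2(f_input))
}

#' RIP-qPCR enrichment chain
#'
#' The full dilution-corrected RIP arithmetic per transcript:
#' normalized ΔCt for the RIP and IgG fractions, percent input
#' (`2^-ΔCt`), fold enrichment over the IgG background
#' (`2^-(ΔCt_RIP - ΔCt_IgG)`), and fold enrichment relative to a
#' negative-control transcript that does not bind the RIP protein.
#'
#' Default dilution fractions reflect a typical bench protocol: 8 of 14
#' µl RIP eluate into cDNA; 10% of input saved, 1 of 14 µl into cDNA.
#'
#' @param data Tibble with columns `target`, `fraction` (`"RIP"`,
#'   `"IgG"`, `"input"`), `ct`, and optionally `dilution_fraction`
#'   (otherwise filled from `f_rip` / `f_input`; the IgG fraction uses
#'   `f_rip`).
#' @param negative_control Target name of the non-binding transcript.
#' @param f_rip,f_input Default dilution fractions.
#' @return A tibble per target: `target`, `dct_rip`, `dct_igg`,
#'   `percent_input`, `fold_enrichment`, `relative_fold_enrichment`.
#' @export
rip_relative_enrichment <- function(data, negative_control,
                                    f_rip = 8 / 14,
                                    f_input = (10 / 100) * (1 / 14)) {
  needed <- c("target", "fraction", "ct")
  if (!all(needed %in% names(data))) {
    abort("`data` needs columns target, fraction, ct.")
  }
  if (!"dilution_fraction" %in% names(data)) {
    data$dilution_fraction <- ifelse(data$fraction == "input",
                                     f_input, f_rip)
  }
  if (any(data$dilution_fraction <= 0 | data$dilution_fraction > 1)) {
    abort("dilution fractions must lie in (0, 1].")
  }
  if (!negative_control %in% data$target) {
    abort("negative-control transcript missing from `data`.")
  }
  wide <- data %>%
    dplyr::group_by(.data$target) %>%
    dplyr::group_modify(function(d, key) {
      get1 <- function(fr) {
        row <- d[d$fraction == fr, , drop = FALSE]
        if (nrow(row) != 1) {
          abort(sprintf("target %s needs exactly one '%s' record.",
                        key$target, fr))
        }
        row
      }
      rip <- get1("RIP"); igg <- get1("IgG"); inp <- get1("input")
      dct_rip <- rip_normalized_dct(rip$ct, rip$dilution_fraction,
                                    inp$ct, inp$dilution_fraction)
      dct_igg <- rip_normalized_dct(igg$ct, igg$dilution_fraction,
                                    inp$ct, inp$dilution_fraction)
      tibble::tibble(
        dct_rip = dct_rip, dct_igg = dct_igg,
        percent_input = 100 * 2^(-dct_rip),
        fold_enrichment = 2^(-(dct_rip - dct_igg)))
    }) %>%
    dplyr::ungroup()
  neg_fold <- wide$fold_enrichment[wide$target == negative_control]
  wide$relative_fold_enrichment <- wide$fold_enrichment / neg_fold
  wide
}

#' Synergy classification from a coefficient of drug interaction
#'
#' CDI below 1 indicates synergy, below 0.7 significant synergy; the
#' boundary values classify on the stronger side.
#'
#' @param cdi Positive CDI value(s).
#' @return Character: `"significant synergy"`, `"synergy"` or `"none"`.
#' @export
classify_synergy <- function(cdi) {
  stopifnot(all(cdi > 0))
  ifelse(cdi <= 0.7, "significant synergy",
         ifelse(cdi <= 1, "synergy", "none"))
}

#' Coefficient of drug interaction from viabilities
#'
#' With viabilities as fractions of the untreated negative control, the
#' conventional (`standard`) CDI compares the combined effect to the
#' product of the single effects: `v(cond+drug) / (v(cond-drug) *
#' v(NC+drug))`; CDI = 1 means the two perturbations act independently.
#' The `printed` mode instead divides by `v(cond-drug) * v(NC-drug)`;
#' because viability is normalized to NC-drug, that denominator term is
#' identically 1, so printed-mode CDI reduces to
#' `v(cond+drug)/v(cond-drug)` (see the package vignette for why both
#' modes exist).
#'
#' @param v_cond_plus,v_cond_minus Viability of the condition with and
#'   without the drug (fractions of the NC-drug reference, or percent --
#'   values above 1.5 are interpreted as percent and divided by 100).
#' @param v_nc_plus Viability of the negative control with the drug
#'   (ignored in `printed` mode).
#' @param mode `"standard"` (default) or `"printed"`.
#' @return The CDI (scalar or vector).
#' @export
cdi <- function(v_cond_plus, v_cond_minus, v_nc_plus = NULL,
                mode = c("standard", "printed")) {
  mode <- match.arg(mode)
  as_frac <- function(v) ifelse(v > 1.5, v / 100, v)
  vp <- as_frac(v_cond_plus)
  vm <- as_frac(v_cond_minus)
  if (any(vm <= 0)) abort("zero or negative denominator viability.")
  if (mode == "standard") {
    if (is.null(v_nc_plus)) {
      abort("standard mode needs the NC+drug viability.")
    }
    vn <- as_frac(v_nc_plus)
    if (any(vn <= 0)) abort("zero or negative denominator viability.")
    vp / (vm * vn)
  } else {
    vp / (vm * 1)                     # NC-drug term is 1 by normalization
  }
}

#' Percent viability and CDI from an absorbance table
#'
#' Normalizes MTS absorbances to the untreated negative control
#' (`percent viability = 100 * A / A[NC, -drug]`) and computes, for
#' every non-control condition, the CDI and its synergy class.
#'
#' @param data Tibble with columns `condition`, `cisplatin` (logical or
#'   0/1) and `absorbance` (replicate means).
#' @param nc Label of the negative-control condition (default `"NC"`).
#' @param mode CDI mode passed to [cdi()].
#' @return A tibble per non-control condition: `condition`,
#'   `viability_minus`, `viability_plus` (percent), `cdi`,
#'   `synergy`.  The full viability table is attached as
#'   `attr(, "viability")`.
#' @export
percent_viability_and_cdi <- function(data, nc = "NC",
                                      mode = c("standard", "printed")) {
  mode <- match.arg(mode)
  needed <- c("condition", "cisplatin", "absorbance")
  if (!all(needed %in% names(data))) {
    abort("`data` needs columns condition, cisplatin, absorbance.")
  }
  data$cisplatin <- as.logical(data$cisplatin)
  ref <- data$absorbance[data$condition == nc & !data$cisplatin]
  if (length(ref) != 1 || ref <= 0) {
    abort(sprintf("need one positive '%s' absorbance without cisplatin.", nc))
  }
  data$viability <- 100 * data$absorbance / ref
  get_v <- function(cond, cis) {
    v <- data$viability[data$condition == cond & data$cisplatin == cis]
    if (length(v) != 1) {
      abort(sprintf("need exactly one record for %s %s cisplatin.",
                    cond, if (cis) "+" else "-"))
    }
    v
  }
  nc_plus <- if (mode == "standard") get_v(nc, TRUE) else NA_real_
  conds <- setdiff(unique(data$condition), nc)
  out <- purrr::map_dfr(conds, function(cond) {
    vm <- get_v(cond, FALSE)
    vp <- get_v(cond, TRUE)
    ci <- cdi(vp, vm, if (mode == "standard") nc_plus else NULL, mode)
    tibble::tibble(condition = cond, viability_minus = vm,
                   viability_plus = vp, cdi = ci,
                   synergy = classify_synergy(ci))
  })
  attr(out, "viability") <- tibble::as_tibble(
    data[c("condition", "cisplatin", "absorbance", "viability")])
  out
}

#' Fit an mRNA decay half-life from an actinomycin-D chase
#'
#' Single-exponential decay with the intercept fixed at 1 (the t = 0
#' fraction): least squares of `ln(fraction) = -k t` through the
#' origin, giving `t½ = ln 2 / k`.  Fractions are re-normalized to the
#' t = 0 value if needed.  A non-positive fitted rate is reported as a
#' stable transcript (`k = 0`, infinite half-life).
#'
#' @param data Tibble with columns `time_h` and `fraction` (remaining
#'   fraction, > 0), including t = 0; at least 3 timepoints.
#' @return A `decay_fit` object with elements `k` (1/h), `t_half` (h),
#'   `r_squared`, `n`, `data` (with fitted values).  `tidy()` returns
#'   the per-timepoint table, `glance()` the one-row fit summary.
#' @export
fit_half_life <- function(data) {
  if (!all(c("time_h", "fraction") %in% names(data))) {
    abort("`data` needs columns time_h and fraction.")
  }
  t <- data$time_h
  f <- data$fraction
  if (length(t) < 3) abort("need >= 3 timepoints.")
  if (!any(t == 0)) abort("a t = 0 timepoint is required.")
  if (any(f <= 0)) {
    abort("non-positive remaining fraction; handle the detection floor before fitting.")
  }
  f <- f / f[t == 0][1]
  lf <- log(f)
  pos <- t > 0
  k <- -sum(t[pos] * lf[pos]) / sum(t[pos]^2)
  stable <- k <= 0
  if (stable) k <- 0
  fitted_lf <- -k * t
  ss_res <- sum((lf - fitted_lf)^2)
  ss_tot <- sum((lf - mean(lf))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(
    list(k = k, t_half = if (stable) Inf else log(2) / k,
         r_squared = r2, stable = stable, n = length(t),
         data = tibble::tibble(time_h = t, fraction = f,
                               fitted = exp(fitted_lf))),
    class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$stable) {
    cat("Decay fit: stable transcript (k = 0, t1/2 = Inf)\n")
  } else {
    cat(sprintf("Decay fit: k = %.4f /h, t1/2 = %.2f h (R2 = %.3f)\n",
                x$k, x$t_half, x$r_squared))
  }
  invisible(x)
}

#' @rdname fit_half_life
#' @param x A `decay_fit` object.
#' @param ... Unused.
#' @export
tidy.decay_fit <- function(x, ...) x$data

#' @rdname fit_half_life
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(k = x$k, t_half = x$t_half, r_squared = x$r_squared,
                 stable = x$stable, n = x$n)
}
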