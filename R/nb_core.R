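#' Median-of-ratios size factors
#'
#' Estimates per-sample library-size factors by the median-of-ratios
#' method: each feature's counts are divided by the feature's geometric
#' mean across samples, and a sample's factor is the median of those
#' ratios over features whose geometric mean is positive.
#'
#' IP and input libraries have systematically different count
#' compositions (antibody enrichment concentrates reads in methylated
#' regions), so factors should be estimated separately within each assay;
#' the pipeline functions do this for you.
#'
#' @param counts A count table: a data frame with a `feature_id` column
#'   and one non-negative integer column per sample.
#' @return A tibble with columns `sample_id` and `size_factor`.
#' @examples
#' counts <- tibble::tibble(feature_id = c("g1", "g2"),
#'                          s1 = c(10L, 20L), s2 = c(20L, 40L))
#' estimate_size_factors(counts)
#' @export
estimate_size_factors <- function(counts) {
  m <- counts_to_matrix(counts)
  sf <- size_factors_matrix(m)
  tibble::tibble(sample_id = colnames(m), size_factor = unname(sf))
}

# Matrix-level worker shared by the pipeline stages.
size_factors_matrix <- function(m) {
  log_geo <- rowMeans(log(m))          # -Inf for any row containing a zero
  use <- is.finite(log_geo)
  if (!any(use)) {
    abort("cannot normalize: no feature has positive counts in every sample.")
  }
  sf <- apply(m[use, , drop = FALSE], 2, function(col) {
    stats::median(col / exp(log_geo[use]))
  })
  if (any(!is.finite(sf) | sf <= 0)) {
    abort("cannot normalize: non-positive size factor estimated.")
  }
  sf
}

#' Per-feature negative-binomial dispersion estimates
#'
#' Method-of-moments dispersion per feature on normalized counts within
#' design cells, followed by shrinkage toward a mean--dispersion trend
#' \eqn{\phi_{tr}(\mu) = a/\mu + b} fitted across features.  The shrunk
#' value is a weighted average of the raw estimate and the trend, with
#' weight increasing in the residual degrees of freedom.  This is a
#' deliberately simple stand-in for the empirical-Bayes machinery of
#' DESeq2/edgeR; it recovers the dispersion scale well enough for the
#' Wald, quasi-likelihood and likelihood-ratio tests built on it.
#'
#' @param counts Count table (`feature_id` + sample columns).
#' @param cells A factor or character vector, one entry per sample, giving
#'   the design cell (e.g. `interaction(condition, assay)`).  Replicates
#'   share a cell.
#' @param size_factors Optional tibble from [estimate_size_factors()]; if
#'   `NULL`, estimated from `counts`.
#' @param prior_df Prior degrees of freedom controlling how strongly raw
#'   estimates are pulled toward the trend (default 20).
#' @return A tibble with columns `feature_id`, `mean_norm`, `phi_raw`,
#'   `phi_trend`, `phi_shrunk`.
#' @export
estimate_dispersions <- function(counts, cells, size_factors = NULL,
                                 prior_df = 20) {
  m <- counts_to_matrix(counts)
  cells <- as.factor(cells)
  if (length(cells) != ncol(m)) {
    abort("`cells` must have one entry per sample column.")
  }
  if (any(table(cells) < 2)) {
    abort("dispersion estimation needs >= 2 replicates per design cell.")
  }
  sf <- if (is.null(size_factors)) size_factors_matrix(m) else {
    size_factors$size_factor[match(colnames(m), size_factors$sample_id)]
  }
  est <- dispersions_matrix(m, cells, sf, prior_df)
  tibble::tibble(feature_id = rownames(m), !!!est)
}

dispersions_matrix <- function(m, cells, sf, prior_df = 20) {
  q <- sweep(m, 2, sf, "/")            # normalized counts
  cells <- as.factor(cells)
  lv <- levels(cells)
  n_c <- as.integer(table(cells)[lv])
  df_res <- sum(n_c - 1L)
  # Pooled method-of-moments across cells:
  #   phi-hat = sum_c (n_c-1)(var_c - mean_c) / sum_c (n_c-1) mean_c^2
  num <- den <- rep(0, nrow(m))
  for (i in seq_along(lv)) {
    qc <- q[, cells == lv[i], drop = FALSE]
    mu_c <- unname(rowMeans(qc))
    v_c <- unname(apply(qc, 1, stats::var))
    w <- n_c[i] - 1L
    num <- num + w * (v_c - mu_c)
    den <- den + w * mu_c^2
  }
  phi_raw <- ifelse(den > 0, pmax(0, num / den), 0)
  mean_norm <- unname(rowMeans(q))
  # Trend phi_tr(mu) = a/mu + b by least squares on features with signal,
  # coefficients clamped to be non-negative.
  use <- mean_norm > 1 & is.finite(phi_raw)
  if (sum(use) >= 10) {
    fit <- stats::lm.fit(cbind(inv_mu = 1 / mean_norm[use], b = 1),
                         phi_raw[use])
    a <- max(0, fit$coefficients[["inv_mu"]])
    b <- max(0, fit$coefficients[["b"]])
  } else {
    a <- 0
    b <- stats::median(phi_raw)
  }
  phi_trend <- ifelse(mean_norm > 0, a / mean_norm + b, b)
  w_raw <- df_res / (df_res + prior_df)
  phi_shrunk <- pmax(0, w_raw * phi_raw + (1 - w_raw) * phi_trend)
  list(mean_norm = mean_norm, phi_raw = phi_raw,
       phi_trend = phi_trend, phi_shrunk = phi_shrunk)
}

#' Fit a negative-binomial GLM with log link and known dispersion
#'
#' Maximizes the NB likelihood with mean \eqn{\mu = \exp(X\beta +
#' \mathrm{offset})} and variance \eqn{\mu + \phi\mu^2} by iteratively
#' reweighted least squares.  \eqn{\phi = 0} is the Poisson limit.
#' Coefficients are on the natural-log scale; result tables downstream
#' report log2 fold changes (divide by `log(2)`).
#'
#' @param y Non-negative integer counts for one feature.
#' @param design Numeric design matrix, rows matching `y`; must be full
#'   rank.
#' @param offset Log-scale offsets (typically `log(size_factor)`);
#'   recycled if scalar.
#' @param phi Dispersion (non-negative scalar).
#' @param tol Relative deviance-change convergence tolerance.
#' @param max_iter Maximum IRLS iterations.
#' @return An object of class `nb_glm_fit`: a list with `coefficients`
#'   (natural log), `vcov` (Fisher-information covariance), `loglik`,
#'   `converged`, `iterations`, `fitted`, `df_residual`, `phi`.  An
#'   all-zero `y` yields an NA fit (`converged = NA`), not an error.
#' @export
fit_nb_glm <- function(y, design, offset = 0, phi = 0,
                       tol = 1e-8, max_iter = 100L) {
  X <- as.matrix(design)
  n <- length(y)
  if (nrow(X) != n) abort("`design` rows must match length of `y`.")
  if (length(offset) == 1) offset <- rep(offset, n)
  if (any(!is.finite(offset))) abort("offsets must be finite.")
  if (phi < 0) abort("`phi` must be non-negative.")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(sprintf("design is not full rank; collinear column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  p <- ncol(X)
  empty <- structure(
    list(coefficients = stats::setNames(rep(NA_real_, p), colnames(X)),
         vcov = matrix(NA_real_, p, p), loglik = NA_real_,
         converged = NA, iterations = 0L, fitted = rep(NA_real_, n),
         df_residual = n - p, phi = phi),
    class = "nb_glm_fit")
  if (all(y == 0)) return(empty)

  beta <- qr.coef(qrX, log(y + 0.5) - offset)
  dev_old <- Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)    # guard against overflow
    mu <- exp(eta)
    w <- mu / (1 + phi * mu)           # Fisher weights for log link
    z <- eta - offset + (y - mu) / mu  # working response
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    dev <- -2 * nb_loglik(y, exp(pmin(drop(X %*% beta_new) + offset, 30)), phi)
    if (!is.finite(dev)) break
    if (abs(dev - dev_old) < tol * (abs(dev_old) + 0.1)) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
    dev_old <- dev
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + phi * mu)
  info <- crossprod(X, X * w)
  vcov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, p, p)
  })
  structure(
    list(coefficients = stats::setNames(drop(beta), colnames(X)),
         vcov = vcov, loglik = nb_loglik(y, mu, phi),
         converged = converged, iterations = iter, fitted = mu,
         df_residual = n - p, phi = phi),
    class = "nb_glm_fit")
}

# Log-likelihood of counts under NB(mu, phi); phi = 0 is Poisson.
nb_loglik <- function(y, mu, phi) {
  if (phi <= 0) {
    sum(stats::dpois(y, mu, log = TRUE))
  } else {
    sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  }
}

#' @export
print.nb_glm_fit <- function(x, ...) {
  cat("Negative-binomial GLM fit (phi =", format(x$phi), ")\n")
  cat("  converged:", x$converged, "in", x$iterations, "iterations\n")
  cat("  log-likelihood:", format(x$loglik), "\n")
  print(x$coefficients)
  invisible(x)
}

#' @rdname fit_nb_glm
#' @param x An `nb_glm_fit` object.
#' @param ... Unused.
#' @export
tidy.nb_glm_fit <- function(x, ...) {
  se <- sqrt(pmax(diag(x$vcov), 0))
  est <- x$coefficients
  stat <- ifelse(se > 0, est / se, NA_real_)
  tibble::tibble(
    term = names(est),
    estimate = unname(est) / LOG2,     # log2 scale for reporting
    std.error = unname(se) / LOG2,
    statistic = unname(stat),
    p.value = 2 * stats::pnorm(abs(unname(stat)), lower.tail = FALSE)
  )
}

#' @rdname fit_nb_glm
#' @export
glance.nb_glm_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, converged = isTRUE(x$converged),
                 iterations = x$iterations, df.residual = x$df_residual,
                 phi = x$phi)
}

#' Wald test of a linear contrast of GLM coefficients
#'
#' Computes \eqn{z = c'\hat\beta / \sqrt{c'\Sigma c}} and a two-sided
#' p-value from the standard normal.
#'
#' @param fit An [fit_nb_glm()] result.
#' @param contrast Numeric contrast vector over the coefficients.
#' @return A one-row tibble: `estimate` (log2), `se` (log2), `statistic`,
#'   `p`.  Zero standard error yields `p = NA` with a warning.
#' @export
wald_test <- function(fit, contrast) {
  if (!inherits(fit, "nb_glm_fit")) abort("`fit` must be an nb_glm_fit.")
  if (!isTRUE(fit$converged)) {
    abort("Wald test requires a converged fit.")
  }
  est <- sum(contrast * fit$coefficients)
  v <- drop(t(contrast) %*% fit$vcov %*% contrast)
  if (!is.finite(v) || v <= 0) {
    warn("zero or undefined standard error; p set to NA.")
    return(tibble::tibble(estimate = est / LOG2, se = NA_real_,
                          statistic = NA_real_, p = NA_real_))
  }
  z <- est / sqrt(v)
  tibble::tibble(estimate = est / LOG2, se = sqrt(v) / LOG2,
                 statistic = z,
                 p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' Normal-prior (ridge) shrinkage of log fold changes
#'
#' Posterior-mode shrinkage under a single zero-centered normal prior:
#' `lfc * s^2 / (s^2 + se^2)`.  Noisier (low-count) estimates shrink
#' proportionally more; sign is preserved and `|shrunk| <= |raw|`.  When
#' `prior_scale` is `NULL` it is estimated from the upper quantile of the
#' raw LFCs, so that genuinely large effects are barely touched.
#'
#' @param lfc_raw Raw log2 fold changes.
#' @param se Matching standard errors (log2 scale).
#' @param prior_scale Positive prior standard deviation, or `NULL` to
#'   estimate.
#' @return Numeric vector of shrunk log2 fold changes.
#' @export
shrink_lfc <- function(lfc_raw, se, prior_scale = NULL) {
  if (length(lfc_raw) != length(se)) {
    abort("`lfc_raw` and `se` must have equal length.")
  }
  if (is.null(prior_scale)) {
    ok <- is.finite(lfc_raw)
    prior_scale <- max(stats::quantile(abs(lfc_raw[ok]), 0.95,
                                       names = FALSE), 0.1)
  }
  if (!is.finite(prior_scale) && prior_scale > 0) prior_scale <- Inf
  if (prior_scale <= 0) abort("`prior_scale` must be positive.")
  if (is.infinite(prior_scale)) return(lfc_raw)
  shrink <- prior_scale^2 / (prior_scale^2 + se^2)
  ifelse(is.finite(se), lfc_raw * shrink, 0)
}

#' Benjamini--Hochberg adjustment with NA propagation
#'
#' Step-up FDR adjustment via [stats::p.adjust()]; `NA` p-values (e.g.
#' all-zero features) are excluded from the number of tests and returned
#' as `NA`.
#'
#' @param p Vector of p-values in \[0, 1\] (NA allowed).
#' @return Vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}
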