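# Independent brute-force oracles and small fixture builders shared by
# the test files.  These stay deliberately naive so they cannot share a
# code path with the implementation they check.

# Median-of-ratios, written longhand feature by feature.
oracle_size_factors <- function(m) {
  geo <- apply(m, 1, function(r) prod(r)^(1 / length(r)))
  keep <- geo > 0
  vapply(seq_len(ncol(m)), function(j) {
    stats::median(m[keep, j] / geo[keep])
  }, double(1))
}

# Benjamini-Hochberg step-up, longhand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Hypergeometric upper tail P(X >= k) by direct enumeration of
# binomial coefficients (N <= 30 keeps choose() exact).
oracle_hyper_upper <- function(k, K, N, n) {
  kk <- max(k, 0):min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# NB log-likelihood used by the grid-search GLM oracle.
oracle_nb_loglik <- function(y, mu, phi) {
  if (phi <= 0) sum(dpois(y, mu, log = TRUE))
  else sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

# Tidy count table from a plain matrix.
make_counts <- function(m, prefix = "f") {
  if (is.null(rownames(m))) {
    rownames(m) <- sprintf("%s%03d", prefix, seq_len(nrow(m)))
  }
  if (is.null(colnames(m))) {
    colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  }
  tibble::as_tibble(m, rownames = "feature_id")
}

# Minimal two-condition input-only sample sheet.
make_input_samples <- function(n_per = 3, conditions = c("A", "B")) {
  tibble::tibble(
    sample_id = paste0("s", sprintf("%02d", seq_len(2 * n_per))),
    condition = rep(conditions, each = n_per),
    assay = "input",
    replicate = rep(seq_len(n_per), 2))
}
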