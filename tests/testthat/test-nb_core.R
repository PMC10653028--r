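test_that("size factors: symmetry, scaling, and brute-force agreement", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2)
  sf <- estimate_size_factors(make_counts(m))
  expect_equal(sf$size_factor, c(1, 1))

  set.seed(11)
  base <- matrix(rpois(40, 50) + 1, ncol = 2)
  m2 <- cbind(base[, 1], 2 * base[, 1])
  sf2 <- estimate_size_factors(make_counts(m2))
  expect_equal(sf2$size_factor, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  set.seed(42)
  m3 <- matrix(rpois(300, 60), nrow = 50, ncol = 6)
  got <- estimate_size_factors(make_counts(m3))$size_factor
  expect_equal(got, oracle_size_factors(m3), tolerance = 1e-12)
})

test_that("size factors error when no feature is positive everywhere", {
  m <- matrix(c(0, 5, 3, 0), ncol = 2)
  expect_error(estimate_size_factors(make_counts(m)), "cannot normalize")
})

test_that("size factors agree with the DESeq2 reference estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(5)
  m <- matrix(rnbinom(600, mu = 80, size = 5), nrow = 100)
  colnames(m) <- paste0("s", 1:6)
  ours <- estimate_size_factors(make_counts(m))$size_factor
  ref <- unname(DESeq2::estimateSizeFactorsForMatrix(m))
  # DESeq2 takes the median on the log scale; with an even number of
  # usable features the two medians differ slightly, so this is a
  # methodological cross-check, not an identity.
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("dispersion estimation recovers Poisson and NB regimes", {
  set.seed(21)
  cells <- rep(c("a", "b"), each = 20)
  mp <- matrix(rpois(300 * 40, 100), nrow = 300)
  dp <- estimate_dispersions(make_counts(mp), cells,
                             size_factors = tibble::tibble(
                               sample_id = sprintf("s%02d", 1:40),
                               size_factor = rep(1, 40)))
  expect_lt(median(dp$phi_shrunk), 0.05)

  set.seed(22)
  cells10 <- rep(c("a", "b"), each = 5)
  mn <- matrix(rnbinom(200 * 10, mu = 100, size = 1 / 0.5), nrow = 200)
  dn <- estimate_dispersions(make_counts(mn), cells10,
                             size_factors = tibble::tibble(
                               sample_id = sprintf("s%02d", 1:10),
                               size_factor = rep(1, 10)))
  expect_gt(median(dn$phi_shrunk), 0.3)
  expect_lt(median(dn$phi_shrunk), 0.7)
})

test_that("dispersion is zero for constant counts and errors on single replicates", {
  m <- matrix(rep(c(10, 40), each = 4), nrow = 1)
  cells <- rep(c("a", "b"), each = 4)
  d <- estimate_dispersions(make_counts(m), cells)
  expect_equal(d$phi_raw, 0)
  expect_error(
    estimate_dispersions(make_counts(matrix(1:2, nrow = 1)), c("a", "b")),
    "2 replicates")
})

test_that("NB GLM matches Poisson closed forms at phi = 0", {
  y <- c(3, 7, 4, 9, 5, 2)
  fit <- fit_nb_glm(y, matrix(1, 6, 1, dimnames = list(NULL, "b0")))
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), log(mean(y)), tolerance = 1e-7)

  y2 <- c(4, 6, 5, 12, 18, 15)
  X <- cbind(b0 = 1, grp = rep(0:1, each = 3))
  fit2 <- fit_nb_glm(y2, X)
  expect_equal(unname(fit2$coefficients[2]),
               log(mean(y2[4:6]) / mean(y2[1:3])), tolerance = 1e-7)
})

test_that("NB GLM matches an independent Poisson glm() fit at phi = 0", {
  set.seed(31)
  X <- cbind(intercept = 1, x = rnorm(12))
  off <- log(runif(12, 0.5, 2))
  y <- rpois(12, exp(0.8 + 0.5 * X[, 2] + off))
  fit <- fit_nb_glm(y, X, offset = off, phi = 0)
  ref <- glm(y ~ X[, 2] + offset(off), family = poisson())
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
})

test_that("NB GLM likelihood beats a grid-search oracle", {
  set.seed(33)
  for (rep in 1:20) {
    X <- cbind(b0 = 1, grp = rep(0:1, each = 5))
    y <- rnbinom(10, mu = exp(2 + 0.8 * X[, 2]), size = 1 / 0.3)
    if (all(y == 0)) next
    fit <- fit_nb_glm(y, X, phi = 0.3)
    expect_true(fit$converged)
    grid <- expand.grid(b0 = fit$coefficients[1] + seq(-0.5, 0.5, 0.01),
                        b1 = fit$coefficients[2] + seq(-0.5, 0.5, 0.01))
    ll <- mapply(function(b0, b1) {
      oracle_nb_loglik(y, exp(b0 + b1 * X[, 2]), 0.3)
    }, grid$b0, grid$b1)
    expect_gte(fit$loglik, max(ll) - 1e-6)
  }
})

test_that("NB GLM degenerate inputs behave per contract", {
  X <- cbind(a = 1, b = 1)                    # collinear
  expect_error(fit_nb_glm(c(1, 2, 3), cbind(a = rep(1, 3), b = rep(1, 3))),
               "collinear")
  fit0 <- fit_nb_glm(rep(0, 4), matrix(1, 4, 1))
  expect_true(is.na(fit0$converged))
  expect_true(all(is.na(fit0$coefficients)))
})

test_that("Wald test: null contrast, and type-I error on NB simulations", {
  y <- c(5, 7, 6, 5, 7, 6)
  X <- cbind(b0 = 1, grp = rep(0:1, each = 3))
  fit <- fit_nb_glm(y, X)
  w0 <- wald_test(fit, c(0, 1))
  expect_equal(w0$p, 2 * pnorm(abs(w0$statistic), lower.tail = FALSE))
  # contrast picking nothing: zero estimate and zero variance => NA + warning
  expect_warning(wnull <- wald_test(fit, c(0, 0)), "standard error")
  expect_true(is.na(wnull$p))
  # symmetric two-group data: contrast estimate ~0 => p ~1
  ys <- c(5, 7, 6, 6, 7, 5)
  fs <- fit_nb_glm(ys, X)
  expect_equal(wald_test(fs, c(0, 1))$p, 1, tolerance = 1e-6)

  set.seed(55)
  X <- cbind(b0 = 1, grp = rep(0:1, each = 5))
  p <- replicate(2000, {
    y <- rnbinom(10, mu = 50, size = 1 / 0.2)
    f <- fit_nb_glm(y, X, phi = 0.2)
    if (isTRUE(f$converged)) wald_test(f, c(0, 1))$p else NA_real_
  })
  rate <- mean(p < 0.05, na.rm = TRUE)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.08)
})

test_that("LFC shrinkage limits, sign preservation and monotonicity", {
  lfc <- c(-2, 0.5, 3)
  se <- c(0.5, 0.2, 1)
  expect_equal(shrink_lfc(lfc, se, Inf), lfc)
  expect_lt(max(abs(shrink_lfc(lfc, se, 1e-6))), 1e-4)
  sh <- shrink_lfc(lfc, se, 1)
  expect_true(all(abs(sh) <= abs(lfc)))
  expect_true(all(sign(sh) == sign(lfc)))
  # same raw LFC, noisier estimate shrinks more
  pair <- shrink_lfc(c(2, 2), c(1, 0.1), 1)
  expect_lt(pair[1], pair[2])
  expect_error(shrink_lfc(1, 1, -1), "positive")
})

test_that("BH adjustment matches hand step-up and a brute-force oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(77)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # NA propagation, and padj >= p always
  p <- c(0.01, NA, 0.5)
  adj <- bh_adjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], oracle_bh(p[c(1, 3)]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("re-adjusting BH output never lowers values", {
  set.seed(78)
  p <- runif(25)
  a1 <- bh_adjust(p)
  expect_true(all(bh_adjust(a1) >= a1 - 1e-12))
})
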