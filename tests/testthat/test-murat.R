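# shared random instance generator for multivariate tests
murat_instance <- function(seed, N = 120, v = 6, K = 2, m = 2,
                           rho_y = 0.5) {
  set.seed(seed)
  G <- matrix(rbinom(N * v, 2, runif(v, 0.05, 0.4)), nrow = N, byrow = TRUE)
  X <- cbind(1, matrix(rnorm(N * m), N))
  Sig <- (1 - rho_y) * diag(K) + rho_y
  Y <- matrix(rnorm(N * K), N, K) %*% chol(Sig)
  w <- runif(v, 0.5, 2)
  list(G = G, X = X, Y = Y, w = w)
}

test_that("multivariate null fit reduces to the univariate fit at K = 1", {
  inst <- murat_instance(1)
  y <- inst$Y[, 1, drop = FALSE]
  mu <- fit_null_univariate(as.numeric(y), inst$X)
  mm <- fit_null_multivariate(y, inst$X)
  expect_equal(as.numeric(mm$Sigma), mu$sigma2)
  expect_equal(as.numeric(mm$E), mu$residuals)
})

test_that("residual covariance estimates the generating correlation", {
  set.seed(2024)
  N <- 2000; K <- 2
  X <- cbind(1, rnorm(N))
  # independent traits: off-diagonal near zero
  m0 <- fit_null_multivariate(matrix(rnorm(N * K), N, K), X)
  expect_lt(abs(cov2cor(m0$Sigma)[1, 2]), 3 / sqrt(N))
  # correlated traits in the bone-density regime
  Sig <- matrix(c(1, 0.68, 0.68, 1), 2)
  Y <- matrix(rnorm(N * K), N, K) %*% chol(Sig)
  m1 <- fit_null_multivariate(Y, X)
  expect_lt(abs(cov2cor(m1$Sigma)[1, 2] - 0.68), 0.05)
  # collinear traits are rejected
  expect_error(fit_null_multivariate(cbind(Y[, 1], Y[, 1]), X),
               "positive definite")
})

test_that("factorized statistic matches the dense stacked-model oracle", {
  for (seed in c(3, 4)) {
    inst <- murat_instance(seed, N = 150, v = 8)
    null <- fit_null_multivariate(inst$Y, inst$X)
    for (rho in c(0, 0.3, 0.7, 1)) {
      fast <- murat_q(null, inst$G, inst$w, rho)
      dense <- dense_multivariate_test(null, inst$G, inst$w, rho)
      expect_equal(fast$Q, dense$Q, tolerance = 1e-12)
      expect_equal(fast$lambda, dense$lambda, tolerance = 1e-9)
      expect_equal(fast$p, dense$p, tolerance = 1e-10)
    }
  }
})

test_that("rho = 0 equals the independently coded independent-effects test", {
  # at rho = 0 the statistic is the sum over traits of whitened per-trait
  # score norms; the dense construction plays the separately coded method
  inst <- murat_instance(5, N = 200, v = 10)
  null <- fit_null_multivariate(inst$Y, inst$X)
  fast <- murat_q(null, inst$G, inst$w, 0)
  dense <- dense_multivariate_test(null, inst$G, inst$w, 0)
  expect_equal(fast$p, dense$p, tolerance = 1e-10)
})

test_that("murat p-value law matches a Monte-Carlo quadratic-form oracle", {
  inst <- murat_instance(6, N = 150, v = 8)
  null <- fit_null_multivariate(inst$Y, inst$X)
  res <- murat_q(null, inst$G, inst$w, 0.4)
  set.seed(60)
  pmc <- mc_mixture_tail(res$lambda, res$Q, 2e5)
  se <- sqrt(max(pmc * (1 - pmc), 1e-12) / 2e5)
  expect_lt(abs(res$p - pmc), 3 * se)
})

test_that("permuting trait order leaves all statistics unchanged", {
  inst <- murat_instance(9, N = 150, v = 6, K = 3, rho_y = 0.4)
  n1 <- fit_null_multivariate(inst$Y, inst$X)
  n2 <- fit_null_multivariate(inst$Y[, c(3, 1, 2)], inst$X)
  for (rho in c(0, 0.5, 1)) {
    a <- murat_q(n1, inst$G, inst$w, rho)
    b <- murat_q(n2, inst$G, inst$w, rho)
    expect_equal(a$Q, b$Q, tolerance = 1e-10)
    expect_equal(a$p, b$p, tolerance = 1e-8)
  }
  o1 <- murat_omnibus(n1, inst$G, inst$w, seed = 3)
  o2 <- murat_omnibus(n2, inst$G, inst$w, seed = 3)
  expect_equal(o1$p_by_rho, o2$p_by_rho, tolerance = 1e-8)
  expect_equal(o1$optimal_rho, o2$optimal_rho)
})

test_that("K = 1 multivariate p equals the univariate SKAT p exactly", {
  for (seed in 11:20) {
    inst <- murat_instance(seed, N = 100, v = 5, K = 1)
    y <- as.numeric(inst$Y)
    nu <- fit_null_univariate(y, inst$X)
    nm <- fit_null_multivariate(inst$Y, inst$X)
    ps <- skat_q(nu, inst$G, inst$w)$p
    pm <- murat_q(nm, inst$G, inst$w, rho = 0.6)$p
    expect_equal(pm, ps, tolerance = 1e-12)
    om <- murat_omnibus(nm, inst$G, inst$w)
    expect_equal(om$p_omnibus, ps, tolerance = 1e-12)
  }
})

test_that("omnibus honors its structural constraints", {
  inst <- murat_instance(30, N = 150, v = 6)
  null <- fit_null_multivariate(inst$Y, inst$X)
  # single-point grid: omnibus p is exactly p(0)
  o0 <- murat_omnibus(null, inst$G, inst$w, grid = 0)
  expect_identical(o0$p_omnibus, unname(o0$p_by_rho[1]))
  expect_equal(unname(o0$p_by_rho[1]), murat_q(null, inst$G, inst$w, 0)$p)
  # full grid: min p <= omnibus <= grid-size * min p; optimal rho in grid
  o <- murat_omnibus(null, inst$G, inst$w, seed = 1)
  expect_gte(o$p_omnibus, min(o$p_by_rho))
  expect_lte(o$p_omnibus, min(1, length(o$p_by_rho) * min(o$p_by_rho)))
  expect_true(o$optimal_rho %in% rho_grid())
  expect_equal(unname(which.min(o$p_by_rho)),
               which(rho_grid() == o$optimal_rho))
  # reproducibility: fixed seed gives bit-identical results
  o2 <- murat_omnibus(null, inst$G, inst$w, seed = 1)
  expect_identical(o$p_omnibus, o2$p_omnibus)
  # guard rails
  expect_error(murat_omnibus(null, inst$G, inst$w, mc_draws = 5000), "10000")
  expect_error(murat_omnibus(null, inst$G, inst$w, grid = c(0.2, 0.5)),
               "grid")
})

test_that("selection penalty holds across random instances", {
  for (seed in 41:50) {
    inst <- murat_instance(seed, N = 100, v = 4)
    null <- fit_null_multivariate(inst$Y, inst$X)
    o <- murat_omnibus(null, inst$G, inst$w, seed = seed)
    expect_gte(o$p_omnibus, min(o$p_by_rho))
  }
})

test_that("region-level wrapper assembles univariate and multivariate results", {
  set.seed(70)
  cfg <- sim_config(n_samples = 200, n_variants = 12, maf = c(0.02, 0.3),
                    seed = 70)
  dat <- simulate_dataset(cfg)
  X <- design_matrix(dat$covariates, 200)
  reg <- assign_variants(list(region("1", 1, 1e6, "G")), dat$genotypes)[[1]]
  rec <- murat_region_test(dat$genotypes, reg, dat$phenotypes, X,
                           scheme = "beta:1,25", seed = 2)
  expect_length(rec$p_univariate, 2)
  expect_equal(rec$p_adj_univariate, min(rec$p_univariate))
  expect_true(rec$p_murat > 0 && rec$p_murat <= 1)
  expect_true(rec$optimal_rho %in% rho_grid())
})
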