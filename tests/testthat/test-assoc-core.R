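test_that("mixture tail probability is exact for chi-square special cases", {
  expect_equal(as.numeric(mixture_chisq_p(1, 3.841459)), 0.05, tolerance = 1e-6)
  expect_equal(as.numeric(mixture_chisq_p(c(1, 1), 5.991465)), 0.05,
               tolerance = 1e-6)
  expect_equal(as.numeric(mixture_chisq_p(rep(1, 5), qchisq(0.999, 5))),
               0.001, tolerance = 1e-6)
  expect_equal(as.numeric(mixture_chisq_p(c(2, 1), -1)), 1)
  # scale invariance: (c*lambda, c*q) gives the same p
  p1 <- mixture_chisq_p(c(2, 1, 0.5), 10)
  p2 <- mixture_chisq_p(1e4 * c(2, 1, 0.5), 1e5)
  expect_identical(as.numeric(p1), as.numeric(p2))
})

test_that("mixture tail agrees with a large Monte-Carlo oracle", {
  set.seed(1234)
  lam <- c(2, 1, 0.5)
  p <- as.numeric(mixture_chisq_p(lam, 10))
  pmc <- mc_mixture_tail(lam, 10, 1e6)
  se <- sqrt(pmc * (1 - pmc) / 1e6)
  expect_lt(abs(p - pmc), 3 * se)
})

test_that("the quantile function inverts the tail probability", {
  set.seed(55)
  for (i in 1:5) {
    lam <- rexp(sample(2:10, 1))
    p <- runif(1, 0.001, 0.5)
    q <- mixture_chisq_quantile(lam, p)
    expect_equal(as.numeric(mixture_chisq_p(lam, q)), p, tolerance = 1e-4)
  }
})

test_that("null fit has orthogonal residuals and known toy solution", {
  y <- c(1, 2, 3)
  null <- fit_null_univariate(y, matrix(1, 3, 1))
  expect_equal(unname(null$coef), 2)
  expect_equal(null$residuals, c(-1, 0, 1))
  expect_equal(null$sigma2, 1)

  set.seed(3)
  X <- cbind(1, matrix(rnorm(200 * 3), 200))
  null2 <- fit_null_univariate(rnorm(200), X)
  expect_lt(max(abs(crossprod(X, null2$residuals))), 1e-9)
})

test_that("null fit recovers simulated coefficients and flags collinearity", {
  set.seed(8)
  N <- 500
  X <- cbind(intercept = 1, age = rnorm(N), sexm = rbinom(N, 1, 0.5))
  alpha <- c(1, 0.5, -0.3)
  y <- as.numeric(X %*% alpha) + rnorm(N)
  fit <- fit_null_univariate(y, X)
  se <- sqrt(diag(solve(crossprod(X))) * fit$sigma2)
  expect_true(all(abs(fit$coef - alpha) < 3 * se))

  Xbad <- cbind(X, age_copy = X[, 2])
  expect_error(fit_null_univariate(y, Xbad), "age_copy")
})

test_that("rank-1 SKAT equals the single-variant score test", {
  set.seed(21)
  N <- 300
  X <- cbind(1, rnorm(N))
  g <- rbinom(N, 2, 0.3)
  y <- rnorm(N)
  null <- fit_null_univariate(y, X)
  res <- skat_q(null, matrix(g, ncol = 1), 1)
  expect_equal(res$Q, sum(g * null$residuals)^2 / null$sigma2)
  Pg <- g - qr.fitted(null$qrX, g)
  expect_equal(res$lambda, sum(g * Pg), tolerance = 1e-10)
  # score-test p computed from first principles
  z2 <- sum(g * null$residuals)^2 / (null$sigma2 * sum(Pg^2))
  expect_equal(res$p, pchisq(z2, 1, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("SKAT p matches the Monte-Carlo law of its quadratic form", {
  set.seed(77)
  N <- 200; v <- 10
  G <- matrix(rbinom(N * v, 2, runif(v, 0.05, 0.4)), nrow = N, byrow = TRUE)
  X <- cbind(1, rnorm(N))
  null <- fit_null_univariate(rnorm(N), X)
  res <- skat_q(null, G, 1)
  pmc <- mc_mixture_tail(res$lambda, res$Q, 2e5)
  se <- sqrt(max(pmc * (1 - pmc), 1e-12) / 2e5)
  expect_lt(abs(res$p - pmc), 3 * se)
})

test_that("p-values are invariant to affine rescaling of the trait", {
  set.seed(19)
  N <- 150
  G <- matrix(rbinom(N * 5, 2, 0.2), nrow = N)
  X <- cbind(1, rnorm(N))
  y <- rnorm(N)
  p1 <- skat_q(fit_null_univariate(y, X), G, 1)$p
  p2 <- skat_q(fit_null_univariate(5 * y - 3, X), G, 1)$p
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("degenerate genotype input yields p = 1 with a flag", {
  null <- fit_null_univariate(rnorm(20), matrix(1, 20, 1))
  expect_warning(res <- skat_q(null, matrix(0, 20, 3), 1), "all-zero")
  expect_equal(res$p, 1)
  expect_match(res$note, "no polymorphic")
  expect_error(skat_q(fit_null_univariate(rep(1, 5) * 2, matrix(1, 5, 1)),
                      matrix(1, 5, 1), 1), "zero residual variance")
})

test_that("adjusted univariate p is the minimum across traits", {
  expect_equal(adjusted_univariate_p(c(0.02, 0.5)), 0.02)
  expect_equal(adjusted_univariate_p(c(1, 1)), 1)
  expect_equal(adjusted_univariate_p(0.3), 0.3)
  expect_error(adjusted_univariate_p(numeric(0)), "empty")
  expect_error(adjusted_univariate_p(c(0.5, 0)), "lie in")
})

test_that("Wald test recovers an injected effect and is calibrated", {
  set.seed(40)
  N <- 1000
  X <- cbind(1, rnorm(N))
  g <- rbinom(N, 2, 0.2)
  y <- as.numeric(X %*% c(0.2, 0.1)) + 0.5 * g + rnorm(N)
  fit <- single_variant_wald(y, X, g)
  expect_lt(abs(fit$beta - 0.5), 3 * fit$se)

  # null calibration: p ~ Uniform(0,1)
  ps <- replicate(200, {
    single_variant_wald(rnorm(200), cbind(1, rnorm(200)),
                        rbinom(200, 2, 0.3))$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.001)
})

test_that("Wald and rank-1 SKAT are asymptotically equivalent", {
  set.seed(41)
  N <- 800
  X <- cbind(1, rnorm(N))
  lp <- matrix(NA_real_, 300, 2)
  for (i in 1:300) {
    g <- rbinom(N, 2, runif(1, 0.05, 0.4))
    y <- rnorm(N) + g * rnorm(1, 0, 0.08)
    null <- fit_null_univariate(y, X)
    lp[i, 1] <- -log10(single_variant_wald(y, X, g)$p)
    lp[i, 2] <- -log10(skat_q(null, matrix(g, ncol = 1), 1)$p)
  }
  expect_gt(cor(lp[, 1], lp[, 2]), 0.99)
})

test_that("SKAT type-I error is nominal under the null", {
  set.seed(61)
  cfg <- sim_config(n_samples = 500, n_variants = 20, covariates = FALSE)
  G <- simulate_genotypes(cfg)$dosages
  X <- matrix(1, 500, 1)
  ps <- replicate(1000, skat_q(fit_null_univariate(rnorm(500), X), G, 1,
                               acc = 1e-7)$p)
  for (a in c(0.05, 0.01)) {
    rate <- mean(ps < a)
    band <- qnorm(0.995) * sqrt(a * (1 - a) / 1000)
    expect_lt(abs(rate - a), band + 1e-9)
  }
})
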