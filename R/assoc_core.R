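#' Tail probability of a weighted mixture of 1-df chi-squares
#'
#' Computes `P(sum_l lambda_l * Z_l^2 >= q)` for independent standard normal
#' `Z_l` — the null law of variance-component score statistics. The primary
#' method is Imhof's exact characteristic-function inversion (a
#' one-dimensional numerical integral); when the inversion fails or returns a
#' value outside (0, 1], the moment-matched noncentral-chi-square
#' approximation of Liu, Tang and Zhang is used instead. The method actually
#' used is recorded in the `"method"` attribute.
#'
#' @param lambda nonnegative eigenvalues; entries below
#'   `1e-10 * max(lambda)` are dropped as numerical zeros.
#' @param q observed statistic. `q < 0` returns 1.
#' @param acc target accuracy of the inversion integral (default `1e-9`).
#' @return p-value in (0, 1] with attribute `method` = `"imhof"` or `"liu"`.
#' @export
mixture_chisq_p <- function(lambda, q, acc = 1e-9) {
  lambda <- mixture_spec(lambda)
  if (length(lambda) == 0L) stop("need at least one positive eigenvalue")
  if (q <= 0) return(structure(1, method = "exact"))
  if (length(lambda) == 1L) {
    return(structure(
      max(stats::pchisq(q / lambda, df = 1, lower.tail = FALSE), 1e-300),
      method = "exact"))
  }
  # normalize scale so that (c * lambda, c * q) maps to the same computation
  s <- lambda[1]
  p <- tryCatch(imhof_p(lambda / s, q / s, acc), error = function(e) NA_real_)
  if (is.finite(p) && p > 0 && p <= 1) {
    return(structure(p, method = "imhof"))
  }
  structure(max(liu_p(lambda, q), 1e-300), method = "liu")
}

#' Canonical eigenvalue spec: sorted descending, numerical zeros dropped
#' @param lambda nonnegative numeric vector.
#' @param tol relative truncation tolerance.
#' @return sorted positive eigenvalues.
#' @export
mixture_spec <- function(lambda, tol = 1e-10) {
  lambda <- lambda[is.finite(lambda)]
  if (length(lambda) == 0L || max(lambda) <= 0) return(numeric(0))
  if (any(lambda < -tol * max(lambda)))
    stop("negative eigenvalue in mixture spec")
  lambda <- lambda[lambda > tol * max(lambda)]
  sort(lambda, decreasing = TRUE)
}

# Imhof/Gil-Pelaez inversion for central quadratic forms,
#   P(Q >= q) = 1/2 + (1/pi) * Int_0^inf sin(theta(u)) / (u * rho(u)) du,
#   theta(u) = (sum_l atan(lambda_l u) - q u) / 2,
#   rho(u)   = prod_l (1 + lambda_l^2 u^2)^(1/4),
# evaluated by the midpoint rule with step h = 4*pi / (q + x_acc), where
# x_acc is a Chernoff point with P(Q >= x_acc) <= acc/10 (periodization /
# aliasing error of the equal-step rule is a tail probability at that
# distance), truncated where the oscillation-aware envelope bound
# 2 * env(U) / (pi q) drops below acc/10.
imhof_p <- function(lambda, q, acc = 1e-9) {
  v <- length(lambda)
  c1 <- sum(lambda); c2 <- sum(lambda^2); lmax <- max(lambda)
  lmin <- min(lambda)
  log_chernoff <- function(x) {
    t <- c(0.2, 0.5, 0.8, 0.95, 0.999) / (2 * lmax)
    min(-t * x - 0.5 * colSums(log1p(-2 * outer(lambda, t))))
  }
  x <- c1 + 10 * sqrt(2 * c2)
  lacc <- log(acc / 10)
  while (log_chernoff(x) > lacc) x <- x * 1.4
  h <- 4 * pi / (q + x)
  log_env <- function(u) -log(u) - 0.25 * sum(log1p(lambda^2 * u^2))
  # tail error after truncating at U: the oscillation-aware alternating
  # bound 2*env(U)/(pi*q) once the phase is monotone, or the absolute
  # envelope integral ~ env(U)*U*2/(v*pi); either below acc/10 suffices
  phase_monotone <- function(u) sum(pmin(lambda, 1 / (lambda * u^2))) < 0.9 * q
  tail_ok <- function(u) {
    le <- log_env(u)
    (phase_monotone(u) && le + log(2 / (pi * q)) < lacc) ||
      (le + log(2 * u / (pi * max(v - 1, 1))) < lacc)
  }
  U <- 10 / lmax
  while (!tail_ok(U)) {
    U <- U * 1.5
    if (U > 1e15) break
  }
  n <- ceiling(U / h)
  if (n > 1e7) stop("inversion grid too large")
  total <- 0
  chunk <- max(1L, floor(4e6 / v))
  done <- 0
  while (done < n) {
    m <- min(chunk, n - done)
    u <- (done + seq_len(m) - 0.5) * h
    lu <- outer(lambda, u)
    theta <- 0.5 * (colSums(atan(lu)) - q * u)
    logrho <- 0.25 * colSums(log1p(lu * lu))
    total <- total + sum(sin(theta) * exp(-logrho) / u)
    done <- done + m
  }
  0.5 + h * total / pi
}

# Liu-Tang-Zhang moment-matched noncentral chi-square approximation
liu_p <- function(lambda, q) {
  c1 <- sum(lambda); c2 <- sum(lambda^2); c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / s1
    delta <- 0
    l <- 1 / s1^2
  }
  mu_x <- l + delta
  sigma_x <- sqrt(2) * a
  tstar <- (q - c1) / sqrt(2 * c2)
  stats::pchisq(tstar * sigma_x + mu_x, df = l, ncp = delta, lower.tail = FALSE)
}

#' Quantile of a mixture-of-chi-squares law
#'
#' Inverse of [mixture_chisq_p()] in its first argument: the `q` with
#' `P(Q >= q) = p`. Root-bracketing around a moment-matched initial guess.
#'
#' @param lambda eigenvalues (as for [mixture_chisq_p()]).
#' @param p upper-tail probability in (0, 1).
#' @param acc inversion accuracy used inside the root search.
#' @return the quantile q.
#' @export
mixture_chisq_quantile <- function(lambda, p, acc = 1e-7) {
  lambda <- mixture_spec(lambda)
  stopifnot(p > 0, p < 1)
  if (length(lambda) == 1L)
    return(lambda * stats::qchisq(p, df = 1, lower.tail = FALSE))
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  f <- function(q) mixture_chisq_p(lambda, q, acc) - p
  lo <- 0; hi <- c1 + 10 * sqrt(2 * c2)
  while (f(hi) > 0) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = 1e-6 * max(1, hi))$root
}

#' Fit the univariate null regression
#'
#' Ordinary least squares of one trait on the covariate design (with
#' intercept); the score test treats the genotype effect as a random effect
#' absent under the null, so the null fit is a fixed-effects regression.
#'
#' @param y numeric response vector (length N).
#' @param X N x (m+1) design matrix including the intercept column.
#' @return class `univariate_null`: coefficients, residuals `r` (satisfying
#'   `X'r = 0`), `sigma2 = r'r / (N - m - 1)`, the QR factorization of X, and
#'   `df` the residual degrees of freedom.
#' @export
fit_null_univariate <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  if (n != nrow(X)) stop("length(y) != nrow(X)")
  if (n <= ncol(X)) stop("need N > number of design columns")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    nm <- colnames(X)
    if (is.null(nm)) nm <- paste0("V", seq_len(ncol(X)))
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(nm[drop_cols], collapse = ", "))
  }
  coef <- qr.coef(qrX, y)
  r <- as.numeric(y - X %*% coef)
  df <- n - ncol(X)
  sigma2 <- sum(r^2) / df
  structure(list(coef = coef, residuals = r, sigma2 = sigma2, X = X,
                 qrX = qrX, df = df, yscale = mean(y^2)),
            class = "univariate_null")
}

# project out the design: P %*% B with P = I - X (X'X)^-1 X'
project_resid <- function(qrX, B) {
  B - qr.fitted(qrX, B)
}

#' Univariate variance-component (SKAT) region statistic
#'
#' Score-type test of the variance component `tau^2 = 0` in the mixed model
#' `y = X alpha + G beta + e`, `beta ~ N(0, tau^2 W)`:
#' `Q = r' G W G' r / sigma2`, with null law `sum_l lambda_l chi^2_1` where
#' the `lambda_l` are the eigenvalues of `W^{1/2} G' P G W^{1/2}` and
#' `P = I - X(X'X)^{-1}X'`.
#'
#' @param null a [fit_null_univariate()] fit.
#' @param G N x v dosage submatrix for the region.
#' @param w length-v weight vector (see [compute_weights()]); a scalar is
#'   recycled.
#' @param acc p-value inversion accuracy.
#' @return list with `Q`, `lambda` (the mixture spec), `p`, `method`
#'   (p-value method), `dropped` (indices of all-zero genotype columns
#'   removed). If every column is zero, `Q = 0`, `p = 1` and
#'   `note = "no polymorphic variants"`.
#' @export
skat_q <- function(null, G, w = 1, acc = 1e-9) {
  G <- as.matrix(G)
  yscale <- if (is.null(null$yscale)) 1 else max(null$yscale, .Machine$double.xmin)
  if (null$sigma2 <= 1e-16 * yscale)
    stop("null model has (numerically) zero residual variance")
  w <- rep_len(w, ncol(G))
  zero <- colSums(abs(G)) == 0
  note <- NULL
  if (any(zero)) {
    warning(sum(zero), " all-zero genotype column(s) dropped")
    G <- G[, !zero, drop = FALSE]
    w <- w[!zero]
  }
  if (ncol(G) == 0L) {
    return(list(Q = 0, lambda = numeric(0), p = 1, method = "degenerate",
                dropped = which(zero), note = "no polymorphic variants"))
  }
  B <- sweep(G, 2, sqrt(w), `*`)
  gr <- crossprod(B, null$residuals)            # sqrt(w_j) * g_j' r
  Q <- sum(gr^2) / null$sigma2
  PB <- project_resid(null$qrX, B)
  lambda <- mixture_spec(eigen(crossprod(PB), symmetric = TRUE,
                               only.values = TRUE)$values)
  if (length(lambda) == 0L) {
    return(list(Q = Q, lambda = lambda, p = 1, method = "degenerate",
                dropped = which(zero), note = "genotypes in design span"))
  }
  p <- mixture_chisq_p(lambda, Q, acc)
  list(Q = Q, lambda = lambda, p = as.numeric(p),
       method = attr(p, "method"), dropped = which(zero), note = note)
}

#' Minimum of per-trait univariate p-values
#'
#' The adjusted univariate summary for a region when K traits were tested
#' separately: the smallest of the K p-values (multiplicity is handled by the
#' significance threshold, not here).
#'
#' @param p numeric vector of per-trait p-values in (0, 1].
#' @return `min(p)`.
#' @export
adjusted_univariate_p <- function(p) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  min(p)
}

#' Single-variant Wald test
#'
#' Linear regression of the trait on the covariate design plus one variant's
#' dosage; returns the dosage coefficient and its Wald p-value.
#'
#' @param y trait vector.
#' @param X design matrix including intercept.
#' @param g dosage vector for one variant.
#' @return list with `beta`, `se`, `p`.
#' @export
single_variant_wald <- function(y, X, g) {
  if (stats::var(g) <= 0) stop("variant has zero variance")
  Xg <- cbind(X, g = g)
  qrX <- qr(Xg)
  if (qrX$rank < ncol(Xg)) stop("variant is collinear with the covariates")
  coef <- qr.coef(qrX, y)
  r <- y - Xg %*% coef
  df <- length(y) - ncol(Xg)
  s2 <- sum(r^2) / df
  XtXinv <- solve(crossprod(Xg))
  se <- sqrt(s2 * XtXinv[ncol(Xg), ncol(Xg)])
  tval <- coef[length(coef)] / se
  list(beta = unname(coef[length(coef)]), se = unname(se),
       p = unname(2 * stats::pt(abs(tval), df, lower.tail = FALSE)))
}
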