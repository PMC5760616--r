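#' Simulation configuration
#'
#' Describes one synthetic data set under the generative multivariate mixed
#' model: genotypes from a first-order Markov haplotype model with a chosen
#' MAF spectrum and adjacent-site LD; K correlated Gaussian traits with
#' trait-level residual correlation; variant effects drawn (once per data
#' set) from `N(0, tau^2 R_rho_sim (x) W_sim)` at the causal variants; and
#' age / age-squared / sex / weight covariate analogs with fixed
#' coefficients.
#'
#' Defaults emulate the bone-density study regime this package targets:
#' two traits with residual correlation 0.68 (the observed correlation of
#' log-transformed femoral-neck and lumbar-spine density), a rare-variant
#' MAF spectrum (0.005-0.05), and an elderly-cohort covariate mix.
#'
#' @param n_samples number of individuals N (default 500, the scale used for
#'   calibration studies).
#' @param n_variants number of variants v in the region (default 20).
#' @param maf either `c(lo, hi)` for a uniform MAF spectrum (hi <= 0.5) or a
#'   length-`n_variants` vector of fixed per-site MAFs.
#' @param ld adjacent-site haplotype correlation in \[0, 1).
#' @param K number of traits (default 2).
#' @param trait_cor residual correlation used to build `Sigma_sim` when
#'   `Sigma_sim` is not given (default 0.68).
#' @param Sigma_sim K x K residual covariance (default: unit variances,
#'   all off-diagonals `trait_cor`).
#' @param causal_idx indices of causal variants (default none: a null model).
#' @param tau effect-size scale, the square root of the variance component
#'   `tau^2` (default 0).
#' @param rho_sim common correlation of a causal variant's effects across
#'   traits (default 0.7).
#' @param w_sim per-variant effect-variance weights for the generator
#'   (default 1; decoupled from analysis weights so misspecification can be
#'   studied).
#' @param covariates logical; generate the covariate block (default TRUE).
#' @param seed integer seed.
#' @return class `sim_config` list.
#' @export
sim_config <- function(n_samples = 500L, n_variants = 20L,
                       maf = c(0.005, 0.05), ld = 0, K = 2L,
                       trait_cor = 0.68, Sigma_sim = NULL,
                       causal_idx = integer(0), tau = 0, rho_sim = 0.7,
                       w_sim = 1, covariates = TRUE, seed = NULL) {
  if (is.null(Sigma_sim)) {
    Sigma_sim <- (1 - trait_cor) * diag(K) + trait_cor * matrix(1, K, K)
  }
  Sigma_sim <- as.matrix(Sigma_sim)
  if (nrow(Sigma_sim) != K) stop("Sigma_sim must be K x K")
  if (min(eigen(Sigma_sim, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("Sigma_sim must be positive definite")
  maf_kind <- if (length(maf) == 2L && maf[1] < maf[2] && n_variants != 2L) {
    "uniform"
  } else if (length(maf) == n_variants) {
    "fixed"
  } else if (length(maf) == 2L && maf[1] < maf[2]) {
    "uniform"
  } else stop("maf must be c(lo, hi) or one value per variant")
  if (maf_kind == "uniform" && maf[2] > 0.5) stop("maf upper bound must be <= 0.5")
  if (maf_kind == "fixed" && any(maf <= 0 | maf > 0.5))
    stop("fixed MAFs must lie in (0, 0.5]")
  if (ld < 0 || ld >= 1) stop("ld must lie in [0, 1)")
  if (length(causal_idx) > 0 &&
      (min(causal_idx) < 1 || max(causal_idx) > n_variants))
    stop("causal indices out of range")
  if (rho_sim < 0 || rho_sim > 1) stop("rho_sim must lie in [0, 1]")
  structure(list(n_samples = as.integer(n_samples),
                 n_variants = as.integer(n_variants), maf = maf, ld = ld,
                 K = as.integer(K), Sigma_sim = Sigma_sim,
                 maf_kind = maf_kind,
                 causal_idx = as.integer(causal_idx), tau = tau,
                 rho_sim = rho_sim,
                 w_sim = rep_len(w_sim, n_variants),
                 covariates = covariates, seed = seed),
            class = "sim_config")
}

#' Simulate a genotype matrix
#'
#' 2N haplotypes from a first-order Markov chain on \{0, 1\}: site j has
#' marginal allele frequency `p_j` (drawn from the configured MAF spectrum)
#' and the transition is chosen so that adjacent sites have haplotype
#' correlation equal to the `ld` parameter (transition probabilities are
#' clamped to \[0, 1\], which can shave the realized correlation when
#' adjacent frequencies differ greatly). Genotypes are haplotype sums.
#'
#' @param cfg a [sim_config()].
#' @return a [genotype_matrix()]; positions are 1 kb apart on chromosome "1".
#' @export
simulate_genotypes <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  v <- cfg$n_variants
  nh <- 2L * cfg$n_samples
  p <- if (cfg$maf_kind == "fixed") cfg$maf
       else stats::runif(v, cfg$maf[1], cfg$maf[2])
  H <- matrix(0L, nh, v)
  H[, 1] <- stats::rbinom(nh, 1L, p[1])
  if (v > 1L) for (j in 2:v) {
    pj <- p[j] + cfg$ld * sqrt(p[j] * (1 - p[j]) / (p[j - 1] * (1 - p[j - 1]))) *
      (H[, j - 1] - p[j - 1])
    H[, j] <- stats::rbinom(nh, 1L, pmin(pmax(pj, 0), 1))
  }
  G <- H[seq(1, nh, by = 2), , drop = FALSE] + H[seq(2, nh, by = 2), , drop = FALSE]
  variants <- data.frame(chrom = "1", pos = 10000 + 1000 * (seq_len(v) - 1),
                         id = paste0("v", seq_len(v)),
                         stringsAsFactors = FALSE)
  genotype_matrix(G, variants,
                  samples = paste0("S", seq_len(cfg$n_samples)))
}

#' Simulate phenotypes, covariates and the true effect matrix
#'
#' Draws the causal effect matrix `beta` (v x K) from
#' `N(0, tau^2 R_rho_sim (x) W_sim)` restricted to the causal variants
#' (zero elsewhere), generates the covariate block (age, age^2, sex, weight
#' analogs) with fixed coefficients, and adds multivariate Gaussian noise
#' with covariance `Sigma_sim`:
#' `Y[, k] = X alpha_k + G beta[, k] + eps[, k]`.
#'
#' @param G a [genotype_matrix()] with `cfg$n_samples` samples.
#' @param cfg a [sim_config()]. `cfg$seed` is NOT re-applied here (so one
#'   seed set before [simulate_genotypes()] governs the whole data set);
#'   set a seed yourself for standalone phenotype draws.
#' @return list with `phenotypes` ([phenotype_matrix()]), `covariates`
#'   ([covariate_matrix()] or NULL), `beta` (v x K truth).
#' @export
simulate_phenotypes <- function(G, cfg) {
  N <- cfg$n_samples
  if (nrow(G$dosages) != N) stop("genotype sample count does not match config")
  K <- cfg$K
  v <- cfg$n_variants
  beta <- matrix(0, v, K)
  if (cfg$tau > 0 && length(cfg$causal_idx) > 0) {
    Rh <- sym_sqrt(exchangeable_R(K, cfg$rho_sim))
    for (j in cfg$causal_idx) {
      z <- stats::rnorm(K)
      beta[j, ] <- cfg$tau * sqrt(cfg$w_sim[j]) * as.numeric(Rh %*% z)
    }
  }
  covs <- NULL
  Xeff <- matrix(0, N, K)
  if (isTRUE(cfg$covariates)) {
    age <- stats::rnorm(N, 72, 5)
    sex <- stats::rbinom(N, 1, 0.5)
    weight <- stats::rnorm(N, 75, 12)
    cv <- cbind(age = age, age2 = age^2, sex = sex, weight = weight)
    covs <- covariate_matrix(cv, samples = G$samples)
    alpha <- c(0.02, -1e-4, 0.15, 0.004)      # fixed covariate coefficients
    Xeff <- matrix(rep(as.numeric(cv %*% alpha), K), N, K)
  }
  eps <- matrix(stats::rnorm(N * K), N, K) %*% chol(cfg$Sigma_sim)
  Y <- Xeff + G$dosages %*% beta + eps
  colnames(Y) <- if (K == 2) c("FN", "LS") else paste0("trait", seq_len(K))
  list(phenotypes = phenotype_matrix(Y, samples = G$samples),
       covariates = covs, beta = beta)
}

#' Simulate a complete data set (genotypes + phenotypes + covariates)
#'
#' @param cfg a [sim_config()]; its seed (if any) makes the whole data set
#'   reproducible.
#' @return list with `genotypes`, `phenotypes`, `covariates`, `beta`.
#' @export
simulate_dataset <- function(cfg) {
  G <- simulate_genotypes(cfg)
  c(list(genotypes = G), simulate_phenotypes(G, cfg))
}
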