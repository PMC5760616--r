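#' Bonferroni significance threshold for a multi-weight, multi-trait scan
#'
#' `alpha / (n_weights * n_phenotype_tests * n_regions)`. For a genome scan
#' of 24,333 gene pieces with 3 weight schemes and 2 separately tested
#' traits at alpha = 0.05 this is 3.42e-7.
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param n_weights number of weighting schemes scanned.
#' @param n_phenotype_tests number of separate phenotype tests (e.g. 2 for
#'   two traits tested univariately; 1 for a joint multivariate test).
#' @param n_regions number of regions.
#' @return the per-test threshold.
#' @export
bonferroni_threshold <- function(alpha, n_weights, n_phenotype_tests, n_regions) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  counts <- c(n_weights, n_phenotype_tests, n_regions)
  if (any(counts < 1)) stop("test counts must be >= 1")
  alpha / (n_weights * n_phenotype_tests * n_regions)
}

#' Minimum p-value per permutation of the genotype-phenotype link
#'
#' For each permutation, the sample order of the genotype matrix is shuffled
#' (phenotypes and covariates stay aligned to each other, so
#' genotype-derived covariates keep their meaning with respect to the
#' phenotype model), the full scan over regions x weight schemes is
#' recomputed with the chosen test, and the minimum p-value is recorded.
#' The null regression is fitted once and re-used: permutation only changes
#' the genotypes.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotypes a [phenotype_matrix()].
#' @param covariates a [covariate_matrix()] or NULL.
#' @param regions list of [region()] objects with variants assigned.
#' @param weight_schemes list (or character vector) of weight schemes.
#' @param test `"skat"` (minimum over traits and regions) or `"murat"`
#'   (omnibus p per region).
#' @param n_perm number of permutations (>= 20).
#' @param seed integer seed.
#' @param grid,mc_draws omnibus controls when `test = "murat"`.
#' @return class `permutation_run`: `min_p` (length `n_perm`), `n_perm`,
#'   `seed`, `n_tests` (regions x weights x phenotype tests in scope), and
#'   the scope description.
#' @export
permute_min_p <- function(genotypes, phenotypes, covariates, regions,
                          weight_schemes = list("identical"),
                          test = c("skat", "murat"), n_perm = 100L,
                          seed = 1L, grid = rho_grid(), mc_draws = 10000L) {
  test <- match.arg(test)
  if (n_perm < 20L) stop("need at least 20 permutations")
  schemes <- lapply(weight_schemes, parse_weight_scheme)
  keep <- Filter(function(r) length(r$variant_idx) > 0, regions)
  if (length(keep) == 0L || length(schemes) == 0L) stop("empty permutation scope")
  X <- design_matrix(covariates, nrow(phenotypes$values))
  Y <- phenotypes$values
  K <- ncol(Y)
  null_uni <- if (test == "skat")
    lapply(seq_len(K), function(k) fit_null_univariate(Y[, k], X))
  null_multi <- if (test == "murat") fit_null_multivariate(Y, X)
  # per region x scheme weights are permutation-invariant
  wlist <- lapply(keep, function(r) {
    maf <- genotypes$variants$maf[r$variant_idx]
    lapply(schemes, function(s) {
      ok <- maf > 0
      list(ok = ok, w = if (any(ok)) compute_weights(maf[ok], s) else numeric(0))
    })
  })
  set.seed(seed)
  N <- nrow(genotypes$dosages)
  min_p <- vapply(seq_len(n_perm), function(b) {
    perm <- sample.int(N)
    Gp <- genotypes$dosages[perm, , drop = FALSE]
    pmin_b <- 1
    for (i in seq_along(keep)) {
      idx <- keep[[i]]$variant_idx
      for (s in seq_along(schemes)) {
        ws <- wlist[[i]][[s]]
        if (!any(ws$ok)) next
        Gsub <- Gp[, idx[ws$ok], drop = FALSE]
        ps <- if (test == "skat") {
          vapply(null_uni, function(nm)
            suppressWarnings(skat_q(nm, Gsub, ws$w)$p), 0)
        } else {
          suppressWarnings(
            murat_omnibus(null_multi, Gsub, ws$w, grid = grid,
                          mc_draws = mc_draws)$p_omnibus)
        }
        pmin_b <- min(pmin_b, ps)
      }
    }
    pmin_b
  }, 0)
  n_tests <- length(keep) * length(schemes) * if (test == "skat") K else 1L
  structure(list(min_p = min_p, n_perm = n_perm, seed = seed,
                 n_tests = n_tests,
                 scope = sprintf("%d regions x %d weights, test=%s",
                                 length(keep), length(schemes), test)),
            class = "permutation_run")
}

#' Effective number of tests and extrapolated significance threshold
#'
#' Models the per-scan minimum p-value as Beta(1, M_eff) — exact when the
#' M_eff tests are independent with uniform p-values — and estimates M_eff
#' by maximum likelihood, `M_eff = -n / sum(log(1 - p_min))`. The
#' genome-wide threshold controlling family-wise error at `alpha` is then
#' `1 - (1 - alpha)^(1 / M_eff)`. When the estimate implies a threshold
#' below the Bonferroni threshold for the same scope (correlation between
#' tests can only reduce the effective number), a warning is raised and the
#' Bonferroni value is reported alongside so the caller can prefer it.
#'
#' @param run a [permute_min_p()] result (or a list with `min_p` and
#'   optionally `n_tests`).
#' @param alpha target family-wise error rate (default 0.05).
#' @return list with `m_eff`, `threshold`, `bonferroni` (NA when the scope
#'   size is unknown).
#' @export
extrapolate_threshold <- function(run, alpha = 0.05) {
  p <- run$min_p
  if (length(p) == 0L) stop("empty permutation run")
  if (length(unique(p)) == 1L) stop("all permutation minima identical; cannot fit")
  if (any(p <= 0 | p > 1)) stop("min p-values must lie in (0, 1]")
  m_eff <- -length(p) / sum(log1p(-pmin(p, 1 - 1e-16)))
  threshold <- 1 - (1 - alpha)^(1 / m_eff)
  bonf <- if (!is.null(run$n_tests)) alpha / run$n_tests else NA_real_
  if (is.finite(bonf) && threshold < bonf) {
    warning(sprintf(paste0(
      "extrapolated threshold (%.3g) is below the Bonferroni threshold ",
      "(%.3g) for the same scope; correlation can only make tests fewer, ",
      "so prefer the Bonferroni value"), threshold, bonf))
  }
  list(m_eff = m_eff, threshold = threshold, bonferroni = bonf)
}
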