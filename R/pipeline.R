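#' Build a design matrix (intercept + covariates)
#'
#' @param covariates a [covariate_matrix()], a plain numeric matrix, or NULL
#'   (intercept-only design).
#' @param n number of samples (used when `covariates` is NULL).
#' @return N x (m+1) matrix whose first column is the intercept.
#' @export
design_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  vals <- if (inherits(covariates, "covariate_matrix")) covariates$values
          else as.matrix(covariates)
  cbind(intercept = 1, vals)
}

#' Log-transform (and optionally within-study standardize) phenotypes
#'
#' Applies a natural-log transform to every trait (all values must be
#' positive), then — when study labels are supplied and standardization is
#' requested — z-standardizes each trait within each source study before the
#' studies are analyzed jointly.
#'
#' @param raw a [phenotype_matrix()] with positive values.
#' @param study_labels optional length-N vector of study identifiers.
#' @param standardize within-study z-standardization flag (default: on when
#'   `study_labels` is given).
#' @return a [phenotype_matrix()] with `log_applied = TRUE`.
#' @export
preprocess_phenotypes <- function(raw, study_labels = NULL,
                                  standardize = !is.null(study_labels)) {
  vals <- raw$values
  if (any(vals <= 0)) {
    bad <- which(vals <= 0, arr.ind = TRUE)[1, ]
    id <- if (!is.null(raw$samples)) raw$samples[bad[1]] else bad[1]
    stop("nonpositive phenotype value for sample ", id,
         " (trait ", raw$trait_names[bad[2]], "); cannot log-transform")
  }
  vals <- log(vals)
  if (standardize) {
    if (is.null(study_labels)) stop("standardize requires study labels")
    for (s in unique(study_labels)) {
      rows <- study_labels == s
      vals[rows, ] <- scale(vals[rows, , drop = FALSE])
    }
  }
  phenotype_matrix(vals, trait_names = raw$trait_names,
                   log_applied = rep(TRUE, ncol(vals)), samples = raw$samples)
}

#' Genotype principal components for population-structure adjustment
#'
#' Restricts to near-common variants (MAF above `maf_min`), greedily prunes
#' them for pairwise LD (a variant is kept only if its squared correlation
#' with every already-kept variant stays at or below `ld_r2_max`),
#' standardizes the surviving dosages, and returns the top principal
#' components with the per-component variance fractions (for a scree plot).
#'
#' @param genotypes a [genotype_matrix()].
#' @param maf_min lower MAF bound for eligible variants (default 0.48).
#' @param ld_r2_max pairwise r^2 ceiling for LD pruning (default 0.1).
#' @param n_pcs number of components (default 5; 0 returns an empty matrix).
#' @return list with `pcs` (N x n_pcs), `var_frac` (variance fractions over
#'   all components of the pruned set), `n_used` (variants entering the PCA).
#' @export
compute_pcs <- function(genotypes, maf_min = 0.48, ld_r2_max = 0.1, n_pcs = 5L) {
  N <- nrow(genotypes$dosages)
  if (n_pcs == 0L) {
    return(list(pcs = matrix(0, N, 0), var_frac = numeric(0), n_used = 0L))
  }
  elig <- which(genotypes$variants$maf > maf_min &
                  apply(genotypes$dosages, 2, stats::var) > 0)
  if (length(elig) < n_pcs) {
    stop("only ", length(elig), " eligible variant(s) for ", n_pcs, " PCs")
  }
  kept <- integer(0)
  for (j in elig) {
    if (length(kept) == 0L) { kept <- j; next }
    r2 <- stats::cor(genotypes$dosages[, j], genotypes$dosages[, kept])^2
    if (max(r2) <= ld_r2_max) kept <- c(kept, j)
  }
  if (length(kept) < n_pcs) {
    stop("only ", length(kept), " variant(s) survive LD pruning for ",
         n_pcs, " PCs")
  }
  Z <- scale(genotypes$dosages[, kept, drop = FALSE])
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  list(pcs = pc$x[, seq_len(k), drop = FALSE],
       var_frac = pc$sdev^2 / sum(pc$sdev^2),
       n_used = length(kept))
}

#' Region-based association scan
#'
#' Evaluates every region x weight scheme with the requested tests
#' (univariate per-trait SKAT and/or the multivariate omnibus), producing
#' the canonical results table plus a QQ summary of each p-value column.
#' Regions with no usable variants yield rows with NA p-values and a reason.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotypes a [phenotype_matrix()].
#' @param covariates a [covariate_matrix()] or NULL.
#' @param regions list of [region()] objects with variants assigned.
#' @param weight_schemes list or character vector of schemes
#'   (default the three study schemes: identical, beta:1,25, beta:0.5,0.5).
#' @param tests subset of `c("murat", "skat")`.
#' @param grid rho grid for the omnibus.
#' @param mc_draws omnibus Monte-Carlo draws.
#' @param seed integer seed (governs omnibus draws; the scan itself is
#'   deterministic given it).
#' @param out_prefix optional path prefix; writes `<prefix>_results.tsv` and
#'   `<prefix>_qq.tsv`.
#' @return list with `results` (data.frame), `qq` (data.frame), `records`
#'   (raw per-region records), `log` (scan counts).
#' @export
run_scan <- function(genotypes, phenotypes, covariates, regions,
                     weight_schemes = c("identical", "beta:1,25", "beta:0.5,0.5"),
                     tests = c("murat", "skat"), grid = rho_grid(),
                     mc_draws = 10000L, seed = 1L, out_prefix = NULL) {
  schemes <- lapply(weight_schemes, parse_weight_scheme)
  X <- design_matrix(covariates, nrow(phenotypes$values))
  Y <- phenotypes$values
  K <- ncol(Y)
  null_uni <- if ("skat" %in% tests)
    lapply(seq_len(K), function(k) fit_null_univariate(Y[, k], X))
  null_multi <- if ("murat" %in% tests) fit_null_multivariate(Y, X)
  if (!is.null(seed)) set.seed(seed)
  records <- list()
  for (r in regions) {
    for (s in schemes) {
      records[[length(records) + 1L]] <- suppressWarnings(
        murat_region_test(genotypes, r, phenotypes, X, scheme = s,
                          grid = grid, mc_draws = mc_draws, seed = NULL,
                          tests = tests, null_uni = null_uni,
                          null_multi = null_multi))
    }
  }
  df <- results_to_df(records)
  pcols <- grep("^p_", names(df), value = TRUE)
  qq <- do.call(rbind, lapply(pcols, function(cc) {
    qq_summary(df[[cc]], label = cc)
  }))
  log <- list(n_regions = length(regions), n_weights = length(schemes),
              n_rows = nrow(df),
              n_na = sum(is.na(df$p_murat) & is.na(df$p_adj_univariate)),
              variants_per_region = vapply(regions, function(r)
                length(r$variant_idx), 0L))
  if (!is.null(out_prefix)) {
    write_results(records, paste0(out_prefix, "_results.tsv"))
    utils::write.table(qq, paste0(out_prefix, "_qq.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(results = df, qq = qq, records = records, log = log)
}

#' Load a YAML scan/simulation configuration
#'
#' The config file is the single source of truth for a command-line run; the
#' CLI wrappers let flags override individual entries and write the
#' effective config beside the outputs.
#'
#' @param path YAML file.
#' @param overrides named list of values taking precedence over the file.
#' @return named list.
#' @export
read_config <- function(path, overrides = list()) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  for (nm in names(overrides)) {
    if (!is.null(overrides[[nm]])) cfg[[nm]] <- overrides[[nm]]
  }
  cfg
}

#' Write the effective configuration beside the outputs
#' @param cfg named list.
#' @param path output YAML path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' QQ summary of a p-value vector
#'
#' Sorted observed `-log10 p` against expected uniform quantiles
#' `-log10((i - 0.5) / n)`, plus the genomic-inflation-style lambda
#' (median observed chi-square quantile over the median expected one).
#'
#' @param p p-value vector (NAs dropped).
#' @param label optional column label recorded in the output.
#' @return data.frame with columns `label`, `expected`, `observed`; the
#'   `lambda` attribute carries the inflation factor.
#' @export
qq_summary <- function(p, label = "p") {
  p <- p[!is.na(p)]
  n <- length(p)
  if (n == 0L) {
    return(structure(data.frame(label = character(0), expected = numeric(0),
                                observed = numeric(0)), lambda = NA_real_))
  }
  obs <- sort(p)
  lambda <- stats::median(stats::qchisq(obs, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1, lower.tail = FALSE)
  structure(data.frame(label = label,
                       expected = -log10((seq_len(n) - 0.5) / n),
                       observed = -log10(obs),
                       stringsAsFactors = FALSE),
            lambda = lambda)
}
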