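#' Genotype matrix with per-variant metadata
#'
#' Container for an N x v matrix of minor-allele dosages together with the
#' variant map (chromosome, 1-based position, identifier, minor allele
#' frequency). Dosages lie in \[0, 2\]: hard genotypes are 0/1/2 copies of the
#' minor allele, imputed dosages are fractional. Variants are kept sorted by
#' (chrom, pos); sample order is the reference order for every other matrix
#' in an analysis.
#'
#' @param dosages numeric N x v matrix, entries in \[0, 2\]. Missing entries
#'   (`NA`) are mean-imputed to `2 * maf` and flagged in the returned object.
#' @param variants data.frame with columns `chrom`, `pos`, `id` and optionally
#'   `maf`. If `maf` is absent it is computed as `mean(dosage) / 2` and folded
#'   to the minor allele (dosage re-oriented as `2 - dosage` when the coded
#'   allele frequency exceeds 0.5); re-orientations are recorded in the
#'   `flipped` column.
#' @param samples character vector of sample identifiers (defaults to the
#'   rownames of `dosages`).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants` (with columns `chrom`, `pos`, `id`, `maf`,
#'   `flipped`), `samples`, and `n_imputed` (count of mean-imputed entries).
#' @export
genotype_matrix <- function(dosages, variants, samples = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosages)))
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(ncol(dosages) == nrow(variants))
  if (is.null(variants$id)) variants$id <- paste0(variants$chrom, ":", variants$pos)
  if (anyDuplicated(samples)) stop("duplicate sample ids in genotype matrix")

  maf_given <- !is.null(variants$maf) && !all(is.na(variants$maf))

  # impute missing dosages to 2 * coded-allele frequency (mean imputation)
  n_imputed <- sum(is.na(dosages))
  if (n_imputed > 0L) {
    for (j in which(colSums(is.na(dosages)) > 0L)) {
      mu <- mean(dosages[, j], na.rm = TRUE)
      if (is.nan(mu)) mu <- 0
      dosages[is.na(dosages[, j]), j] <- mu
    }
  }
  if (any(dosages < -1e-8 | dosages > 2 + 1e-8))
    stop("dosages must lie in [0, 2]")
  dosages[dosages < 0] <- 0
  dosages[dosages > 2] <- 2

  # fold to minor allele: coded-allele frequency > 0.5 => flip orientation
  af <- colMeans(dosages) / 2
  flipped <- af > 0.5
  if (any(flipped)) {
    dosages[, flipped] <- 2 - dosages[, flipped]
    af[flipped] <- 1 - af[flipped]
  }
  variants$flipped <- unname(flipped)
  if (!maf_given) {
    variants$maf <- unname(af)
  } else if (any(variants$maf > 0.5 + 1e-12, na.rm = TRUE)) {
    stop("supplied maf column must be folded (<= 0.5)")
  }

  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  dosages <- dosages[, ord, drop = FALSE]
  rownames(variants) <- NULL
  dimnames(dosages) <- list(samples, variants$id)

  structure(
    list(dosages = dosages, variants = variants, samples = samples,
         n_imputed = n_imputed),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%d entries imputed)\n",
              nrow(x$dosages), ncol(x$dosages), x$n_imputed))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Phenotype matrix (N samples x K continuous traits)
#'
#' @param values numeric N x K matrix (or data.frame) of trait values; must be
#'   complete and finite.
#' @param trait_names length-K character vector (defaults to column names).
#' @param log_applied logical, per trait, whether a log transform has been
#'   applied (bookkeeping for [preprocess_phenotypes()]).
#' @param samples optional sample identifiers.
#' @return An object of class `phenotype_matrix`.
#' @export
phenotype_matrix <- function(values, trait_names = colnames(values),
                             log_applied = rep(FALSE, ncol(values)),
                             samples = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 1L) stop("need at least one trait")
  if (any(!is.finite(values))) stop("phenotype matrix must be complete and finite")
  if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(ncol(values)))
  colnames(values) <- trait_names
  if (!is.null(samples)) rownames(values) <- samples
  structure(
    list(values = values, trait_names = trait_names,
         log_applied = rep_len(log_applied, ncol(values)), samples = samples),
    class = "phenotype_matrix"
  )
}

#' Covariate matrix (N samples x m covariates)
#'
#' The intercept is not stored; design matrices are built downstream by
#' prepending a column of ones. Full column rank (with intercept) is enforced.
#'
#' @param values numeric N x m matrix; complete, finite.
#' @param names length-m character vector of covariate names.
#' @param samples optional sample identifiers.
#' @return An object of class `covariate_matrix`.
#' @export
covariate_matrix <- function(values, names = colnames(values),
                             samples = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values))) stop("covariate matrix must be complete and finite")
  if (is.null(names)) names <- paste0("x", seq_len(ncol(values)))
  colnames(values) <- names
  X <- cbind(1, values)
  if (qr(X)$rank < ncol(X)) {
    stop("covariates are collinear (with intercept); inspect columns: ",
         paste(names, collapse = ", "))
  }
  structure(list(values = values, names = names, samples = samples),
            class = "covariate_matrix")
}

#' Genomic region with its ordered variant subset
#'
#' A region is an interval on one chromosome (1-based, inclusive) plus the
#' ordered indices of the variants of a [genotype_matrix()] that fall in it.
#' Regions come in three granularities: gene pieces
#' ([make_gene_pieces()]), at-most-30-variant windows ([make_windows()]), and
#' single variants ([single_variant_regions()]).
#'
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive interval bounds, `start <= end`.
#' @param label region label (typically the gene name).
#' @param piece_index integer >= 0; position of this piece along its gene.
#' @param variant_idx strictly increasing integer indices into a genotype
#'   matrix (may be empty).
#' @return An object of class `region`.
#' @export
region <- function(chrom, start, end, label = NA_character_, piece_index = 0L,
                   variant_idx = integer(0)) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (end < start) stop(sprintf("region %s: end (%s) < start (%s)", label, end, start))
  variant_idx <- as.integer(variant_idx)
  if (length(variant_idx) > 1L && any(diff(variant_idx) <= 0L))
    stop("variant indices must be strictly increasing")
  structure(
    list(chrom = as.character(chrom), start = start, end = end,
         label = as.character(label), piece_index = as.integer(piece_index),
         variant_idx = variant_idx),
    class = "region"
  )
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("region %s:%s-%s [%s piece %d] %d variants\n", x$chrom,
              format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE),
              x$label, x$piece_index, length(x$variant_idx)))
  invisible(x)
}

#' Attach the variants of a genotype matrix to regions
#'
#' Fills each region's `variant_idx` with the (sorted) indices of the variants
#' lying inside its interval on the same chromosome.
#'
#' @param regions list of [region()] objects.
#' @param genotypes a [genotype_matrix()].
#' @return The regions, with `variant_idx` populated.
#' @export
assign_variants <- function(regions, genotypes) {
  v <- genotypes$variants
  lapply(regions, function(r) {
    idx <- which(v$chrom == r$chrom & v$pos >= r$start & v$pos <= r$end)
    r$variant_idx <- as.integer(sort(idx))
    r
  })
}

# align a named data matrix to the genotype sample order; used by readers
align_to_samples <- function(values, row_ids, samples) {
  pos <- match(samples, row_ids)
  if (anyNA(pos)) {
    stop("samples missing from table: ",
         paste(utils::head(samples[is.na(pos)], 5), collapse = ", "))
  }
  values[pos, , drop = FALSE]
}
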