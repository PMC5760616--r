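#' Build gene pieces from gene intervals
#'
#' Each gene interval is extended by `flank_bp` on both ends (floored at
#' position 1). Flanked genes no longer than `split_threshold_bp` become one
#' region; longer genes are partitioned into `ceiling(L / piece_max_bp)`
#' contiguous non-overlapping pieces of near-equal length, which keeps every
#' piece within `[piece_min_bp, piece_max_bp]` for any flanked length above
#' the split threshold. Piece indices increment along the gene: 0 for an
#' unsplit gene, 1..n for the pieces of a split gene.
#'
#' @param gene_intervals data.frame with columns `chrom`, `start`, `end`,
#'   `name` (1-based inclusive; see [read_gene_intervals()]).
#' @param flank_bp flank added to each end (default 5000).
#' @param split_threshold_bp flanked genes longer than this are split
#'   (default 150000).
#' @param piece_min_bp,piece_max_bp piece length bounds (defaults 50000 and
#'   100000).
#' @param genotypes optional [genotype_matrix()]; if given, each piece's
#'   variant indices are populated.
#' @return list of [region()] objects.
#' @export
make_gene_pieces <- function(gene_intervals, flank_bp = 5000,
                             split_threshold_bp = 150000,
                             piece_min_bp = 50000, piece_max_bp = 100000,
                             genotypes = NULL) {
  if (any(gene_intervals$end < gene_intervals$start)) {
    bad <- which(gene_intervals$end < gene_intervals$start)[1]
    stop("gene with end < start: ", gene_intervals$name[bad])
  }
  out <- list()
  for (i in seq_len(nrow(gene_intervals))) {
    g <- gene_intervals[i, ]
    s <- max(1, g$start - flank_bp)
    e <- g$end + flank_bp
    L <- e - s + 1
    if (L <= split_threshold_bp) {
      out[[length(out) + 1L]] <- region(g$chrom, s, e, g$name, 0L)
    } else {
      n <- ceiling(L / piece_max_bp)
      base <- L %/% n
      rem <- L %% n
      sizes <- rep(base, n)
      if (rem > 0) sizes[seq_len(rem)] <- base + 1
      starts <- s + cumsum(c(0, sizes[-n]))
      for (k in seq_len(n)) {
        out[[length(out) + 1L]] <-
          region(g$chrom, starts[k], starts[k] + sizes[k] - 1, g$name, k)
      }
    }
  }
  if (!is.null(genotypes)) out <- assign_variants(out, genotypes)
  out
}

#' Split a region into windows of at most `max_variants` variants
#'
#' The region's ordered variant list is chunked into
#' `ceiling(v / max_variants)` consecutive non-overlapping windows with sizes
#' as equal as possible (differing by at most 1); their union is exactly the
#' region's variant list. Window bounds are set to the first/last variant
#' position in the window.
#'
#' @param region a [region()] with variants assigned.
#' @param genotypes the [genotype_matrix()] the indices refer to.
#' @param max_variants maximum variants per window (default 30).
#' @return list of [region()] windows (empty list for an empty region).
#' @export
make_windows <- function(region, genotypes, max_variants = 30L) {
  idx <- region$variant_idx
  v <- length(idx)
  if (v == 0L) return(list())
  n <- ceiling(v / max_variants)
  base <- v %/% n
  rem <- v %% n
  sizes <- rep(base, n)
  if (rem > 0) sizes[seq_len(rem)] <- base + 1
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  pos <- genotypes$variants$pos
  lapply(seq_len(n), function(k) {
    sub <- idx[starts[k]:ends[k]]
    region(region$chrom, pos[sub[1]], pos[sub[length(sub)]],
           region$label, k, sub)
  })
}

#' One region per variant carried by enough individuals
#'
#' A variant is retained when the minor allele is carried by at least
#' `min_carriers` individuals; a carrier is a sample with dosage > 0.5
#' (equivalently >= 1 minor allele for hard genotypes).
#'
#' @param genotypes a [genotype_matrix()].
#' @param min_carriers minimum carrier count (default 4; variants carried by
#'   fewer individuals are removed).
#' @return list of single-variant [region()] objects.
#' @export
single_variant_regions <- function(genotypes, min_carriers = 4L) {
  carriers <- colSums(genotypes$dosages > 0.5)
  keep <- which(carriers >= min_carriers)
  v <- genotypes$variants
  lapply(keep, function(j) {
    region(v$chrom[j], v$pos[j], v$pos[j], v$id[j], 0L, j)
  })
}

#' Restrict regions to rare variants
#'
#' Variants with MAF at or above `maf_cutoff` are dropped from each region's
#' variant list (rare means strictly below the cutoff). The MAF source is
#' either the sample MAF carried by the genotype matrix or an external
#' per-variant MAF vector (e.g. frequencies estimated in a larger reference
#' set).
#'
#' @param genotypes a [genotype_matrix()].
#' @param regions list of [region()] objects with variants assigned.
#' @param maf_cutoff rare-variant threshold (default 0.05).
#' @param maf_source `"sample"` or `"external"`.
#' @param external_maf numeric vector, length = number of variants in
#'   `genotypes`, required when `maf_source = "external"`.
#' @return the regions with variant lists restricted; regions left empty are
#'   kept (with zero variants) and reported via a message.
#' @export
filter_rare <- function(genotypes, regions, maf_cutoff = 0.05,
                        maf_source = c("sample", "external"),
                        external_maf = NULL) {
  maf_source <- match.arg(maf_source)
  maf <- if (maf_source == "sample") {
    genotypes$variants$maf
  } else {
    if (is.null(external_maf)) stop("external MAF source requested but none supplied")
    if (length(external_maf) != nrow(genotypes$variants))
      stop("external_maf length must match variant count")
    external_maf
  }
  out <- lapply(regions, function(r) {
    r$variant_idx <- r$variant_idx[maf[r$variant_idx] < maf_cutoff]
    r
  })
  emptied <- sum(vapply(out, function(r) length(r$variant_idx) == 0L, TRUE) &
                   !vapply(regions, function(r) length(r$variant_idx) == 0L, TRUE))
  if (emptied > 0)
    message(emptied, " region(s) left with 0 variants by the rare-variant filter")
  out
}
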