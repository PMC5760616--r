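#' Read a genotype matrix from VCF or a plain dosage table
#'
#' VCF input (v4.x) uses the `DS` FORMAT field verbatim when present,
#' otherwise `GT` converted to 0/1/2 minor-allele counts. Multi-allelic sites
#' are rejected. A plain-table dialect is also accepted: a TSV with one row
#' per sample, a `sample` id column, and one column per variant named
#' `chrom:pos` or `chrom:pos:id`.
#'
#' @param path VCF (`.vcf`, optionally `.gz`) or TSV dosage table.
#' @param region_filter optional [region()]; only variants inside it are kept.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, region_filter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  is_vcf <- grepl("\\.vcf(\\.gz)?$", path)
  gm <- if (is_vcf) read_genotypes_vcf(path) else read_genotypes_table(path)
  if (!is.null(region_filter)) {
    keep <- with(gm$variants, chrom == region_filter$chrom &
                   pos >= region_filter$start & pos <= region_filter$end)
    gm <- genotype_matrix(gm$dosages[, keep, drop = FALSE],
                          gm$variants[keep, c("chrom", "pos", "id", "maf")],
                          gm$samples)
  }
  gm
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(vcf@gt) == 0L) stop("VCF has no variant records: ", path)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    stop("multi-allelic site(s) not supported, e.g. record ",
         which(multi)[1], " (", fix[which(multi)[1], "CHROM"], ":",
         fix[which(multi)[1], "POS"], "); decompose upstream")
  }
  fmt <- vcf@gt[, 1]
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    if (is.null(gt)) stop("VCF has neither DS nor GT fields: ", path)
    bad <- !is.na(gt) & !grepl("^[01.]([/|][01.])?$", gt)
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf("malformed GT '%s' at record %d sample %d",
                   gt[bad][1], w[1], w[2]))
    }
    ds <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    ds[gt %in% c("0/0", "0|0", "0")] <- 0
    ds[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
    ds[gt %in% c("1/1", "1|1", "1")] <- 2
  }
  variants <- data.frame(
    chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"]),
    stringsAsFactors = FALSE
  )
  genotype_matrix(t(ds), variants, samples = colnames(ds))
}

read_genotypes_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  idc <- which(tolower(names(tab)) %in% c("sample", "sample_id", "iid", "id"))[1]
  if (is.na(idc)) stop("dosage table needs a sample id column: ", path)
  samples <- as.character(tab[[idc]])
  mat <- as.matrix(tab[, -idc, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(tab[, -idc, drop = FALSE], is.numeric, TRUE))[1]
    stop("non-numeric dosage column: ", names(tab[, -idc, drop = FALSE])[bad])
  }
  parts <- strsplit(colnames(mat), ":", fixed = TRUE)
  variants <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    pos = suppressWarnings(as.numeric(vapply(parts, `[`, "", 2))),
    id = vapply(parts, function(p) if (length(p) >= 3) p[3] else paste(p[1:2], collapse = ":"), ""),
    stringsAsFactors = FALSE
  )
  if (anyNA(variants$pos)) {
    stop("dosage-table variant columns must be named chrom:pos or chrom:pos:id")
  }
  genotype_matrix(mat, variants, samples = samples)
}

#' Read a phenotype or covariate table
#'
#' Whitespace/TSV table with a header row, one row per sample and a sample id
#' column. Rows with any missing value are dropped (complete-case) and
#' reported via a message. If `samples` is given, rows are re-aligned to that
#' order and all requested samples must be present after the complete-case
#' drop.
#'
#' @param path table path.
#' @param samples optional character vector giving the reference sample order
#'   (normally `genotypes$samples`).
#' @param as one of `"phenotype"` or `"covariate"`.
#' @return A [phenotype_matrix()] or [covariate_matrix()].
#' @export
read_table <- function(path, samples = NULL, as = c("phenotype", "covariate")) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  idc <- which(tolower(names(tab)) %in% c("sample", "sample_id", "iid", "id"))[1]
  if (is.na(idc)) stop("table needs a sample id column: ", path)
  ids <- as.character(tab[[idc]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample id in ", path, ": ", ids[duplicated(ids)][1])
  }
  vals <- tab[, -idc, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]]) && !all(is.na(vals[[j]]))) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) & !is.na(vals[[j]]))[1]
      stop(sprintf("non-numeric value in column '%s', row %d of %s",
                   names(vals)[j], bad, path))
    }
  }
  keep <- stats::complete.cases(vals)
  if (any(!keep)) {
    message(sum(!keep), " row(s) with missing values dropped from ", path, ": ",
            paste(utils::head(ids[!keep], 5), collapse = ", "))
  }
  vals <- as.matrix(vals[keep, , drop = FALSE])
  ids <- ids[keep]
  if (!is.null(samples)) {
    vals <- align_to_samples(vals, ids, samples)
    ids <- samples
  }
  rownames(vals) <- ids
  if (as == "phenotype") phenotype_matrix(vals, samples = ids)
  else covariate_matrix(vals, samples = ids)
}

#' Read gene intervals (TSV or BED)
#'
#' A 4-column table `chrom start end name`. Files ending in `.bed` are taken
#' as 0-based half-open and converted to the 1-based inclusive convention
#' used throughout; other files are assumed already 1-based inclusive.
#'
#' @param path interval file.
#' @return data.frame with columns `chrom`, `start`, `end`, `name` (1-based
#'   inclusive).
#' @export
read_gene_intervals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name"),
                           colClasses = c("character", "numeric", "numeric", "character"))
  first <- utils::read.table(path, header = FALSE, nrows = 1,
                             stringsAsFactors = FALSE)
  if (is.character(first[[2]])) { # header row present
    tab <- tab[-1, , drop = FALSE]
    tab$start <- as.numeric(tab$start); tab$end <- as.numeric(tab$end)
  }
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    tab$start <- tab$start + 1 # 0-based half-open -> 1-based inclusive
  }
  if (any(tab$end < tab$start)) {
    stop("interval with end < start: ", tab$name[which(tab$end < tab$start)[1]])
  }
  rownames(tab) <- NULL
  tab
}

#' Write region test results to TSV
#'
#' One row per region x weight scheme, deterministic column order:
#' `chrom, start, end, gene, piece, n_variants, pct_rare, weight,
#' p_<trait1..K>, p_adj_univariate, p_murat, optimal_rho`. P-values are
#' printed in scientific notation with 4 significant digits.
#'
#' @param results list of test-result records as produced by [run_scan()] /
#'   [murat_region_test()].
#' @param path output TSV path.
#' @return The results data.frame, invisibly.
#' @export
write_results <- function(results, path) {
  df <- results_to_df(results)
  pcols <- grep("^p_|^optimal_rho$", names(df), value = TRUE)
  out <- df
  for (cc in setdiff(pcols, "optimal_rho")) {
    out[[cc]] <- ifelse(is.na(df[[cc]]), "NA", sprintf("%.3e", df[[cc]]))
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write results to ", path, ": ",
                              conditionMessage(e)))
  invisible(df)
}

# flatten a list of test-result records into the canonical results table
results_to_df <- function(results) {
  if (length(results) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      gene = character(0), piece = integer(0),
                      n_variants = integer(0), pct_rare = numeric(0),
                      weight = character(0), p_adj_univariate = numeric(0),
                      p_murat = numeric(0), optimal_rho = numeric(0),
                      note = character(0)))
  }
  K <- max(vapply(results, function(r) length(r$p_univariate), 1L))
  tn <- results[[which.max(vapply(results, function(r) length(r$p_univariate), 1L))]]$trait_names
  if (is.null(tn)) tn <- paste0("trait", seq_len(K))
  rows <- lapply(results, function(r) {
    pu <- rep(NA_real_, K)
    pu[seq_along(r$p_univariate)] <- r$p_univariate
    d <- data.frame(chrom = r$region$chrom, start = r$region$start,
                    end = r$region$end, gene = r$region$label,
                    piece = r$region$piece_index,
                    n_variants = length(r$region$variant_idx),
                    pct_rare = if (is.null(r$pct_rare)) NA_real_ else r$pct_rare,
                    weight = r$weight, stringsAsFactors = FALSE)
    for (k in seq_len(K)) d[[paste0("p_", tn[k])]] <- pu[k]
    d$p_adj_univariate <- if (is.null(r$p_adj_univariate)) NA_real_ else r$p_adj_univariate
    d$p_murat <- if (is.null(r$p_murat)) NA_real_ else r$p_murat
    d$optimal_rho <- if (is.null(r$optimal_rho)) NA_real_ else r$optimal_rho
    d$note <- if (is.null(r$note)) "" else r$note
    d
  })
  do.call(rbind, rows)
}

#' Read back a results TSV written by [write_results()]
#' @param path results TSV.
#' @return data.frame with numeric p-value columns.
#' @export
read_results <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (cc in grep("^p_", names(df), value = TRUE)) {
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  }
  df
}

#' Write regions to a TSV audit file
#' @param regions list of [region()] objects.
#' @param path output path.
#' @export
write_regions <- function(regions, path) {
  df <- do.call(rbind, lapply(regions, function(r) {
    data.frame(chrom = r$chrom, start = r$start, end = r$end, gene = r$label,
               piece = r$piece_index, n_variants = length(r$variant_idx),
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) df <- data.frame(chrom = character(0), start = numeric(0),
                                    end = numeric(0), gene = character(0),
                                    piece = integer(0), n_variants = integer(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write a genotype matrix as a minimal VCF (v4.2, DS field)
#'
#' Round-trip companion to [read_genotypes()]; used by the simulator CLI.
#' REF/ALT are placeholder alleles (the dosage is the data of record).
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output `.vcf` path.
#' @export
write_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", genotypes$samples), collapse = "\t")),
             con)
  body <- vapply(seq_len(nrow(v)), function(j) {
    paste(c(v$chrom[j], format(v$pos[j], scientific = FALSE), v$id[j], "A", "C",
            ".", "PASS", ".", "DS",
            sprintf("%.4g", genotypes$dosages[, j])), collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}
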