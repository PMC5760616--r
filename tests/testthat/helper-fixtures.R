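# in-code fixtures shared across test files

# small hard-genotype matrix with known dosage columns
toy_genotypes <- function(dosages, chrom = "1", pos = NULL) {
  dosages <- as.matrix(dosages)
  v <- ncol(dosages)
  if (is.null(pos)) pos <- 1000 * seq_len(v)
  genotype_matrix(dosages,
                  data.frame(chrom = chrom, pos = pos,
                             id = paste0("v", seq_len(v)),
                             stringsAsFactors = FALSE))
}

# write a minimal GT-based VCF and return its path
write_toy_vcf <- function(gt_rows, chrom = "1", pos = NULL, alt = "C",
                          samples = NULL) {
  n <- length(strsplit(gt_rows[[1]], "\t")[[1]])
  if (is.null(samples)) samples <- paste0("S", seq_len(n))
  if (is.null(pos)) pos <- 100 * seq_along(gt_rows)
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(gt_rows), function(i) {
    paste(c(chrom, pos[i], paste0("rs", i), "A", alt, ".", "PASS", ".", "GT",
            strsplit(gt_rows[[i]], "\t")[[1]]), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  path
}

# dense stacked-model construction of the multivariate score test, written
# directly from the Kronecker algebra; serves as the independent oracle for
# the factorized implementation
dense_multivariate_test <- function(null, G, w, rho) {
  K <- null$K
  N <- nrow(G)
  v <- ncol(G)
  B <- G %*% diag(sqrt(rep_len(w, v)), v)
  Gt <- kronecker(diag(K), B)
  Xt <- kronecker(diag(K), null$X)
  Vinv <- kronecker(null$Sigma_inv, diag(N))
  rt <- as.numeric(null$E)                       # trait-major stack
  S <- as.numeric(t(Gt) %*% Vinv %*% rt)
  R <- (1 - rho) * diag(K) + rho * matrix(1, K, K)
  RI <- kronecker(R, diag(v))
  Q <- as.numeric(t(S) %*% RI %*% S)
  Pt <- Vinv - Vinv %*% Xt %*% solve(t(Xt) %*% Vinv %*% Xt, t(Xt) %*% Vinv)
  Lam <- t(Gt) %*% Pt %*% Gt
  e2 <- eigen(RI, symmetric = TRUE)
  RIh <- e2$vectors %*% (t(e2$vectors) * sqrt(pmax(e2$values, 0)))
  lam <- eigen(RIh %*% Lam %*% RIh, symmetric = TRUE, only.values = TRUE)$values
  p <- mixture_chisq_p(mixture_spec(lam), Q)
  list(Q = Q, lambda = mixture_spec(lam), p = as.numeric(p))
}

# Monte-Carlo tail of a chi-square mixture
mc_mixture_tail <- function(lambda, q, n_draws = 2e5) {
  draws <- colSums(lambda * matrix(stats::rchisq(length(lambda) * n_draws, 1),
                                   nrow = length(lambda)))
  mean(draws >= q)
}
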