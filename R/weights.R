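#' Variant weighting schemes
#'
#' Three MAF-based schemes for the diagonal weight matrix
#' `W = diag(w_1, ..., w_v)` of a region test:
#' \describe{
#'   \item{identical}{`w_j = 1` for every variant.}
#'   \item{beta(a1, a2)}{`sqrt(w_j)` is the Beta(a1, a2) density evaluated at
#'     the variant's MAF. Beta(1, 25) is the usual rare-variant up-weighting:
#'     `sqrt(w_j) = 25 (1 - MAF_j)^24`.}
#'   \item{invsd}{`sqrt(w_j) = 1 / sqrt(MAF_j (1 - MAF_j))`, the inverse of
#'     the allele-count standard deviation — the unnormalized form of
#'     Beta(0.5, 0.5) weighting (the dropped `1/pi` constant rescales W and
#'     leaves score-test p-values unchanged).}
#' }
#'
#' @param kind `"identical"`, `"beta"` or `"invsd"`.
#' @param a1,a2 Beta parameters (used for `kind = "beta"`).
#' @return An object of class `weight_scheme`.
#' @export
weight_scheme <- function(kind = c("identical", "beta", "invsd"), a1 = 1, a2 = 25) {
  kind <- match.arg(kind)
  if (kind == "beta" && (a1 <= 0 || a2 <= 0)) stop("beta parameters must be positive")
  structure(list(kind = kind, a1 = a1, a2 = a2), class = "weight_scheme")
}

#' Parse a scheme label such as "identical", "beta:1,25" or "beta:0.5,0.5"
#'
#' `beta:0.5,0.5` maps to the `invsd` scheme (its unnormalized equivalent).
#' @param label character scalar.
#' @return A [weight_scheme()].
#' @export
parse_weight_scheme <- function(label) {
  if (inherits(label, "weight_scheme")) return(label)
  if (label %in% c("identical", "invsd")) return(weight_scheme(label))
  if (grepl("^beta:", label)) {
    ab <- as.numeric(strsplit(sub("^beta:", "", label), ",")[[1]])
    if (length(ab) != 2 || anyNA(ab)) stop("cannot parse weight scheme: ", label)
    if (ab[1] == 0.5 && ab[2] == 0.5) return(weight_scheme("invsd"))
    return(weight_scheme("beta", ab[1], ab[2]))
  }
  stop("unknown weight scheme: ", label)
}

#' Parse a list of scheme labels from a single CLI string
#'
#' Splits on commas that start a new scheme (so `"identical,beta:1,25"`
#' yields `identical` and `beta:1,25`), then parses each label.
#' @param label character scalar or vector of labels.
#' @return list of [weight_scheme()] objects.
#' @export
parse_weight_schemes <- function(label) {
  if (length(label) == 1L && is.character(label)) {
    label <- strsplit(label, ",(?=(identical|invsd|beta:))", perl = TRUE)[[1]]
  }
  lapply(label, parse_weight_scheme)
}

#' @export
format.weight_scheme <- function(x, ...) {
  switch(x$kind,
         identical = "identical",
         invsd = "beta:0.5,0.5",
         beta = sprintf("beta:%g,%g", x$a1, x$a2))
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("weight_scheme:", format(x), "\n"); invisible(x)
}

#' Compute per-variant weights
#'
#' @param mafs numeric vector of minor allele frequencies in (0, 0.5].
#' @param scheme a [weight_scheme()] or parseable label.
#' @return nonnegative numeric weight vector `w` (not its square root).
#' @export
compute_weights <- function(mafs, scheme) {
  scheme <- parse_weight_scheme(scheme)
  if (any(mafs < 0 | mafs > 0.5)) stop("MAFs must lie in [0, 0.5]")
  diverges <- switch(scheme$kind,
                     identical = FALSE,
                     beta = scheme$a1 < 1,
                     invsd = TRUE)
  if (any(mafs == 0) && diverges) {
    stop("monomorphic variant (MAF = 0) has divergent weight under scheme '",
         format(scheme), "'; drop monomorphic variants first")
  }
  sw <- switch(scheme$kind,
               identical = rep(1, length(mafs)),
               beta = stats::dbeta(mafs, scheme$a1, scheme$a2),
               invsd = 1 / sqrt(mafs * (1 - mafs)))
  sw^2
}
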