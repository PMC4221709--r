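#' Genomic relationship matrix
#'
#' Allele-frequency-centered, variance-scaled cross-product relationship
#' matrix: with W the dosage matrix centered by 2p_j per SNP,
#' K = W W' / sum_j 2 p_j (1 - p_j). Missing dosages are mean-imputed for
#' this computation only; monomorphic SNPs (and X-linked SNPs when
#' `autosomes_only`) are excluded.
#'
#' @param g a [geno_matrix()].
#' @param autosomes_only drop chromosome "X" before computing (default TRUE,
#'   the standard choice for kinship).
#' @return object of class `kinship`: the n x n matrix with attributes
#'   `ids`, `autosomal_only`, `n_snps_used`.
#' @export
genomic_kinship <- function(g, autosomes_only = TRUE) {
  keep <- rep(TRUE, ncol(g$dosage))
  if (autosomes_only) keep <- g$map$chrom != "X"
  d <- g$dosage[, keep, drop = FALSE]
  if (nrow(d) < 2)
    stop("degenerate input: need at least 2 samples", call. = FALSE)
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (sum(poly) < 10)
    stop("degenerate input: fewer than 10 polymorphic SNPs", call. = FALSE)
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(d, 2, 2 * p)
  W[is.na(W)] <- 0                      # mean imputation after centering
  K <- tcrossprod(W) / sum(2 * p * (1 - p))
  K <- (K + t(K)) / 2
  structure(K, ids = g$samples$id, autosomal_only = isTRUE(autosomes_only),
            n_snps_used = sum(poly), class = c("kinship", "matrix", "array"),
            dimnames = list(g$samples$id, g$samples$id))
}

#' Restrict a kinship matrix to a sample subset
#' @param K a `kinship` (or plain) matrix with dimnames.
#' @param ids sample ids to keep, in order.
#' @return the restricted matrix.
#' @export
kinship_subset <- function(K, ids) {
  miss <- setdiff(ids, rownames(K))
  if (length(miss))
    stop("format error: ids absent from kinship: ", paste(head(miss, 3),
         collapse = ", "), call. = FALSE)
  K2 <- unclass(K)[ids, ids]
  structure(K2, ids = ids, autosomal_only = attr(K, "autosomal_only"),
            class = class(K))
}
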