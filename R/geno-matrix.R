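#' Genotype matrix container
#'
#' Light S3 container tying the dosage matrix to its SNP map and sample
#' metadata. Dosages count copies of allele `a1` (0/1/2, `NA` = missing).
#'
#' @param dosage integer matrix, individuals x SNPs; rownames are sample ids.
#' @param map data.frame with columns `chrom`, `id`, `cM`, `bp`, `a1`, `a2`
#'   (one row per SNP, positions strictly increasing within chromosome).
#' @param samples data.frame with columns `id`, `sex` ("M"/"F"), `batch`;
#'   extra columns (e.g. `sire`, `dam`) are carried along.
#' @return object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, map, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != nrow(samples))
    stop("format error: dosage rows do not match sample metadata", call. = FALSE)
  if (ncol(dosage) != nrow(map))
    stop("format error: dosage columns do not match SNP map", call. = FALSE)
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("format error: dosages must be 0/1/2/NA", call. = FALSE)
  for (ch in unique(map$chrom)) {
    bp <- map$bp[map$chrom == ch]
    if (is.unsorted(bp, strictly = TRUE))
      stop("format error: positions must strictly increase within chromosome ",
           ch, call. = FALSE)
  }
  rownames(dosage) <- samples$id
  colnames(dosage) <- map$id
  structure(list(dosage = dosage, map = as.data.frame(map),
                 samples = as.data.frame(samples)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d SNPs on %d chromosome(s); %.2f%% missing\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom)),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param g a `geno_matrix`.
#' @param samples sample ids or logical/integer index over rows.
#' @param snps SNP ids or logical/integer index over columns.
#' @return a `geno_matrix`.
#' @export
subset_geno <- function(g, samples = NULL, snps = NULL) {
  ri <- seq_len(nrow(g$dosage))
  ci <- seq_len(ncol(g$dosage))
  if (!is.null(samples))
    ri <- if (is.character(samples)) match(samples, g$samples$id) else ri[samples]
  if (!is.null(snps))
    ci <- if (is.character(snps)) match(snps, g$map$id) else ci[snps]
  if (anyNA(ri) || anyNA(ci))
    stop("format error: unknown sample or SNP in subset", call. = FALSE)
  geno_matrix(g$dosage[ri, ci, drop = FALSE], g$map[ci, , drop = FALSE],
              g$samples[ri, , drop = FALSE])
}
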