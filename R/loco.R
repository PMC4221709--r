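#' Leave-one-chromosome-out association scan
#'
#' Kinship-corrected scan in which each chromosome's SNPs are tested
#' against a polygenic null model whose kinship excludes that chromosome
#' (LOCO). This removes proximal contamination — a SNP contributing to the
#' kinship it is tested against has part of its own signal absorbed by the
#' polygenic term, deflating effect estimates and, downstream, the
#' between-sex z-statistics. Non-autosomal SNPs are tested against the full
#' autosomal kinship (they never enter it).
#'
#' @param g a [geno_matrix()].
#' @param y trait vector aligned with `g$samples` (NA dropped).
#' @param covariates fixed-effect design (see [fit_polygenic()]).
#' @return list `(assoc, fit)`: `assoc` is the assembled `assoc_result` in
#'   map order; `fit` is the full-autosomal-kinship null fit (the one whose
#'   h2 is reported).
#' @export
loco_scan <- function(g, y, covariates = NULL) {
  ok <- !is.na(y)
  gs <- subset_geno(g, samples = ok)
  ys <- y[ok]
  covs <- if (is.null(covariates)) NULL else
    as.matrix(covariates)[ok, , drop = FALSE]
  auto <- gs$map$chrom != "X"
  d <- gs$dosage[, auto, drop = FALSE]
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  d <- d[, poly, drop = FALSE]; p <- p[poly]
  chrom <- gs$map$chrom[auto][poly]
  W <- sweep(d, 2, 2 * p)
  W[is.na(W)] <- 0
  den_chr <- tapply(2 * p * (1 - p), chrom, sum)
  num_chr <- lapply(unique(chrom), function(ch)
    tcrossprod(W[, chrom == ch, drop = FALSE]))
  names(num_chr) <- unique(chrom)
  num_all <- Reduce(`+`, num_chr)
  den_all <- sum(den_chr)

  full_fit <- fit_polygenic(ys, covs, num_all / den_all)
  pieces <- list()
  for (ch in unique(gs$map$chrom)) {
    if (ch %in% names(num_chr)) {
      Kl <- (num_all - num_chr[[ch]]) / (den_all - den_chr[[ch]])
      fit <- fit_polygenic(ys, covs, Kl)
    } else fit <- full_fit                      # X or all-monomorphic chrom
    pieces[[ch]] <- score_scan(fit, subset_geno(gs, snps = gs$map$chrom == ch))
  }
  assoc <- do.call(rbind, pieces[unique(gs$map$chrom)])
  assoc <- assoc[match(gs$map$id, assoc$snp), ]
  rownames(assoc) <- NULL
  class(assoc) <- c("assoc_result", "data.frame")
  list(assoc = assoc, fit = full_fit)
}
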