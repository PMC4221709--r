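#' Kinship-corrected score-test association scan
#'
#' Tests every SNP against the trait using the null polygenic fit: each
#' genotype column is mean-imputed, centered, projected orthogonal to the
#' fixed effects in the inverse-covariance metric, and scored against the
#' null-model residuals:
#'
#'   beta = (g' Vinv r) / (g' Vinv g),  se = (g' Vinv g)^(-1/2),
#'   chisq = (beta / se)^2 ~ chi-square(1).
#'
#' With the variance components held fixed this equals the generalized
#' least-squares estimate of the SNP effect in the joint fixed-effects
#' model, without per-SNP refitting.
#'
#' @param fit a [fit_polygenic()] result (the null model: covariates only).
#' @param g a [geno_matrix()] whose samples align with the fit's input rows
#'   (rows dropped for missing y are dropped here too).
#' @return data.frame of class `assoc_result`: `snp`, `chrom`, `bp`,
#'   `beta`, `se`, `chisq`, `p`, `maf`, `n`, `tested`, `reason`.
#' @export
score_scan <- function(fit, g) {
  stopifnot(inherits(fit, "polygenic_fit"))
  G <- g$dosage[fit$ok, , drop = FALSE]
  n <- nrow(G)
  if (n != fit$n)
    stop("format error: genotype samples not aligned with fit", call. = FALSE)
  maf <- apply(G, 2, function(x)
    if (all(is.na(x))) NA_real_ else minor_allele_frequency(x))
  n_used <- colSums(!is.na(G))
  Gc <- sweep(G, 2, colMeans(G, na.rm = TRUE))
  Gc[is.na(Gc)] <- 0
  X <- fit$X
  ViX <- fit$Vinv %*% X
  # project out fixed effects in the Vinv metric
  B <- solve(crossprod(X, ViX), crossprod(ViX, Gc))
  Gt <- Gc - X %*% B
  ViG <- fit$Vinv %*% Gt
  num <- drop(crossprod(ViG, fit$residuals))
  den <- colSums(Gt * ViG)

  tested <- is.finite(den) & den > 1e-12 & !is.na(maf) & maf > 0
  beta <- se <- chisq <- p <- rep(NA_real_, ncol(G))
  beta[tested] <- num[tested] / den[tested]
  se[tested] <- 1 / sqrt(den[tested])
  chisq[tested] <- (beta[tested] / se[tested])^2
  p[tested] <- stats::pchisq(chisq[tested], df = 1, lower.tail = FALSE)
  out <- data.frame(snp = g$map$id, chrom = g$map$chrom, bp = g$map$bp,
                    beta = beta, se = se, chisq = chisq, p = p, maf = maf,
                    n = n_used, tested = tested,
                    reason = ifelse(tested, "",
                                    ifelse(is.na(maf) | maf == 0,
                                           "monomorphic", "zero_variance")),
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Write an association scan as a tab-delimited table
#' @param assoc an `assoc_result`.
#' @param path output file.
#' @export
write_assoc <- function(assoc, path) {
  out <- data.frame(CHR = assoc$chrom, SNP = assoc$snp, BP = assoc$bp,
                    BETA = assoc$beta, SE = assoc$se, CHISQ = assoc$chisq,
                    P = assoc$p, MAF = assoc$maf, N = assoc$n)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
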