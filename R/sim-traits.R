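#' Simulate trait values over the pedigree's F2 animals
#'
#' For each configured trait the phenotype of F2 individual i is
#'
#'   y_i = sex_offset * 1(male_i) + batch_b(i) + sum_q x_iq * beta_q,sex(i)
#'         + u_i + e_i
#'
#' where x_iq are QTL dosages and `u` is an infinitesimal polygenic value:
#' iid standard-normal effects on every autosomal non-QTL SNP, summed over
#' the individual's (clean) genotypes and standardized, then scaled per sex
#' to variance h2_sex/(1-h2_sex) * residual_sd^2 — so the narrow-sense
#' heritability of the polygenic + residual part equals h2_sex within each
#' sex, and the genetic covariance among relatives follows their realized
#' genome sharing. Batch effects are iid N(0, batch_sd^2) and
#' e_i ~ N(0, residual_sd^2). A single standardized polygenic vector is
#' scaled per sex, so male and female genetic values stay correlated.
#'
#' QTL dosages are taken from the clean (pre-artifact) genotypes; X-linked
#' SNPs are never used as QTL nor as polygenic background.
#'
#' @param genotypes clean [geno_matrix()] from [gene_drop()].
#' @param pedigree the pedigree used for the gene drop.
#' @param config the [sim_config()].
#' @return data.frame (`trait_table`): `id`, `sex`, `batch`, one numeric
#'   column per configured trait; F2 rows only.
#' @export
simulate_traits <- function(genotypes, pedigree, config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "traits"))
  f2 <- pedigree$id[pedigree$generation == "F2"]
  n <- length(f2)
  sex <- pedigree$sex[match(f2, pedigree$id)]
  batch <- pedigree$batch[match(f2, pedigree$id)]
  male <- sex == "M"

  auto <- which(genotypes$map$chrom != "X")
  out <- data.frame(id = f2, sex = sex, batch = batch, stringsAsFactors = FALSE)

  for (nm in names(config$traits)) {
    tr <- config$traits[[nm]]
    s2e <- tr$residual_sd^2
    s2g <- c(M = tr$h2_male / (1 - tr$h2_male),
             F = tr$h2_female / (1 - tr$h2_female)) * s2e
    qtl_idx <- if (is.null(tr$qtl)) integer(0) else
      (tr$qtl$chrom - 1L) * config$n_snps + tr$qtl$snp
    bg <- setdiff(auto, qtl_idx)
    W <- genotypes$dosage[f2, bg, drop = FALSE]
    W <- sweep(W, 2, colMeans(W))
    u0 <- drop(W %*% stats::rnorm(length(bg)))   # infinitesimal background
    if (stats::sd(u0) > 0) u0 <- (u0 - mean(u0)) / stats::sd(u0)
    u <- sqrt(s2g[sex]) * u0
    qtl_part <- 0
    if (!is.null(tr$qtl)) {
      q <- tr$qtl
      idx <- (q$chrom - 1L) * config$n_snps + q$snp
      x <- genotypes$dosage[f2, idx, drop = FALSE]
      beta <- ifelse(male, 1, 0) %o% (q$effect_male * tr$residual_sd /
                                        sqrt(1 - tr$h2_male)) +
        ifelse(male, 0, 1) %o% (q$effect_female * tr$residual_sd /
                                  sqrt(1 - tr$h2_female))
      qtl_part <- rowSums(x * beta)
    }
    b_eff <- stats::rnorm(length(unique(batch)), 0, tr$batch_sd)
    names(b_eff) <- unique(batch)
    y <- tr$sex_offset * as.numeric(male) + b_eff[batch] + qtl_part + u +
      stats::rnorm(n, 0, tr$residual_sd)
    out[[nm]] <- unname(y)
  }
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Simulate a complete F2 cross
#'
#' Convenience wrapper chaining [simulate_founders()], [make_pedigree()],
#' [gene_drop()], [inject_artifacts()] and [simulate_traits()], then
#' restricting to the analyzed F2 subset (`analyzed_fraction`).
#'
#' @param config a [sim_config()].
#' @param keep_clean also return the pre-artifact genotypes.
#' @return list with `genotypes` (artifact-injected, all pedigree members),
#'   `clean` (if requested), `pedigree`, `traits` (analyzed F2 only),
#'   `analyzed_ids`, `panel`, `config`.
#' @export
simulate_cross <- function(config, keep_clean = FALSE) {
  validate_sim_config(config)
  panel <- simulate_founders(config)
  ped <- make_pedigree(config)
  clean <- gene_drop(ped, panel, config)
  geno <- inject_artifacts(clean, config)
  traits <- simulate_traits(clean, ped, config)
  set.seed(stage_seed(config$seed, "subset"))
  n_keep <- max(1L, floor(config$analyzed_fraction * nrow(traits)))
  keep <- sort(sample(nrow(traits), n_keep))
  res <- list(genotypes = geno, pedigree = ped,
              traits = traits[keep, , drop = FALSE],
              analyzed_ids = traits$id[keep],
              panel = panel, config = config)
  if (keep_clean) res$clean <- clean
  res
}
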