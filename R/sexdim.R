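#' Per-scan significance thresholds
#'
#' Bonferroni-style per-scan levels: suggestive = 1/N_snp (one expected
#' false positive per genome scan) and genome-wide = 0.05/N_snp.
#'
#' @param n_snp number of SNPs tested in the scan.
#' @return named numeric vector `c(suggestive =, genomewide =)`.
#' @export
significance_thresholds <- function(n_snp) {
  if (length(n_snp) != 1 || is.na(n_snp) || n_snp < 1)
    stop("undefined input: n_snp must be a positive count", call. = FALSE)
  c(suggestive = 1 / n_snp, genomewide = 0.05 / n_snp)
}

#' Combined and sex-stratified association scans
#'
#' Runs three kinship-corrected scans of one trait: males only and females
#' only (fixed effect: batch; kinship restricted to the stratum) and both
#' sexes combined (fixed effects: sex + batch; full kinship).
#'
#' @param g a [geno_matrix()] (analyzed samples).
#' @param y trait vector aligned with `g$samples`.
#' @param sex,batch labels aligned with `y`.
#' @param K autosomal [genomic_kinship()] over `g`'s samples (used for the
#'   per-stratum heritability fits; when `loco = FALSE` also for the scans).
#' @param min_n minimum individuals with trait data per stratum (default
#'   30); a smaller stratum is skipped with a reason, the others still run.
#' @param loco use leave-one-chromosome-out kinship for the scans (default
#'   TRUE; see [loco_scan()]).
#' @return list with `male`, `female`, `combined` — each a list
#'   `(assoc, fit)` or `(skipped = reason)` — plus `n` per stratum.
#' @export
stratified_scans <- function(g, y, sex, batch, K, min_n = 30, loco = TRUE) {
  ids <- g$samples$id
  stopifnot(length(y) == length(ids), length(sex) == length(ids),
            length(batch) == length(ids))
  K <- unclass(K)
  batch_design <- function(b) {
    b <- factor(b)
    if (nlevels(b) < 2) return(NULL)
    stats::model.matrix(~b)[, -1, drop = FALSE]
  }
  run_one <- function(rows, covars) {
    gs <- subset_geno(g, samples = rows)
    if (loco) {
      res <- loco_scan(gs, y[rows], covars)
      res$fit <- fit_polygenic(y[rows], covars, K[rows, rows])
      res
    } else {
      fit <- fit_polygenic(y[rows], covars, K[rows, rows])
      list(assoc = score_scan(fit, gs), fit = fit)
    }
  }
  res <- list()
  for (s in c("M", "F")) {
    rows <- which(sex == s & !is.na(y))
    nm <- if (s == "M") "male" else "female"
    res[[nm]] <- if (length(rows) < min_n)
      list(skipped = sprintf("stratum %s below minimum n (%d < %d)", s,
                             length(rows), min_n))
    else run_one(rows, batch_design(batch[rows]))
  }
  rows <- which(!is.na(y))
  bd <- batch_design(batch[rows])
  sx <- stats::model.matrix(~factor(sex[rows], levels = c("F", "M")))[, -1,
                                                                      drop = FALSE]
  colnames(sx) <- "sexM"
  res$combined <- run_one(rows, cbind(sx, bd))
  res$n <- c(male = sum(sex == "M" & !is.na(y)),
             female = sum(sex == "F" & !is.na(y)), combined = length(rows))
  res
}

#' z-test for sexually dimorphic SNP effects
#'
#' For each SNP with effect estimates in both sexes,
#'   Z = (beta_male - beta_female) / sqrt(se_male^2 + se_female^2),
#' standard normal under the null of equal allelic effects. SNPs with minor
#' allele frequency below `maf_min` in either sex, or untested in either
#' scan, are flagged untested.
#'
#' Because every F2 animal is related to animals of the other sex, the
#' stratum effect estimates are not quite independent and the raw
#' difference statistic runs mildly conservative; by default the z-scores
#' are therefore genomic-control scaled (`gc = TRUE`): p-values are
#' computed from z / sqrt(lambda_z) with lambda_z = median(z^2)/0.4549,
#' estimated over tested SNPs whenever at least `gc_min_snps` of them are
#' available (the raw `z` column is always reported unscaled).
#'
#' @param male,female `assoc_result`s from the two strata (same SNP set).
#' @param maf_min per-stratum MAF guard (default 0.05).
#' @param sided `"two"` (default: dimorphism in either direction) or
#'   `"male"`/`"female"` for a one-sided test of a larger effect in that
#'   sex.
#' @param gc apply genomic control to the p-values (default TRUE).
#' @param gc_min_snps minimum tested SNPs before lambda_z is estimated
#'   (below it lambda_z = 1).
#' @return data.frame of class `sexdim_result`: `snp`, `chrom`, `bp`,
#'   `beta_male`, `se_male`, `beta_female`, `se_female`, `maf_male`,
#'   `maf_female`, `z` (raw), `z_gc`, `p_z`, `tested`, `reason`; attribute
#'   `lambda_z`.
#' @export
z_dimorphism <- function(male, female, maf_min = 0.05, sided = "two",
                         gc = TRUE, gc_min_snps = 50) {
  if (!identical(male$snp, female$snp))
    stop("format error: male and female scans must cover the same SNPs",
         call. = FALSE)
  sided <- match.arg(sided, c("two", "male", "female"))
  z <- (male$beta - female$beta) / sqrt(male$se^2 + female$se^2)
  tested <- male$tested & female$tested &
    !is.na(male$maf) & !is.na(female$maf) &
    male$maf >= maf_min & female$maf >= maf_min & is.finite(z)
  reason <- rep("", length(z))
  reason[!male$tested | !female$tested] <- "untested_stratum"
  reason[(male$tested & female$tested) &
           (is.na(male$maf) | is.na(female$maf) |
              male$maf < maf_min | female$maf < maf_min)] <- "low_maf"
  reason[tested] <- ""
  z[!tested] <- NA_real_
  lambda <- 1
  if (gc && sum(tested) >= gc_min_snps)
    lambda <- stats::median(z[tested]^2) / stats::qchisq(0.5, 1)
  zg <- z / sqrt(lambda)
  p <- switch(sided,
              two = 2 * stats::pnorm(-abs(zg)),
              male = stats::pnorm(zg, lower.tail = FALSE),
              female = stats::pnorm(zg))
  out <- data.frame(snp = male$snp, chrom = male$chrom, bp = male$bp,
                    beta_male = male$beta, se_male = male$se,
                    beta_female = female$beta, se_female = female$se,
                    maf_male = male$maf, maf_female = female$maf,
                    z = z, z_gc = zg, p_z = p, tested = tested,
                    reason = reason, stringsAsFactors = FALSE)
  attr(out, "lambda_z") <- lambda
  class(out) <- c("sexdim_result", "data.frame")
  out
}

#' Permutation test for a sex difference in heritability
#'
#' Observed statistic: |h2_male - h2_female| from per-stratum
#' [fit_polygenic()] (batch fixed effect, kinship restricted to the
#' stratum). The sex labels are then shuffled B times (stratum sizes
#' preserved) and the statistic recomputed under each shuffle; the p-value
#' uses the add-one estimator (1 + #(null >= observed)) / (1 + B), bounded
#' below by 1/(B+1).
#'
#' @param y trait vector.
#' @param sex,batch labels aligned with `y`.
#' @param K autosomal kinship over the same samples.
#' @param B number of permutations (default 1000).
#' @param seed RNG seed for the shuffles.
#' @param max_fail abort if more than this fraction of permutation fits
#'   fail (default 0.05).
#' @return list of class `h2_comparison`: `h2_male`, `h2_female`,
#'   `observed`, `B`, `p`, `null` (the permuted statistics).
#' @export
heritability_permutation_test <- function(y, sex, batch, K, B = 1000,
                                          seed = 1, max_fail = 0.05) {
  ok <- !is.na(y) & !is.na(sex)
  y <- y[ok]; sex <- sex[ok]; batch <- batch[ok]
  K <- unclass(K)[ok, ok, drop = FALSE]
  if (sum(sex == "M") < 30 || sum(sex == "F") < 30)
    stop("degenerate input: need >= 30 individuals per sex", call. = FALSE)
  bd <- function(rows) {
    b <- factor(batch[rows])
    if (nlevels(b) < 2) NULL else stats::model.matrix(~b)[, -1, drop = FALSE]
  }
  h2_of <- function(rows) fit_polygenic(y[rows], bd(rows),
                                        K[rows, rows, drop = FALSE])$h2
  stat_of <- function(lab) abs(h2_of(which(lab == "M")) -
                                 h2_of(which(lab == "F")))
  h2m <- h2_of(which(sex == "M"))
  h2f <- h2_of(which(sex == "F"))
  observed <- abs(h2m - h2f)
  set.seed(seed)
  nulls <- rep(NA_real_, B)
  fails <- 0L
  for (b in seq_len(B)) {
    lab <- sample(sex)
    nulls[b] <- tryCatch(stat_of(lab), error = function(e) {
      fails <<- fails + 1L
      NA_real_
    })
  }
  if (fails > max_fail * B)
    stop(sprintf("convergence failure in %d/%d permutations", fails, B),
         call. = FALSE)
  p <- (1 + sum(nulls >= observed, na.rm = TRUE)) / (1 + sum(!is.na(nulls)))
  structure(list(h2_male = h2m, h2_female = h2f, observed = observed,
                 B = B, p = p, null = nulls), class = "h2_comparison")
}

#' @export
print.h2_comparison <- function(x, ...) {
  cat(sprintf("h2 male = %.3f, female = %.3f; |diff| = %.3f; permutation p = %.4g (B = %d)\n",
              x$h2_male, x$h2_female, x$observed, x$p, x$B))
  invisible(x)
}

#' Compare stratified and combined scan significance sets
#'
#' Counts SNP-trait pairs significant in the combined scan, in any
#' stratified scan (male or female), their intersection, and each exclusive
#' margin; percentages follow the usual Venn accounting (stratified-only as
#' a percentage of the combined count; shared as a percentage of the
#' union).
#'
#' @param stratified data.frame with columns `key` (SNP or SNP-trait pair
#'   identifier) and `p` — the per-pair minimum of the male/female scan
#'   p-values — or an `assoc_result`.
#' @param combined same, for the combined scan.
#' @param threshold significance level applied to both.
#' @return list of class `scan_comparison`: `threshold`, `n_stratified`,
#'   `n_combined`, `n_shared`, `n_stratified_only`, `n_combined_only`,
#'   `n_union`, `pct_stratified_only_of_combined`, `pct_shared_of_union`.
#' @export
compare_scans <- function(stratified, combined, threshold) {
  as_keyed <- function(x) {
    if (inherits(x, "assoc_result") || ("snp" %in% names(x) && !"key" %in% names(x))) {
      key <- if ("trait" %in% names(x)) paste(x$trait, x$snp) else x$snp
      data.frame(key = key, p = x$p, stringsAsFactors = FALSE)
    } else as.data.frame(x)
  }
  s <- as_keyed(stratified); cb <- as_keyed(combined)
  universe <- union(s$key, cb$key)
  if (!length(universe))
    stop("undefined input: empty SNP universe", call. = FALSE)
  sig_s <- unique(s$key[!is.na(s$p) & s$p < threshold])
  sig_c <- unique(cb$key[!is.na(cb$p) & cb$p < threshold])
  shared <- intersect(sig_s, sig_c)
  s_only <- setdiff(sig_s, sig_c)
  c_only <- setdiff(sig_c, sig_s)
  un <- union(sig_s, sig_c)
  structure(list(
    threshold = threshold,
    n_stratified = length(sig_s), n_combined = length(sig_c),
    n_shared = length(shared), n_stratified_only = length(s_only),
    n_combined_only = length(c_only), n_union = length(un),
    pct_stratified_only_of_combined =
      if (length(sig_c)) 100 * length(s_only) / length(sig_c) else NA_real_,
    pct_shared_of_union =
      if (length(un)) 100 * length(shared) / length(un) else NA_real_),
    class = "scan_comparison")
}

#' @export
print.scan_comparison <- function(x, ...) {
  cat(sprintf(paste0("scan comparison at p < %.3g:\n",
                     "  stratified %d | combined %d | shared %d (%.1f%% of union)\n",
                     "  stratified-only %d (%.1f%% of combined)\n"),
              x$threshold, x$n_stratified, x$n_combined, x$n_shared,
              x$pct_shared_of_union, x$n_stratified_only,
              x$pct_stratified_only_of_combined))
  invisible(x)
}

#' Tail-shift test of |Z| for a SNP subset
#'
#' Welch two-sample t-test comparing the absolute z-statistics of a subset
#' (e.g. SNPs found only by the stratified scans) against those of all
#' tested SNPs — a shifted subset indicates the subset carries sex-specific
#' effects.
#'
#' @param z_all z-statistics of all tested SNPs.
#' @param z_subset z-statistics of the subset.
#' @return list `(t, p, mean_subset, mean_all, degenerate)`.
#' @export
zdist_shift_test <- function(z_all, z_subset) {
  z_all <- z_all[!is.na(z_all)]; z_subset <- z_subset[!is.na(z_subset)]
  if (!length(z_all) || !length(z_subset))
    stop("undefined input: empty z vector", call. = FALSE)
  a <- abs(z_all); s <- abs(z_subset)
  if (length(s) < 2 || stats::sd(s) == 0 || stats::sd(a) == 0)
    return(list(t = NA_real_, p = NA_real_, mean_subset = mean(s),
                mean_all = mean(a), degenerate = TRUE))
  tt <- stats::t.test(s, a)
  list(t = unname(tt$statistic), p = tt$p.value, mean_subset = mean(s),
       mean_all = mean(a), degenerate = FALSE)
}

#' Spearman correlation of per-trait heritabilities between sexes
#'
#' @param h2_male,h2_female paired per-trait heritability vectors.
#' @return list `(rho, p, n, degenerate)`.
#' @export
spearman_h2_correlation <- function(h2_male, h2_female) {
  ok <- !is.na(h2_male) & !is.na(h2_female)
  x <- h2_male[ok]; y <- h2_female[ok]
  if (length(x) < 3)
    stop("undefined input: need >= 3 paired traits", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(x),
                degenerate = TRUE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
       degenerate = FALSE)
}

#' Write a dimorphism table as tab-delimited text
#' @param sd a `sexdim_result`.
#' @param path output file.
#' @export
write_sexdim <- function(sd, path) {
  out <- data.frame(CHR = sd$chrom, SNP = sd$snp, BP = sd$bp,
                    BETA_M = sd$beta_male, SE_M = sd$se_male,
                    BETA_F = sd$beta_female, SE_F = sd$se_female,
                    MAF_M = sd$maf_male, MAF_F = sd$maf_female,
                    Z = sd$z, P_Z = sd$p_z, TESTED = sd$tested,
                    REASON = sd$reason)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
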