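#' Simulation benchmarks of the pipeline's statistical properties
#'
#' These functions reproduce the package's validation studies on the F2
#' design it targets: calibration of the sex-dimorphism z-test, power to
#' recover sex-specific QTL, heritability recovery, and calibration/power
#' of the heritability permutation test. They are used by the test suite
#' and by `scripts/acceptance.R`, and are exported so the studies can be
#' rerun at other seeds or sizes.
#'
#' @name benchmarks
#' @keywords internal
NULL

# study-shaped cohort at reduced size: the full mating design, n_F2 animals,
# 18 autosomes x n_snps SNPs
bench_cohort <- function(seed, n_F2 = 900, n_snps = 112, traits,
                         missing_rate = 0.02, geno_error_rate = 0.001) {
  cfg <- sim_config(n_snps = n_snps, n_chromosomes = 18, include_x = FALSE,
                    pedigree_counts = list(n_sires_F0 = 2, n_dams_F0 = 17,
                                           n_sires_F1 = 9, n_dams_F1 = 59,
                                           n_F2 = n_F2, n_batches = 6),
                    traits = traits, missing_rate = missing_rate,
                    geno_error_rate = geno_error_rate, seed = seed)
  sim <- simulate_cross(cfg)
  g <- subset_geno(sim$genotypes, samples = sim$traits$id)
  list(g = g, traits = sim$traits, K = genomic_kinship(g), map = g$map)
}

bench_trait <- function(h2_male = 0.4, h2_female = 0.4, qtl = NULL,
                        sex_offset = 0, batch_sd = 0.25, residual_sd = 1) {
  list(t1 = list(qtl = qtl, h2_male = h2_male, h2_female = h2_female,
                 sex_offset = sex_offset, batch_sd = batch_sd,
                 residual_sd = residual_sd))
}

#' @rdname benchmarks
#' @param seed integer seed.
#' @return `benchmark_ztest_null()`: list with the fraction of two-sided
#'   dimorphism p-values below 0.05, the Kolmogorov-Smirnov uniformity
#'   p-value, lambda_z, and the number of tested SNPs, on a null cohort
#'   (450 expected per sex, 2016 SNPs, h2 = 0.4 in both sexes, no QTL).
#' @export
benchmark_ztest_null <- function(seed = 1) {
  co <- bench_cohort(seed, traits = bench_trait())
  sc <- stratified_scans(co$g, co$traits$t1, co$traits$sex, co$traits$batch,
                         co$K)
  zd <- z_dimorphism(sc$male$assoc, sc$female$assoc)
  p <- zd$p_z[zd$tested]
  list(frac_p05 = mean(p < 0.05),
       ks_p = suppressWarnings(stats::ks.test(p, "punif"))$p.value,
       lambda_z = attr(zd, "lambda_z"), n = length(p))
}

#' @rdname benchmarks
#' @param seeds integer vector of replicate seeds.
#' @param effect_male,effect_female QTL effect sizes in trait-SD units.
#' @return `benchmark_dimorphic_recovery()`: per-seed data.frame with the
#'   QTL's dimorphism p, per-stratum and combined scan p, and the
#'   suggestive threshold, for a MAF-0.3 QTL on chromosome 5.
#' @export
benchmark_dimorphic_recovery <- function(seeds = 1:10, effect_male = 0.6,
                                         effect_female = 0) {
  qtl <- data.frame(chrom = 5L, snp = 50L, effect_male = effect_male,
                    effect_female = effect_female, freq = 0.3)
  rows <- lapply(seeds, function(s) {
    co <- bench_cohort(s, traits = bench_trait(qtl = qtl))
    sc <- stratified_scans(co$g, co$traits$t1, co$traits$sex,
                           co$traits$batch, co$K)
    zd <- z_dimorphism(sc$male$assoc, sc$female$assoc)
    qid <- co$map$id[co$map$chrom == "5"][50]
    i <- match(qid, zd$snp)
    thr <- significance_thresholds(sum(sc$male$assoc$tested))[["suggestive"]]
    data.frame(seed = s, p_z = zd$p_z[i], p_male = sc$male$assoc$p[i],
               p_female = sc$female$assoc$p[i],
               p_combined = sc$combined$assoc$p[i], suggestive = thr)
  })
  do.call(rbind, rows)
}

#' @rdname benchmarks
#' @param h2 simulated heritability (equal in both sexes).
#' @param n_F2 cohort size.
#' @return `benchmark_h2_recovery()`: vector of REML heritability estimates,
#'   one per seed, from genomic-kinship fits of traits simulated at `h2`.
#' @export
benchmark_h2_recovery <- function(h2, seeds = 1:10, n_F2 = 500) {
  vapply(seeds, function(s) {
    co <- bench_cohort(s, n_F2 = n_F2, n_snps = 112,
                       traits = bench_trait(h2_male = h2, h2_female = h2,
                                            batch_sd = 0),
                       missing_rate = 0, geno_error_rate = 0)
    fit_polygenic(co$traits$t1, NULL, co$K)$h2
  }, numeric(1))
}

#' @rdname benchmarks
#' @param n_traits number of null traits for the calibration study.
#' @param B permutations per trait.
#' @return `benchmark_perm_calibration()`: vector of permutation p-values
#'   for `n_traits` traits simulated with identical generative models in
#'   both sexes (h2 = 0.3, 100 expected per sex).
#' @export
benchmark_perm_calibration <- function(seed = 1, n_traits = 50, B = 200) {
  traits <- stats::setNames(rep(list(list(qtl = NULL, h2_male = 0.3,
                                          h2_female = 0.3, sex_offset = 0,
                                          batch_sd = 0.2, residual_sd = 1)),
                                n_traits), paste0("t", seq_len(n_traits)))
  co <- bench_cohort(seed, n_F2 = 200, n_snps = 60, traits = traits,
                     missing_rate = 0, geno_error_rate = 0)
  vapply(seq_len(n_traits), function(i)
    heritability_permutation_test(co$traits[[paste0("t", i)]],
                                  co$traits$sex, co$traits$batch, co$K,
                                  B = B,
                                  seed = (seed * 1000 + i) %% 2147483647)$p,
    numeric(1))
}

#' @rdname benchmarks
#' @return `benchmark_perm_power()`: vector of permutation p-values, one
#'   per seed, for traits simulated with h2_male = 0.7 vs h2_female = 0.1
#'   at 300 expected individuals per sex.
#' @export
benchmark_perm_power <- function(seeds = 1:10, B = 200) {
  vapply(seeds, function(s) {
    co <- bench_cohort(s, n_F2 = 600, n_snps = 60,
                       traits = bench_trait(h2_male = 0.7, h2_female = 0.1,
                                            batch_sd = 0.2),
                       missing_rate = 0, geno_error_rate = 0)
    heritability_permutation_test(co$traits$t1, co$traits$sex,
                                  co$traits$batch, co$K, B = B,
                                  seed = s)$p
  }, numeric(1))
}
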