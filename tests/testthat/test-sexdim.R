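test_that("significance thresholds follow the 1/N and 0.05/N rules", {
  thr <- significance_thresholds(39454)
  expect_equal(signif(thr[["suggestive"]], 2), 2.5e-5)
  expect_equal(thr[["genomewide"]], 0.05 / 39454)
  expect_equal(signif(thr[["genomewide"]], 5), 1.2673e-6)
  expect_equal(unname(significance_thresholds(1)), c(1, 0.05))
  expect_error(significance_thresholds(0), "undefined")
})

test_that("z-statistic follows the stratum-difference formula", {
  mk <- function(beta, se, maf = 0.3) {
    structure(data.frame(snp = paste0("s", seq_along(beta)), chrom = "1",
                         bp = seq_along(beta), beta = beta, se = se,
                         chisq = (beta / se)^2,
                         p = pchisq((beta / se)^2, 1, lower.tail = FALSE),
                         maf = maf, n = 100, tested = TRUE, reason = "",
                         stringsAsFactors = FALSE),
              class = c("assoc_result", "data.frame"))
  }
  m <- mk(c(1.0, 0.4), c(0.5, 0.2))
  f <- mk(c(0.2, 0.4), c(0.3, 0.2))
  zd <- z_dimorphism(m, f)
  expect_equal(zd$z[1], 0.8 / sqrt(0.34), tolerance = 1e-12)
  expect_equal(round(zd$z[1], 3), 1.372)
  expect_equal(zd$z[2], 0)
  expect_equal(zd$p_z[2], 1)
  # stratum swap negates Z, keeps two-sided p
  zs <- z_dimorphism(f, m)
  expect_equal(zs$z, -zd$z)
  expect_equal(zs$p_z, zd$p_z)
  # MAF guard
  f2 <- mk(c(0.2, 0.4), c(0.3, 0.2), maf = c(0.3, 0.01))
  zg <- z_dimorphism(m, f2)
  expect_false(zg$tested[2])
  expect_equal(zg$reason[2], "low_maf")
  expect_true(is.na(zg$z[2]))
  # one-sided modes
  z1 <- z_dimorphism(m, f, sided = "male")
  expect_equal(z1$p_z[1], pnorm(zd$z[1], lower.tail = FALSE))
})

test_that("scan comparison satisfies set arithmetic and inclusion-exclusion", {
  mkset <- function(keys, sig) data.frame(key = keys,
                                          p = ifelse(keys %in% sig, 1e-8, 0.5))
  u <- as.character(1:200)
  cmp <- compare_scans(mkset(u, as.character(51:163)),
                       mkset(u, as.character(1:100)), threshold = 1e-4)
  expect_equal(cmp$n_shared, 50)
  expect_equal(cmp$n_stratified_only, 63)
  expect_equal(cmp$pct_stratified_only_of_combined, 63)
  expect_equal(cmp$pct_shared_of_union, 100 * 50 / 163)
  # identity and disjoint cases
  ci <- compare_scans(mkset(u, u[1:10]), mkset(u, u[1:10]), 1e-4)
  expect_equal(ci$pct_shared_of_union, 100)
  expect_equal(ci$n_stratified_only, 0)
  cd <- compare_scans(mkset(u, u[1:10]), mkset(u, u[11:20]), 1e-4)
  expect_equal(cd$pct_shared_of_union, 0)
  expect_equal(cd$pct_stratified_only_of_combined, 100)
  # inclusion-exclusion on random instances
  set.seed(61)
  for (i in 1:20) {
    s <- mkset(u, sample(u, sample(0:80, 1)))
    cb <- mkset(u, sample(u, sample(1:80, 1)))
    cc <- compare_scans(s, cb, 1e-4)
    expect_equal(cc$n_union,
                 cc$n_stratified + cc$n_combined - cc$n_shared)
    expect_equal(cc$n_stratified, cc$n_shared + cc$n_stratified_only)
    expect_equal(cc$n_combined, cc$n_shared + cc$n_combined_only)
  }
  expect_error(compare_scans(data.frame(key = character(), p = numeric()),
                             data.frame(key = character(), p = numeric()),
                             0.05), "empty")
})

test_that("|Z| tail-shift test separates shifted subsets and tolerates edge cases", {
  set.seed(62)
  z_all <- rnorm(500)
  r0 <- zdist_shift_test(z_all, z_all)
  expect_gt(r0$p, 0.99)
  expect_lt(abs(r0$t), 0.01)
  shifted <- rnorm(500, mean = 3)
  r1 <- zdist_shift_test(z_all, shifted)
  expect_lt(r1$p, 1e-10)
  expect_gt(r1$mean_subset, r1$mean_all)
  r2 <- zdist_shift_test(z_all, 2.5)       # singleton: no crash
  expect_true(r2$degenerate)
})

test_that("heritability permutation p-values are bounded and reproducible", {
  sim <- simulate_cross(study_config(seed = 63, n_F2 = 150, n_snps = 50,
                                     n_chromosomes = 5))
  g <- subset_geno(sim$genotypes, samples = sim$traits$id)
  K <- genomic_kinship(g)
  r1 <- heritability_permutation_test(sim$traits$t1, sim$traits$sex,
                                      sim$traits$batch, K, B = 30, seed = 9)
  r2 <- heritability_permutation_test(sim$traits$t1, sim$traits$sex,
                                      sim$traits$batch, K, B = 30, seed = 9)
  expect_identical(r1$null, r2$null)
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 1 / 31)
  expect_lte(r1$p, 1)
  expect_gte(r1$observed, 0)
  r3 <- heritability_permutation_test(sim$traits$t1, sim$traits$sex,
                                      sim$traits$batch, K, B = 30, seed = 10)
  expect_false(identical(r1$null, r3$null))
})

test_that("stratified scans skip an undersized stratum but produce the rest", {
  sim <- simulate_cross(small_config(seed = 64, n_F2 = 120, n_snps = 30,
                                     n_chromosomes = 3))
  g <- subset_geno(sim$genotypes, samples = sim$traits$id)
  K <- genomic_kinship(g)
  y <- sim$traits$t1
  y[sim$traits$sex == "F"][1:(sum(sim$traits$sex == "F") - 10)] <- NA
  sc <- stratified_scans(g, y, sim$traits$sex, sim$traits$batch, K)
  expect_false(is.null(sc$female$skipped))
  expect_s3_class(sc$male$assoc, "assoc_result")
  expect_s3_class(sc$combined$assoc, "assoc_result")
})

test_that("spearman h2 correlation handles concordant, reversed and flat input", {
  expect_equal(spearman_h2_correlation(1:10 / 10, 1:10 / 10)$rho, 1)
  expect_equal(spearman_h2_correlation(1:10 / 10, 10:1 / 10)$rho, -1)
  expect_true(spearman_h2_correlation(rep(0.5, 5), 1:5 / 10)$degenerate)
  expect_error(spearman_h2_correlation(0.1, 0.2), "paired")
  set.seed(65)
  shared <- runif(50, 0, 0.6)
  r <- spearman_h2_correlation(shared + rnorm(50, 0, 0.1),
                               shared + rnorm(50, 0, 0.1))
  expect_gt(r$rho, 0)
  expect_lt(r$p, 0.05)
})
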