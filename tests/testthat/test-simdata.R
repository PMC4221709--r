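test_that("config validation rejects bad rates, counts and heritabilities", {
  expect_error(small_config(missing_rate = 1.5), "rates")
  expect_error(small_config(traits = list(t = list(qtl = NULL, h2_male = 1,
                                                   h2_female = 0.2,
                                                   sex_offset = 0,
                                                   batch_sd = 0,
                                                   residual_sd = 1))),
               "heritabilities")
  expect_error(sim_config(founder_divergence = list(shape1 = -1, shape2 = 1)),
               "divergence")
  expect_error(small_config(traits = list(t = list(
    qtl = data.frame(chrom = 1L, snp = 999L, effect_male = 1,
                     effect_female = 0),
    h2_male = 0.2, h2_female = 0.2, sex_offset = 0, batch_sd = 0,
    residual_sd = 1))), "QTL index")
})

test_that("default pedigree counts reproduce the study design", {
  cfg <- sim_config()
  expect_equal(unlist(cfg$pedigree_counts),
               c(n_sires_F0 = 2L, n_dams_F0 = 17L, n_sires_F1 = 9L,
                 n_dams_F1 = 59L, n_F2 = 1912L, n_batches = 6L))
})

test_that("config round-trips through YAML", {
  cfg <- small_config(traits = list(t1 = list(
    qtl = data.frame(chrom = 1L, snp = 3L, effect_male = 0.5,
                     effect_female = 0, freq = 0.3),
    h2_male = 0.3, h2_female = 0.5, sex_offset = 1, batch_sd = 0.1,
    residual_sd = 2)))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  expect_equal(cfg2$pedigree_counts, cfg$pedigree_counts)
  expect_equal(cfg2$traits$t1$qtl$freq, 0.3)
  expect_equal(cfg2$seed, cfg$seed)
})

test_that("pedigree structure is a valid two-generation intercross", {
  ped <- make_pedigree(small_config())
  expect_s3_class(ped, "pedigree")
  f0 <- ped$id[ped$generation == "F0"]
  f1 <- ped[ped$generation == "F1", ]
  f2 <- ped[ped$generation == "F2", ]
  expect_true(all(f1$sire %in% f0) && all(f1$dam %in% f0))
  expect_true(all(f2$sire %in% f1$id) && all(f2$dam %in% f1$id))
  expect_true(all(is.na(ped$batch[ped$generation != "F2"])))
  expect_true(all(!is.na(f2$batch)))
  expect_equal(nrow(f2), 200)
  # batches near-balanced (round-robin)
  expect_true(diff(range(table(f2$batch))) <= 1)
})

test_that("founder fixation forces monomorphic breeds and heterozygous F1", {
  cfg <- small_config(founder_divergence = list(shape1 = 1, shape2 = 1))
  panel <- simulate_founders(cfg)
  panel$freq_A[] <- 0; panel$freq_B[] <- 1
  ids <- panel$founder_ids
  for (i in seq_along(ids)) {
    f <- if (panel$founder_breed[i] == "A") 0L else 1L
    panel$haplotypes[2 * i - 1, ] <- f
    panel$haplotypes[2 * i, ] <- f
  }
  ped <- make_pedigree(cfg)
  g <- gene_drop(ped, panel, cfg)
  f1 <- g$dosage[g$samples$generation == "F1", ]
  expect_true(all(f1 == 1L))
  # F2 segregate 1:2:1 (single SNP: genotypes independent across meioses;
  # pooling SNPs would double-count linked loci)
  f2 <- g$dosage[g$samples$generation == "F2", ]
  cnt <- tabulate(f2[, 1] + 1L, nbins = 3)
  expect_gt(stats::chisq.test(cnt, p = c(1, 2, 1) / 4)$p.value, 0.01)
})

test_that("simulation is deterministic given the seed", {
  s1 <- simulate_cross(small_config(seed = 5, missing_rate = 0.05,
                                    geno_error_rate = 0.01))
  s2 <- simulate_cross(small_config(seed = 5, missing_rate = 0.05,
                                    geno_error_rate = 0.01))
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  expect_identical(s1$traits, s2$traits)
  s3 <- simulate_cross(small_config(seed = 6, missing_rate = 0.05,
                                    geno_error_rate = 0.01))
  expect_false(identical(s1$genotypes$dosage, s3$genotypes$dosage))
})

test_that("zero divergence gives pooled founder frequency near 0.5", {
  cfg <- small_config(n_snps = 200, n_chromosomes = 2,
                      founder_divergence = list(shape1 = 1e6, shape2 = 1e6))
  panel <- simulate_founders(cfg)
  expect_true(all(abs(panel$freq_A - 0.5) < 0.01))
  # haplotype allele frequency within 3 binomial SD of 0.5
  f <- mean(panel$haplotypes)
  n_allele <- length(panel$haplotypes)
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / n_allele))
})

test_that("gene drop emits zero Mendelian errors before artifact injection", {
  sim <- simulate_cross(small_config(seed = 3), keep_clean = TRUE)
  rates <- mendel_error_rates(sim$clean, sim$pedigree)
  expect_equal(sum(rates$snp_rate), 0)
  expect_equal(sum(rates$sample_rate), 0)
  expect_gt(rates$n_trios, 0)
})

test_that("F2 allele frequencies track the founder-breed mean", {
  cfg <- study_config(seed = 4, n_snps = 100, n_chromosomes = 3, n_F2 = 400)
  panel <- simulate_founders(cfg)
  ped <- make_pedigree(cfg)
  g <- gene_drop(ped, panel, cfg)
  f2 <- g$dosage[g$samples$generation == "F2", ]
  obs <- colMeans(f2) / 2
  # expectation given the realized founder haplotypes actually used: each
  # F2 genome is half breed-A-derived, half breed-B-derived
  hap_A <- panel$haplotypes[rep(panel$founder_breed == "A", each = 2), ]
  hap_B <- panel$haplotypes[rep(panel$founder_breed == "B", each = 2), ]
  expected <- (colMeans(hap_A) + colMeans(hap_B)) / 2
  expect_gt(cor(obs, expected), 0.9)
  expect_lt(mean(abs(obs - expected)), 0.1)
  # and the breed-mean parameterization holds on average
  theo <- (panel$freq_A + panel$freq_B) / 2
  expect_lt(abs(mean(obs) - mean(theo)), 0.05)
})

test_that("genomic kinship of F2 sibs rank-correlates with pedigree kinship", {
  sim <- simulate_cross(small_config(seed = 9, n_snps = 80,
                                     n_chromosomes = 5, n_F2 = 120))
  g2 <- subset_geno(sim$genotypes, samples = sim$traits$id)
  K <- genomic_kinship(g2)
  A <- pedigree_kinship(sim$pedigree)[sim$traits$id, sim$traits$id]
  lt <- lower.tri(A)
  expect_gt(cor(unclass(K)[lt], A[lt], method = "spearman"), 0.5)
})

test_that("artifact injection respects its rates and leaves input unchanged", {
  sim <- simulate_cross(small_config(seed = 2), keep_clean = TRUE)
  cfg0 <- small_config(seed = 2)
  cfg0$missing_rate <- 0; cfg0$geno_error_rate <- 0
  expect_identical(inject_artifacts(sim$clean, cfg0)$dosage, sim$clean$dosage)
  cfg1 <- cfg0; cfg1$missing_rate <- 1
  expect_true(all(is.na(inject_artifacts(sim$clean, cfg1)$dosage)))
  # realized missing fraction within 3 binomial SD at rate 0.1
  cfg2 <- small_config(seed = 2, n_snps = 125, n_chromosomes = 4, n_F2 = 200)
  cfg2$missing_rate <- 0.1
  big <- simulate_cross(cfg2, keep_clean = TRUE)
  nm <- length(big$clean$dosage)
  expect_gt(nm, 1e5)
  frac <- mean(is.na(inject_artifacts(big$clean, cfg2)$dosage))
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / nm))
})

test_that("noise-only traits have variance near the residual variance", {
  cfg <- small_config(seed = 8, n_F2 = 400,
                      traits = list(t = list(qtl = NULL, h2_male = 0,
                                             h2_female = 0, sex_offset = 0,
                                             batch_sd = 0, residual_sd = 1)))
  sim <- simulate_cross(cfg)
  v <- var(sim$traits$t)
  n <- nrow(sim$traits)
  ci <- (n - 1) * v / qchisq(c(0.9995, 0.0005), n - 1)
  expect_true(ci[1] < 1 && 1 < ci[2])
})

test_that("sex mean offset of 72 is recovered by the sex-effect model", {
  cfg <- study_config(seed = 10, n_F2 = 600, n_snps = 40, n_chromosomes = 5,
                      traits = list(fat = list(qtl = NULL, h2_male = 0.2,
                                               h2_female = 0.2,
                                               sex_offset = 72,
                                               batch_sd = 10,
                                               residual_sd = 30)))
  sim <- simulate_cross(cfg)
  fit <- sex_effect_model(sim$traits$fat, sim$traits$sex, sim$traits$batch)
  expect_lt(abs(fit$estimate - 72), 1.96 * fit$se * 1.5)
  expect_lt(fit$p, 1e-6)
})

test_that("per-sex QTL effects are recovered by stratified regression", {
  slopes <- sapply(1:20, function(i) {
    cfg <- study_config(seed = 400 + i, n_snps = 40, n_chromosomes = 3,
                        n_F2 = 300,
                        traits = list(t = list(
                          qtl = data.frame(chrom = 1L, snp = 10L,
                                           effect_male = 0.5,
                                           effect_female = 0, freq = 0.5),
                          h2_male = 0, h2_female = 0, sex_offset = 0,
                          batch_sd = 0, residual_sd = 1)))
    sim <- simulate_cross(cfg, keep_clean = TRUE)
    x <- sim$clean$dosage[sim$traits$id, 10]
    y <- sim$traits$t
    m <- sim$traits$sex == "M"
    c(male = unname(coef(lm(y[m] ~ x[m]))[2]),
      female = unname(coef(lm(y[!m] ~ x[!m]))[2]))
  })
  mm <- rowMeans(slopes)
  se <- apply(slopes, 1, sd) / sqrt(ncol(slopes))
  expect_lt(abs(mm["male"] - 0.5), 3 * se["male"])
  expect_lt(abs(mm["female"] - 0), 3 * se["female"])
})
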