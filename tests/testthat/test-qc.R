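test_that("minor allele frequency counts the rarer allele", {
  expect_equal(minor_allele_frequency(c(0, 0, 0, 0)), 0)
  expect_equal(minor_allele_frequency(c(1, 1, 1, 1)), 0.5)
  expect_equal(minor_allele_frequency(c(0, 1, 2, 2, 1, NA)), 0.4)
  expect_equal(minor_allele_frequency(c(2, 2, 2)), 0)   # folded
  expect_error(minor_allele_frequency(c(NA, NA)), "missing")
})

test_that("HWE exact test matches the combinatorial oracle", {
  expect_equal(hwe_exact_test(10, 0, 0), 1)
  expect_equal(hwe_exact_test(1, 0, 1), hwe_oracle(1, 0, 1))
  expect_equal(hwe_exact_test(3, 5, 2), hwe_oracle(3, 5, 2))
  # a grid of counts, exact agreement
  for (nAA in c(0, 2, 7)) for (nAa in c(0, 3, 10)) for (naa in c(1, 4)) {
    expect_equal(hwe_exact_test(nAA, nAa, naa), hwe_oracle(nAA, nAa, naa),
                 tolerance = 1e-12,
                 label = sprintf("hwe(%d,%d,%d)", nAA, nAa, naa))
  }
  expect_error(hwe_exact_test(0, 0, 0), "undefined")
})

test_that("HWE conditional probabilities sum to one over all outcomes", {
  # p over the admissible heterozygote set is a distribution: the test's
  # p-value at the most probable outcome must be 1
  for (n in c(5, 17, 50)) {
    for (nA in c(1, n %/% 2, n)) {
      hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
      ps <- vapply(hets, function(h)
        hwe_exact_test((nA - h) / 2, h, n - (nA + h) / 2), numeric(1))
      expect_true(all(ps > 0 & ps <= 1))
      expect_equal(max(ps), 1)   # probability-ordering includes everything
    }
  }
})

test_that("Mendelian trio rules flag impossible transmissions", {
  # rows: sire, dam, child ok, child bad
  d <- rbind(sire = c(0L, 0L, 2L, 2L, 0L),
             dam  = c(0L, 2L, 2L, 0L, 1L),
             ok   = c(0L, 1L, 2L, 1L, 1L),
             bad  = c(1L, 0L, 1L, 0L, NA))
  map <- data.frame(chrom = "1", id = paste0("s", 1:5), cM = 1:5,
                    bp = 1:5 * 100L, a1 = "A", a2 = "B")
  samples <- data.frame(id = c("sire", "dam", "ok", "bad"),
                        sex = c("M", "F", "M", "F"), batch = "b1")
  g <- geno_matrix(d, map, samples)
  ped <- data.frame(id = samples$id,
                    sire = c(NA, NA, "sire", "sire"),
                    dam = c(NA, NA, "dam", "dam"))
  r <- mendel_error_rates(g, ped)
  expect_equal(unname(r$sample_rate["ok"]), 0)
  expect_equal(unname(r$sample_rate["bad"]), 1)     # 4 errors / 4 assessable
  expect_equal(unname(r$snp_rate), c(0.5, 0.5, 0.5, 0.5, 0))
  expect_equal(r$n_trios, 2L)
})

test_that("sample QC removes low-call-rate samples per brute force", {
  set.seed(1)
  n <- 6; m <- 200
  d <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  miss <- c(0.95, 0.5, 0.05, 0, 0, 0)
  for (i in 1:n) d[i, sample(m, round(miss[i] * m))] <- NA
  g <- toy_geno(d)
  ped <- data.frame(id = g$samples$id, sire = NA_character_,
                    dam = NA_character_)
  res <- suppressWarnings(sample_qc(g, ped, call_rate_min = 0.9,
                                    mendel_rate_max = 0.05))
  brute_keep <- rowMeans(!is.na(d)) > 0.9
  expect_equal(res$genotypes$samples$id, g$samples$id[brute_keep])
  expect_equal(res$report$n_retained + length(res$report$removed_ids), n)
  # fully-missing sample removed even at the permissive 0.1 default
  res2 <- suppressWarnings(sample_qc(g, ped))
  expect_equal(sum(rowMeans(!is.na(d)) <= 0.1),
               n - res2$report$n_retained)
  # clean data: no-op
  res3 <- suppressWarnings(sample_qc(toy_geno(matrix(1L, 4, 5)), ped))
  expect_equal(res3$report$n_retained, 4)
  expect_equal(sum(res3$report$removed), 0)
})

test_that("SNP QC equals brute-force reapplication of all four filters", {
  sim <- simulate_cross(small_config(seed = 31, n_snps = 100,
                                     n_chromosomes = 4, n_F2 = 150,
                                     missing_rate = 0.03,
                                     geno_error_rate = 0.02),
                        keep_clean = TRUE)
  g <- sim$genotypes
  # inject gross violations: one SNP mostly missing, one monomorphic
  g$dosage[1:140, 3] <- NA
  g$dosage[, 7] <- 1L
  g$dosage[, 9] <- 0L
  res <- snp_qc(g, sim$pedigree)
  d <- g$dosage
  cr <- colMeans(!is.na(d))
  maf <- sapply(seq_len(ncol(d)), function(j) {
    x <- d[, j][!is.na(d[, j])]
    if (!length(x)) return(0)
    p <- sum(x) / (2 * length(x)); min(p, 1 - p)
  })
  hwe <- sapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    hwe_exact_test(sum(x == 2, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                   sum(x == 0, na.rm = TRUE))
  })
  mend <- mendel_error_rates(g, sim$pedigree)$snp_rate
  brute <- cr > 0.9 & maf > 0.05 & hwe > 1e-6 & mend < 0.1
  expect_equal(res$genotypes$map$id, g$map$id[brute])
  expect_equal(res$report$n_snp, sum(brute))
  expect_false("snp_1_0007" %in% res$genotypes$map$id)
})

test_that("stricter thresholds retain a subset (filter monotonicity)", {
  sim <- simulate_cross(small_config(seed = 32, n_snps = 80,
                                     n_chromosomes = 3, n_F2 = 120,
                                     missing_rate = 0.05,
                                     geno_error_rate = 0.02))
  loose <- snp_qc(sim$genotypes, sim$pedigree, call_rate_min = 0.8,
                  maf_min = 0.01, hwe_p_min = 1e-8, mendel_rate_max = 0.2)
  strict <- snp_qc(sim$genotypes, sim$pedigree, call_rate_min = 0.95,
                   maf_min = 0.1, hwe_p_min = 1e-4, mendel_rate_max = 0.05)
  expect_true(all(strict$genotypes$map$id %in% loose$genotypes$map$id))
})

test_that("QC retained sets are invariant to sample and SNP order", {
  sim <- simulate_cross(small_config(seed = 33, n_snps = 40,
                                     n_chromosomes = 2, n_F2 = 80,
                                     missing_rate = 0.05,
                                     geno_error_rate = 0.02))
  g <- sim$genotypes
  res1 <- snp_qc(g, sim$pedigree)
  perm <- sample(nrow(g$dosage))
  gp <- subset_geno(g, samples = perm)
  res2 <- snp_qc(gp, sim$pedigree)
  expect_setequal(res1$genotypes$map$id, res2$genotypes$map$id)
})
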