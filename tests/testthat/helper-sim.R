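# Shared fixtures: small F2 configurations built in code.

small_config <- function(seed = 1, n_snps = 30, n_chromosomes = 4,
                         n_F2 = 200, include_x = TRUE,
                         traits = list(t1 = list(qtl = NULL, h2_male = 0.4,
                                                 h2_female = 0.4,
                                                 sex_offset = 0,
                                                 batch_sd = 0.2,
                                                 residual_sd = 1)),
                         missing_rate = 0, geno_error_rate = 0, ...) {
  sim_config(n_snps = n_snps, n_chromosomes = n_chromosomes,
             include_x = include_x,
             pedigree_counts = list(n_sires_F0 = 2, n_dams_F0 = 4,
                                    n_sires_F1 = 3, n_dams_F1 = 6,
                                    n_F2 = n_F2, n_batches = 3),
             traits = traits, missing_rate = missing_rate,
             geno_error_rate = geno_error_rate, seed = seed, ...)
}

# study-shaped pedigree at reduced F2 count
study_config <- function(seed = 1, n_F2 = 500, n_snps = 100,
                         n_chromosomes = 18, include_x = FALSE,
                         traits = list(t1 = list(qtl = NULL, h2_male = 0.4,
                                                 h2_female = 0.4,
                                                 sex_offset = 0,
                                                 batch_sd = 0.25,
                                                 residual_sd = 1)),
                         missing_rate = 0, geno_error_rate = 0, ...) {
  sim_config(n_snps = n_snps, n_chromosomes = n_chromosomes,
             include_x = include_x,
             pedigree_counts = list(n_sires_F0 = 2, n_dams_F0 = 17,
                                    n_sires_F1 = 9, n_dams_F1 = 59,
                                    n_F2 = n_F2, n_batches = 6),
             traits = traits, missing_rate = missing_rate,
             geno_error_rate = geno_error_rate, seed = seed, ...)
}

# tiny hand-buildable geno_matrix
toy_geno <- function(dosage, sex = NULL, batch = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  map <- data.frame(chrom = "1", id = sprintf("s%02d", seq_len(m)),
                    cM = seq_len(m), bp = seq_len(m) * 1000L,
                    a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  samples <- data.frame(id = sprintf("i%02d", seq_len(n)),
                        sex = sex %||% rep(c("M", "F"), length.out = n),
                        batch = batch %||% rep("b1", n),
                        stringsAsFactors = FALSE)
  geno_matrix(dosage, map, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent HWE oracle: direct combinatoric probability of each
# heterozygote count given allele totals, summed over outcomes at most as
# probable as the observed one
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  # multinomial-coefficient route: #arrangements with h het pairs ~
  # n! / (nAA! h! naa!) * 2^h, normalized over the admissible het counts
  pr <- vapply(hets, function(h) {
    naa <- (nA - h) / 2
    nbb <- n - naa - h
    exp(lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
          h * log(2))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  sum(pr[pr <= obs + 1e-12 * obs])
}
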