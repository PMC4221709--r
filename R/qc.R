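#' Minor allele frequency of a dosage vector
#'
#' Frequency of the rarer allele among non-missing calls; always in
#' [0, 0.5].
#'
#' @param dosages vector of 0/1/2/NA allele-1 counts.
#' @return frequency in [0, 0.5].
#' @export
minor_allele_frequency <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) stop("undefined input: all genotypes missing", call. = FALSE)
  p <- sum(d) / (2 * length(d))
  min(p, 1 - p)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the observed allele counts, enumerates all
#' heterozygote counts of the same parity and sums the probabilities of
#' outcomes no more probable than the observed one (two-sided,
#' probability-ordering). Suited to small genotype classes where the
#' chi-square approximation fails.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0) || n_AA + n_Aa + n_aa == 0)
    stop("undefined input: genotype counts must be non-negative with positive sum",
         call. = FALSE)
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa            # rarer-or-not does not matter: symmetric
  het <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  # P(n_Aa = h | n, nA) via log factorials
  logp <- lfactorial(n) - lfactorial((nA - het) / 2) - lfactorial(het) -
    lfactorial(n - (nA + het) / 2) + het * log(2) +
    lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, het)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Mendelian-inconsistency rates per SNP and per sample
#'
#' Resolves parent-offspring trios from the pedigree (both parents present
#' in the genotype data) and flags an (offspring, SNP) call as an error when
#' the offspring dosage is impossible given both parents' non-missing
#' dosages at a biallelic locus. Rates are errors over assessable calls;
#' individuals outside resolvable trios contribute nothing.
#'
#' @param g a [geno_matrix()].
#' @param pedigree pedigree data.frame (`id`, `sire`, `dam`).
#' @return list with `snp_rate` (per SNP), `sample_rate` (per sample, 0 for
#'   non-offspring), `n_trios`.
#' @export
mendel_error_rates <- function(g, pedigree) {
  ids <- g$samples$id
  ped <- pedigree[match(ids, pedigree$id), , drop = FALSE]
  off <- which(!is.na(ped$sire) & !is.na(ped$dam) &
                 ped$sire %in% ids & ped$dam %in% ids)
  m <- ncol(g$dosage)
  snp_err <- snp_tot <- numeric(m)
  sample_rate <- stats::setNames(numeric(length(ids)), ids)
  if (!length(off)) {
    warning("no resolvable trio; all Mendelian rates are 0")
    return(list(snp_rate = stats::setNames(numeric(m), g$map$id),
                sample_rate = sample_rate, n_trios = 0L))
  }
  C <- g$dosage[off, , drop = FALSE]
  S <- g$dosage[match(ped$sire[off], ids), , drop = FALSE]
  D <- g$dosage[match(ped$dam[off], ids), , drop = FALSE]
  ok <- !is.na(C) & !is.na(S) & !is.na(D)
  # impossible iff child carries an allele count no parent pair can supply
  err <- ok & (((S == 0 | D == 0) & C == 2) |
                 ((S == 2 | D == 2) & C == 0) |
                 (S == 0 & D == 0 & C != 0) |
                 (S == 2 & D == 2 & C != 2) |
                 (((S == 0 & D == 2) | (S == 2 & D == 0)) & C != 1))
  snp_err <- colSums(err); snp_tot <- colSums(ok)
  samp_err <- rowSums(err); samp_tot <- rowSums(ok)
  sample_rate[off] <- ifelse(samp_tot > 0, samp_err / samp_tot, 0)
  list(snp_rate = stats::setNames(ifelse(snp_tot > 0, snp_err / snp_tot, 0),
                                  g$map$id),
       sample_rate = sample_rate, n_trios = length(off))
}

#' Sample-level quality control
#'
#' Removes samples with SNP call rate at or below `call_rate_min` or
#' per-sample Mendelian inconsistency rate at or above `mendel_rate_max`
#' (strict inequalities retain, mirroring "greater than" / "smaller than"
#' filter phrasing).
#'
#' @param g a [geno_matrix()].
#' @param pedigree pedigree for trio resolution.
#' @param call_rate_min retain samples with call rate strictly above this.
#'   The default 0.10 reads the protocol literally; 0.90 is the
#'   conventional alternative.
#' @param mendel_rate_max retain samples with Mendelian rate strictly below.
#' @return list `(genotypes, report)`; the `qc_report` itemizes removals.
#' @export
sample_qc <- function(g, pedigree, call_rate_min = 0.10,
                      mendel_rate_max = 0.05) {
  stopifnot(call_rate_min >= 0, call_rate_min <= 1,
            mendel_rate_max >= 0, mendel_rate_max <= 1)
  call_rate <- rowMeans(!is.na(g$dosage))
  mend <- mendel_error_rates(g, pedigree)$sample_rate
  fail_call <- !(call_rate > call_rate_min)
  fail_mend <- !(mend < mendel_rate_max)
  keep <- !(fail_call | fail_mend)
  if (!any(keep))
    stop("degenerate output: no samples survive sample QC", call. = FALSE)
  report <- structure(list(
    stage = "sample_qc",
    thresholds = c(call_rate_min = call_rate_min,
                   mendel_rate_max = mendel_rate_max),
    removed = c(call_rate = sum(fail_call),
                mendel = sum(fail_mend & !fail_call)),
    removed_ids = g$samples$id[!keep],
    n_input = nrow(g$dosage), n_retained = sum(keep)),
    class = "qc_report")
  list(genotypes = subset_geno(g, samples = keep), report = report)
}

#' SNP-level quality control
#'
#' Keeps SNPs passing all four filters simultaneously: call rate strictly
#' above `call_rate_min`, minor allele frequency strictly above `maf_min`,
#' Hardy-Weinberg exact-test p strictly above `hwe_p_min`, and Mendelian
#' error rate strictly below `mendel_rate_max`.
#'
#' @inheritParams sample_qc
#' @param call_rate_min,maf_min,hwe_p_min,mendel_rate_max filter thresholds.
#' @return list `(genotypes, report)`; `report$n_snp` is the retained SNP
#'   count used for downstream significance thresholds.
#' @export
snp_qc <- function(g, pedigree, call_rate_min = 0.9, maf_min = 0.05,
                   hwe_p_min = 1e-6, mendel_rate_max = 0.1) {
  for (t in c(call_rate_min, maf_min, hwe_p_min, mendel_rate_max))
    stopifnot(t >= 0, t <= 1)
  d <- g$dosage
  call_rate <- colMeans(!is.na(d))
  maf <- apply(d, 2, function(x)
    if (all(is.na(x))) 0 else minor_allele_frequency(x))
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    cnt <- c(sum(x == 2, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
             sum(x == 0, na.rm = TRUE))
    if (sum(cnt) == 0) return(0)
    hwe_exact_test(cnt[1], cnt[2], cnt[3])
  }, numeric(1))
  mend <- mendel_error_rates(g, pedigree)$snp_rate

  pass <- (call_rate > call_rate_min) & (maf > maf_min) &
    (hwe_p > hwe_p_min) & (mend < mendel_rate_max)
  if (!any(pass))
    stop("degenerate output: no SNPs survive SNP QC", call. = FALSE)
  report <- structure(list(
    stage = "snp_qc",
    thresholds = c(call_rate_min = call_rate_min, maf_min = maf_min,
                   hwe_p_min = hwe_p_min, mendel_rate_max = mendel_rate_max),
    removed = c(call_rate = sum(!(call_rate > call_rate_min)),
                maf = sum(call_rate > call_rate_min & !(maf > maf_min)),
                hwe = sum(call_rate > call_rate_min & maf > maf_min &
                            !(hwe_p > hwe_p_min)),
                mendel = sum(call_rate > call_rate_min & maf > maf_min &
                               hwe_p > hwe_p_min & !(mend < mendel_rate_max))),
    removed_ids = g$map$id[!pass],
    n_input = ncol(d), n_retained = sum(pass), n_snp = sum(pass)),
    class = "qc_report")
  list(genotypes = subset_geno(g, snps = pass), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("%s: %d -> %d retained\n", x$stage, x$n_input, x$n_retained))
  for (nm in names(x$removed))
    cat(sprintf("  removed by %-10s %d\n", paste0(nm, ":"), x$removed[[nm]]))
  invisible(x)
}

#' Write a QC report as a tab-delimited table
#' @param report a `qc_report`.
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(stage = report$stage,
                   filter = c(names(report$removed), "retained"),
                   count = c(unname(report$removed), report$n_retained))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
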