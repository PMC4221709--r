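#' Simulate divergent founder breeds
#'
#' Draws per-SNP allele frequencies for the two founder breeds from mirrored
#' Beta distributions (breed A ~ Beta(shape1, shape2), breed B ~
#' Beta(shape2, shape1)), then samples phased founder haplotypes from those
#' frequencies. QTL SNPs with a forced `freq` in the trait architecture get
#' that frequency in both breeds, which pins their expected F2 allele
#' frequency.
#'
#' @param config a [sim_config()].
#' @return object of class `founder_panel`: list with `map` (SNP map),
#'   `freq_A`, `freq_B` (per-SNP allele-1 frequencies) and `haplotypes`
#'   (2*n_founders x n_snps 0/1 matrix; rows `<id>.1`, `<id>.2`), plus
#'   `founder_ids` and `founder_breed` ("A" for F0 sires, "B" for F0 dams).
#' @export
simulate_founders <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "founders"))
  n_chr <- config$n_chromosomes + as.integer(config$include_x)
  chroms <- as.character(seq_len(config$n_chromosomes))
  if (config$include_x) chroms <- c(chroms, "X")
  m <- config$n_snps * n_chr

  # uniform random map positions, sorted within chromosome
  pos <- lapply(seq_len(n_chr), function(i)
    sort(stats::runif(config$n_snps, 0, config$chrom_length_cM)))
  map <- data.frame(
    chrom = rep(chroms, each = config$n_snps),
    id = sprintf("snp_%s_%04d", rep(chroms, each = config$n_snps),
                 rep(seq_len(config$n_snps), n_chr)),
    cM = unlist(pos),
    bp = as.integer(round(unlist(pos) * 1e6)) + rep(seq_len(config$n_snps), n_chr),
    a1 = "A", a2 = "B", stringsAsFactors = FALSE)

  fd <- config$founder_divergence
  freq_A <- stats::rbeta(m, fd$shape1, fd$shape2)
  freq_B <- stats::rbeta(m, fd$shape2, fd$shape1)
  # pin forced QTL frequencies (autosomes only; QTL never sit on X)
  for (tr in config$traits) {
    q <- tr$qtl
    if (!is.null(q) && !is.null(q$freq)) {
      keep <- !is.na(q$freq)
      idx <- (q$chrom[keep] - 1L) * config$n_snps + q$snp[keep]
      freq_A[idx] <- freq_B[idx] <- q$freq[keep]
    }
  }

  pc <- config$pedigree_counts
  founder_ids <- c(sprintf("F0S%02d", seq_len(pc$n_sires_F0)),
                   sprintf("F0D%02d", seq_len(pc$n_dams_F0)))
  founder_breed <- rep(c("A", "B"), c(pc$n_sires_F0, pc$n_dams_F0))
  nf <- length(founder_ids)
  hap <- matrix(0L, nrow = 2L * nf, ncol = m)
  rownames(hap) <- paste(rep(founder_ids, each = 2L), 1:2, sep = ".")
  for (i in seq_len(nf)) {
    f <- if (founder_breed[i] == "A") freq_A else freq_B
    hap[2L * i - 1L, ] <- as.integer(stats::runif(m) < f)
    hap[2L * i, ]      <- as.integer(stats::runif(m) < f)
  }
  structure(list(map = map, freq_A = freq_A, freq_B = freq_B,
                 haplotypes = hap, founder_ids = founder_ids,
                 founder_breed = founder_breed),
            class = "founder_panel")
}
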