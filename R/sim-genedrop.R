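#' Drop founder genes through the pedigree
#'
#' Transmits founder haplotypes to F1 and F2 by simulated meiosis: per
#' chromosome the number of crossovers is Poisson(map length in Morgans)
#' with breakpoints uniform on the map (Haldane, no interference) and a
#' fair-coin starting strand. Offspring dosage is the sum of the two
#' inherited haplotypes, so the emitted genotypes contain no Mendelian
#' errors by construction.
#'
#' @param pedigree from [make_pedigree()].
#' @param panel from [simulate_founders()].
#' @param config the [sim_config()] (map length, seed).
#' @return a [geno_matrix()] covering all pedigree members, with `sire`,
#'   `dam`, `generation` carried in `$samples`.
#' @export
gene_drop <- function(pedigree, panel, config) {
  validate_pedigree(pedigree)
  if (ncol(panel$haplotypes) != nrow(panel$map))
    stop("structural error: panel haplotypes do not cover the SNP map",
         call. = FALSE)
  set.seed(stage_seed(config$seed, "genedrop"))
  map <- panel$map
  m <- nrow(map)
  n <- nrow(pedigree)
  chroms <- unique(map$chrom)
  chr_idx <- lapply(chroms, function(ch) which(map$chrom == ch))
  names(chr_idx) <- chroms
  L_morgan <- config$chrom_length_cM / 100

  # haplotype store: 2 rows per individual
  H <- matrix(NA_integer_, nrow = 2L * n, ncol = m)
  rownames(H) <- paste(rep(pedigree$id, each = 2L), 1:2, sep = ".")
  fi <- match(paste(rep(panel$founder_ids, each = 2L), 1:2, sep = "."),
              rownames(panel$haplotypes))
  H[paste(rep(panel$founder_ids, each = 2L), 1:2, sep = "."), ] <-
    panel$haplotypes[fi, ]

  meiosis <- function(h1, h2) {
    gamete <- integer(m)
    for (ch in chroms) {
      ii <- chr_idx[[ch]]
      cm <- map$cM[ii]
      k <- stats::rpois(1L, L_morgan)
      cuts <- if (k > 0L) sort(stats::runif(k, 0, config$chrom_length_cM)) else numeric(0)
      # strand index at each locus: start + number of crossovers before it
      strand <- (ifelse(stats::runif(1L) < 0.5, 0L, 1L) +
                   findInterval(cm, cuts)) %% 2L
      gamete[ii] <- ifelse(strand == 0L, h1[ii], h2[ii])
    }
    gamete
  }

  si <- match(pedigree$sire, pedigree$id)
  di <- match(pedigree$dam, pedigree$id)
  if (any(xor(is.na(si), is.na(di))))
    stop("structural error: individuals must have both parents or none",
         call. = FALSE)
  for (i in seq_len(n)) {
    if (is.na(si[i])) next
    if (si[i] >= i || di[i] >= i)
      stop("structural error: pedigree not sorted parents-first (cycle?)",
           call. = FALSE)
    H[2L * i - 1L, ] <- meiosis(H[2L * si[i] - 1L, ], H[2L * si[i], ])
    H[2L * i, ]      <- meiosis(H[2L * di[i] - 1L, ], H[2L * di[i], ])
  }

  dosage <- H[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  samples <- data.frame(id = pedigree$id, sex = pedigree$sex,
                        batch = pedigree$batch, sire = pedigree$sire,
                        dam = pedigree$dam, generation = pedigree$generation,
                        stringsAsFactors = FALSE)
  geno_matrix(dosage, map, samples)
}

#' Inject missingness and genotyping error
#'
#' Independently sets calls missing at `missing_rate` and perturbs calls to
#' a random *other* dosage at `geno_error_rate` (error applied first, then
#' missingness). The input object is not modified.
#'
#' @param genotypes a [geno_matrix()].
#' @param config the [sim_config()] carrying the rates and seed.
#' @return a new [geno_matrix()].
#' @export
inject_artifacts <- function(genotypes, config) {
  for (r in c(config$missing_rate, config$geno_error_rate))
    if (r < 0 || r > 1) stop("configuration error: rates must lie in [0, 1]",
                             call. = FALSE)
  set.seed(stage_seed(config$seed, "artifacts"))
  d <- genotypes$dosage
  nm <- length(d)
  if (config$geno_error_rate > 0) {
    err <- which(stats::runif(nm) < config$geno_error_rate & !is.na(d))
    if (length(err)) {
      # shift by 1 or 2 mod 3 => always a different dosage
      d[err] <- (d[err] + sample(c(1L, 2L), length(err), replace = TRUE)) %% 3L
    }
  }
  if (config$missing_rate > 0) {
    d[stats::runif(nm) < config$missing_rate] <- NA_integer_
  }
  geno_matrix(d, genotypes$map, genotypes$samples)
}
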