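#' Simulation configuration for a two-breed F2 cross
#'
#' Builds and validates the configuration object consumed by
#' [simulate_cross()] and its component stages. Defaults emulate a large
#' White Duroc x Erhualian style intercross: 2 F0 boars x 17 F0 sows produce
#' the F1, 9 F1 boars x 59 F1 sows produce 1912 F2 in 6 batches, genotyped
#' on a ~60K SNP array (18 autosomes plus an autosomally simulated X).
#'
#' @param n_snps SNPs per chromosome.
#' @param n_chromosomes number of autosomes.
#' @param include_x add one X chromosome, simulated autosome-like and
#'   excluded from trait architecture.
#' @param chrom_length_cM genetic map length per chromosome (centimorgans).
#' @param founder_divergence list with Beta shape parameters `shape1`,
#'   `shape2` for breed-A allele frequencies; breed B uses the mirrored
#'   Beta, so the two founder breeds diverge in frequency on average.
#' @param pedigree_counts named list/vector: `n_sires_F0`, `n_dams_F0`,
#'   `n_sires_F1`, `n_dams_F1`, `n_F2`, `n_batches`.
#' @param male_fraction expected fraction of F2 males.
#' @param analyzed_fraction fraction of F2 retained for analysis (the rest
#'   emulate unphenotyped/ungenotyped animals).
#' @param traits named list of trait architectures, each a list with
#'   elements `qtl` (data.frame with columns `chrom`, `snp` (index within
#'   chromosome), `effect_male`, `effect_female` in trait-SD units and
#'   optional `freq` forcing that SNP's allele frequency in both founder
#'   breeds), `h2_male`, `h2_female` (polygenic heritabilities in [0,1)),
#'   `sex_offset` (male minus female mean, trait units), `batch_sd`,
#'   `residual_sd`.
#' @param missing_rate fraction of genotype calls set missing.
#' @param geno_error_rate fraction of calls perturbed to a random other
#'   dosage.
#' @param seed integer seed; every stage derives its stream from it.
#'
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_snps = 3200,
                       n_chromosomes = 18,
                       include_x = TRUE,
                       chrom_length_cM = 100,
                       founder_divergence = list(shape1 = 0.6, shape2 = 1.4),
                       pedigree_counts = list(n_sires_F0 = 2, n_dams_F0 = 17,
                                              n_sires_F1 = 9, n_dams_F1 = 59,
                                              n_F2 = 1912, n_batches = 6),
                       male_fraction = 0.5,
                       analyzed_fraction = 1,
                       traits = list(trait1 = list(qtl = NULL,
                                                   h2_male = 0.4, h2_female = 0.4,
                                                   sex_offset = 0, batch_sd = 0.25,
                                                   residual_sd = 1)),
                       missing_rate = 0.02,
                       geno_error_rate = 0.001,
                       seed = 1L) {
  cfg <- list(n_snps = as.integer(n_snps),
              n_chromosomes = as.integer(n_chromosomes),
              include_x = isTRUE(include_x),
              chrom_length_cM = as.numeric(chrom_length_cM),
              founder_divergence = founder_divergence,
              pedigree_counts = lapply(as.list(pedigree_counts), as.integer),
              male_fraction = as.numeric(male_fraction),
              analyzed_fraction = as.numeric(analyzed_fraction),
              traits = traits,
              missing_rate = as.numeric(missing_rate),
              geno_error_rate = as.numeric(geno_error_rate),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with(cfg, {
    if (n_snps < 1L || n_chromosomes < 1L)
      stop("configuration error: counts must be positive", call. = FALSE)
    if (chrom_length_cM <= 0)
      stop("configuration error: chrom_length_cM must be positive", call. = FALSE)
    fd <- founder_divergence
    if (!is.list(fd) || is.null(fd$shape1) || is.null(fd$shape2) ||
        fd$shape1 <= 0 || fd$shape2 <= 0)
      stop("configuration error: invalid founder divergence parameters",
           call. = FALSE)
    pc <- pedigree_counts
    need <- c("n_sires_F0", "n_dams_F0", "n_sires_F1", "n_dams_F1",
              "n_F2", "n_batches")
    if (!all(need %in% names(pc)) || any(unlist(pc[need]) < 1L))
      stop("configuration error: pedigree counts must be positive and complete",
           call. = FALSE)
    if (pc$n_sires_F1 + pc$n_dams_F1 < 2L)
      stop("configuration error: need F1 parents of both sexes", call. = FALSE)
    for (r in c(missing_rate, geno_error_rate, male_fraction, analyzed_fraction))
      if (r < 0 || r > 1)
        stop("configuration error: rates must lie in [0, 1]", call. = FALSE)
    for (nm in names(traits)) {
      tr <- traits[[nm]]
      for (h in c(tr$h2_male, tr$h2_female))
        if (h < 0 || h >= 1)
          stop("configuration error: heritabilities must lie in [0, 1): trait ",
               nm, call. = FALSE)
      if (tr$residual_sd <= 0)
        stop("configuration error: residual_sd must be positive: trait ", nm,
             call. = FALSE)
      if (!is.null(tr$qtl)) {
        q <- tr$qtl
        if (any(q$chrom < 1L) || any(q$chrom > n_chromosomes) ||
            any(q$snp < 1L) || any(q$snp > n_snps))
          stop("configuration error: QTL index outside SNP range: trait ", nm,
               call. = FALSE)
      }
    }
  })
  invisible(cfg)
}

#' Read / write a simulation configuration as YAML
#'
#' @param cfg a `sim_config` object.
#' @param path file path.
#' @return `read_sim_config()` returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  x <- unclass(cfg)
  x$traits <- lapply(x$traits, function(tr) {
    if (!is.null(tr$qtl)) tr$qtl <- as.list(as.data.frame(tr$qtl))
    tr
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$traits <- lapply(x$traits, function(tr) {
    if (!is.null(tr$qtl)) tr$qtl <- as.data.frame(tr$qtl)
    tr
  })
  do.call(sim_config, x)
}

# Per-stage RNG streams derived from one master seed; offsets keep stages
# independent under reordering. Kept below 2^31.
stage_seed <- function(seed, stage) {
  offs <- c(founders = 11L, pedigree = 23L, genedrop = 37L,
            artifacts = 53L, traits = 71L, subset = 89L)
  as.integer((as.numeric(seed) * 1000 + offs[[stage]]) %% 2147483647)
}
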