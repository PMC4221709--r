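#' Build the F2 mating pedigree
#'
#' Lays out a two-generation intercross: every F0 sire is mated to a share of
#' the F0 dams to produce the F1 parents; F1 sows are split among F1 boars
#' and each mating contributes an equal share of the F2 (remainder spread
#' over the first matings). F2 sex is Bernoulli(`male_fraction`); batches are
#' assigned round-robin.
#'
#' @param config a [sim_config()].
#' @return data.frame of class `pedigree` with columns `id`, `sire`, `dam`,
#'   `generation` ("F0", "F1", "F2"), `sex` ("M"/"F"), `batch` (NA outside F2).
#' @export
make_pedigree <- function(config) {
  validate_sim_config(config)
  pc <- config$pedigree_counts
  set.seed(stage_seed(config$seed, "pedigree"))

  f0_sires <- sprintf("F0S%02d", seq_len(pc$n_sires_F0))
  f0_dams  <- sprintf("F0D%02d", seq_len(pc$n_dams_F0))
  n_f1 <- pc$n_sires_F1 + pc$n_dams_F1
  # each F0 dam mated to one F0 sire (dams split evenly over sires);
  # F1 individuals allocated round-robin over the F0 matings
  dam_sire <- f0_sires[rep_len(seq_along(f0_sires), length(f0_dams))]
  f1_dam  <- f0_dams[rep_len(seq_along(f0_dams), n_f1)]
  f1_sire <- dam_sire[match(f1_dam, f0_dams)]
  f1_sex  <- rep(c("M", "F"), c(pc$n_sires_F1, pc$n_dams_F1))
  f1_id   <- sprintf("F1%s%02d", f1_sex, stats::ave(seq_len(n_f1), f1_sex,
                                                    FUN = seq_along))
  f1_boars <- f1_id[f1_sex == "M"]
  f1_sows  <- f1_id[f1_sex == "F"]

  # F1 sows split among F1 boars; F2 allocated near-equally across matings
  sow_boar <- f1_boars[rep_len(seq_along(f1_boars), length(f1_sows))]
  n_mat <- length(f1_sows)
  per <- rep(pc$n_F2 %/% n_mat, n_mat)
  extra <- pc$n_F2 %% n_mat
  if (extra > 0L) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  f2_dam  <- rep(f1_sows, per)
  f2_sire <- sow_boar[match(f2_dam, f1_sows)]
  f2_sex  <- ifelse(stats::runif(pc$n_F2) < config$male_fraction, "M", "F")
  f2_id   <- sprintf("F2_%05d", seq_len(pc$n_F2))
  f2_batch <- sprintf("b%d", rep_len(seq_len(pc$n_batches), pc$n_F2))

  ped <- data.frame(
    id = c(f0_sires, f0_dams, f1_id, f2_id),
    sire = c(rep(NA_character_, length(f0_sires) + length(f0_dams)),
             f1_sire, f2_sire),
    dam = c(rep(NA_character_, length(f0_sires) + length(f0_dams)),
            f1_dam, f2_dam),
    generation = rep(c("F0", "F1", "F2"),
                     c(length(f0_sires) + length(f0_dams), n_f1, pc$n_F2)),
    sex = c(rep("M", length(f0_sires)), rep("F", length(f0_dams)),
            f1_sex, f2_sex),
    batch = c(rep(NA_character_, length(f0_sires) + length(f0_dams) + n_f1),
              f2_batch),
    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped),
            all(c("id", "sire", "dam", "generation", "sex") %in% names(ped)))
  if (anyDuplicated(ped$id)) stop("structural error: duplicated ids", call. = FALSE)
  gen <- split(ped, ped$generation)
  par_of <- function(g) c(gen[[g]]$sire, gen[[g]]$dam)
  if (!all(par_of("F1") %in% gen$F0$id))
    stop("structural error: F1 parents must be F0", call. = FALSE)
  if (!all(par_of("F2") %in% gen$F1$id))
    stop("structural error: F2 parents must be F1", call. = FALSE)
  invisible(ped)
}

#' Pedigree-expected additive relationship matrix
#'
#' Numerator relationship matrix (tabular method) over all pedigree members;
#' founders are assumed unrelated and non-inbred. This is the expectation of
#' twice the kinship coefficient, the covariance structure used to draw
#' polygenic values in [simulate_traits()] — deliberately distinct from the
#' realized genomic kinship estimated by [genomic_kinship()].
#'
#' @param ped a pedigree (parents must precede offspring).
#' @return n x n matrix with dimnames from `ped$id`.
#' @export
pedigree_kinship <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  if (any(!is.na(si) & si >= seq_len(n)) || any(!is.na(di) & di >= seq_len(n)))
    stop("structural error: parents must precede offspring", call. = FALSE)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (!is.na(s) && !is.na(d)) {
      A[i, i] <- 1 + 0.5 * A[s, d]
      if (i > 1L) {
        j <- seq_len(i - 1L)
        A[i, j] <- A[j, i] <- 0.5 * (A[s, j] + A[d, j])
      }
    } else {
      A[i, i] <- 1
    }
  }
  A
}
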