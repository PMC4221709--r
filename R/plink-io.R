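#' Read a PLINK bed/bim/fam triplet
#'
#' Decodes PLINK 1 binary genotypes (SNP-major, magic bytes 0x6c 0x1b 0x01)
#' into a [geno_matrix()]. Dosages count copies of the bim's first allele
#' (A1, conventionally the minor allele): bed code 00 -> 2, 10 -> 1,
#' 11 -> 0, 01 -> NA. Chromosome "19" and "X" are both accepted as the pig
#' X and normalized to "X".
#'
#' @param path_prefix path without extension; `<prefix>.bed/.bim/.fam` must
#'   exist.
#' @return a [geno_matrix()]; fam sex codes 1/2 become "M"/"F", the fam
#'   family id is kept as `batch` when it looks like a batch label.
#' @export
read_plink <- function(path_prefix) {
  bed <- paste0(path_prefix, ".bed")
  bim <- paste0(path_prefix, ".bim")
  fam <- paste0(path_prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("format error: missing file ", f, call. = FALSE)

  fam_df <- utils::read.table(fam, stringsAsFactors = FALSE,
                              col.names = c("fid", "id", "sire", "dam",
                                            "sex_code", "pheno"))
  bim_df <- utils::read.table(bim, stringsAsFactors = FALSE,
                              col.names = c("chrom", "id", "cM", "bp",
                                            "a1", "a2"))
  bim_df$chrom <- as.character(bim_df$chrom)
  bim_df$chrom[bim_df$chrom == "19"] <- "X"
  n <- nrow(fam_df); m <- nrow(bim_df)

  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("format error: bad magic bytes in ", bed, call. = FALSE)
  if (raw[3] != as.raw(0x01))
    stop("format error: ", bed, " is not SNP-major", call. = FALSE)
  bps <- ceiling(n / 4)                      # bytes per SNP
  if (length(raw) - 3L != bps * m)
    stop("format error: ", bed, " size does not match fam/bim dimensions",
         call. = FALSE)

  codes <- .bed_decode_table()               # 256 x 4 matrix of dosages
  body <- matrix(raw[-(1:3)], nrow = bps, ncol = m)
  idx <- matrix(as.integer(body) + 1L, nrow = bps)
  dosage <- matrix(NA_integer_, nrow = n, ncol = m)
  for (k in 1:4) {
    if (k > n) next
    rows <- seq.int(k, n, by = 4L)
    byte_rows <- ((rows - 1L) %/% 4L) + 1L
    dosage[rows, ] <- codes[cbind(as.vector(idx[byte_rows, , drop = FALSE]),
                                  k)][seq_len(length(rows) * m)]
  }

  sire <- ifelse(fam_df$sire %in% c("0", 0), NA_character_, as.character(fam_df$sire))
  dam <- ifelse(fam_df$dam %in% c("0", 0), NA_character_, as.character(fam_df$dam))
  samples <- data.frame(id = as.character(fam_df$id),
                        sex = c("1" = "M", "2" = "F")[as.character(fam_df$sex_code)],
                        batch = ifelse(fam_df$fid %in% c("0", 0), NA_character_,
                                       as.character(fam_df$fid)),
                        sire = sire, dam = dam, stringsAsFactors = FALSE)
  geno_matrix(dosage, bim_df, samples)
}

# dosage of allele1 for each (byte value, within-byte sample slot)
.bed_decode_table <- function() {
  tab <- matrix(NA_integer_, 256, 4)
  dos <- c(`0` = 2L, `1` = NA, `2` = 1L, `3` = 0L)   # 00,01,10,11
  for (b in 0:255) {
    for (k in 1:4) {
      two <- bitwAnd(bitwShiftR(b, 2L * (k - 1L)), 3L)
      tab[b + 1L, k] <- dos[[two + 1L]]
    }
  }
  tab
}

#' Write a genotype matrix as PLINK bed/bim/fam
#'
#' Inverse of [read_plink()]; `write_plink()` then [read_plink()] recovers
#' the dosage matrix exactly, and re-writing a read triplet is
#' byte-identical for canonical files.
#'
#' @param g a [geno_matrix()].
#' @param path_prefix output path without extension.
#' @return `path_prefix`, invisibly.
#' @export
write_plink <- function(g, path_prefix) {
  n <- nrow(g$dosage); m <- ncol(g$dosage)
  samples <- g$samples
  fid <- if (!is.null(samples$batch)) ifelse(is.na(samples$batch), "0",
                                             samples$batch) else "0"
  sire <- if (!is.null(samples$sire)) ifelse(is.na(samples$sire), "0",
                                             samples$sire) else "0"
  dam <- if (!is.null(samples$dam)) ifelse(is.na(samples$dam), "0",
                                           samples$dam) else "0"
  fam <- data.frame(fid = fid, id = samples$id, sire = sire, dam = dam,
                    sex = c(M = 1L, F = 2L)[samples$sex], pheno = -9L)
  utils::write.table(fam, paste0(path_prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  bim <- g$map[, c("chrom", "id", "cM", "bp", "a1", "a2")]
  utils::write.table(bim, paste0(path_prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")

  code <- c(`2` = 0L, `1` = 2L, `0` = 3L)            # dosage -> 2-bit code
  d <- g$dosage
  v <- matrix(0L, nrow = 4L * ceiling(n / 4), ncol = m)   # zero-bit padding
  v[seq_len(n), ] <- ifelse(is.na(d), 1L, code[as.character(d)])
  k <- seq(1L, nrow(v), by = 4L)
  bytes <- v[k, , drop = FALSE] + 4L * v[k + 1L, , drop = FALSE] +
    16L * v[k + 2L, , drop = FALSE] + 64L * v[k + 3L, , drop = FALSE]
  con <- file(paste0(path_prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(path_prefix)
}
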