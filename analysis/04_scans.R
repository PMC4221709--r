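#!/usr/bin/env Rscript
# Stage 4 — kinship-corrected genome scans, combined and by sex.
#
# Builds the autosomal genomic relationship matrix from the QC'd panel and
# runs, for each trait, three LOCO score scans: males only, females only
# (batch fixed effect) and both sexes combined (sex + batch). Writes one
# scan table per trait/stratum plus Manhattan-ready columns.

suppressPackageStartupMessages(library(sexdimgwas))

g <- read_plink("results/cohort_qc")
pheno <- read.table("results/phenotypes.tsv", header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
g <- subset_geno(g, samples = g$samples$id %in% pheno$id)   # F2 only
pheno <- pheno[match(g$samples$id, pheno$id), ]
stopifnot(!anyNA(pheno$id))
K <- genomic_kinship(g, autosomes_only = TRUE)
thr <- significance_thresholds(ncol(g$dosage))

for (tn in setdiff(names(pheno), c("id", "sex", "batch"))) {
  y <- normality_screen_and_transform(pheno[[tn]])$values
  sc <- stratified_scans(g, y, pheno$sex, pheno$batch, K)
  for (s in c("male", "female", "combined")) {
    write_assoc(sc[[s]]$assoc, sprintf("results/scan_%s_%s.tsv", s, tn))
    manh <- data.frame(SNP = sc[[s]]$assoc$snp, CHR = sc[[s]]$assoc$chrom,
                       BP = sc[[s]]$assoc$bp,
                       LOG10P = -log10(sc[[s]]$assoc$p))
    write.table(manh, sprintf("results/manhattan_%s_%s.tsv", s, tn),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  top <- sc$combined$assoc[which.min(sc$combined$assoc$p), ]
  cat(sprintf("%s: h2 M %.2f / F %.2f; top combined SNP %s (p = %.2g%s)\n",
              tn, sc$male$fit$h2, sc$female$fit$h2, top$snp, top$p,
              if (top$p < thr["suggestive"]) ", suggestive" else ""))
}
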