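#!/usr/bin/env Rscript
# Stage 2 — genotype quality control.
#
# Reads the PLINK cohort from stage 1, applies sample QC (call rate > 0.10,
# per-sample Mendelian inconsistency < 0.05) then SNP QC (call rate > 0.9,
# MAF > 0.05, HWE exact p > 1e-6, Mendelian error rate < 0.1), and writes
# the filtered genotypes plus the per-filter accounting.

suppressPackageStartupMessages(library(sexdimgwas))

g <- read_plink("results/cohort")
ped <- read.table("results/pedigree.tsv", header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)

s <- sample_qc(g, ped)
v <- snp_qc(s$genotypes, ped)
print(s$report)
print(v$report)
write_qc_report(s$report, "results/qc_samples.tsv")
write_qc_report(v$report, "results/qc_snps.tsv")
write_plink(v$genotypes, "results/cohort_qc")

thr <- significance_thresholds(v$report$n_snp)
cat(sprintf("N_snp = %d -> suggestive p < %.3g, genome-wide p < %.3g\n",
            v$report$n_snp, thr["suggestive"], thr["genomewide"]))
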