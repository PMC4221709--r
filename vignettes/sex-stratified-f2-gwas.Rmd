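---
title: "Dissecting sexually dimorphic genetic architecture in an F2 cross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting sexually dimorphic genetic architecture in an F2 cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Many complex traits — fat deposition, meat quality, fatty-acid composition,
hematological parameters — differ between males and females, and part of
that difference is genetic: a locus can act in one sex and be silent, or
act in the opposite direction, in the other. A two-breed F2 intercross is a
powerful setting to look for such loci: crossing two divergent founder
breeds (a handful of F0 boars of one breed to a larger set of F0 sows of
the other, intercrossing the F1, and phenotyping hundreds to thousands of
F2 animals) maximises segregation of breed differences, and rearing all F2
under one management regime strips away most of the environmental noise
that plagues outbred association studies.

`sexdimgwas` implements the complete analysis chain for this design:

1. **Genotype QC** — sample filters (call rate, per-sample Mendelian
   inconsistency) then SNP filters (call rate, MAF, exact Hardy–Weinberg
   test, per-SNP Mendelian error rate), each a strict inequality against
   its threshold.
2. **Phenotype preparation** — Shapiro–Wilk normality screen with a log2
   transform for strongly non-normal traits, derived traits such as the
   meat-colour hue angle H\* = arctan(b\*/a\*), a sex-effect linear model
   with batch adjustment, and FDR q-values across traits.
3. **Mixed-model machinery** — a VanRaden-type genomic relationship matrix,
   single-component REML heritability, and a kinship-corrected score-test
   genome scan.
4. **Dimorphism statistics** — combined and sex-stratified scans, the
   z-test comparing per-sex SNP effects, a sex-label permutation test for
   heritability differences, and the stratified-versus-combined accounting
   of significant SNPs.
5. **A gene-dropping simulator** of the whole design, so every stage is
   testable end to end without access to any real genotypes.

# The generative model behind the simulator

The simulator emulates the mating design of a large pig intercross: by
default 2 F0 boars (breed A) × 17 F0 sows (breed B) produce the F1, 9 F1
boars × 59 F1 sows produce 1912 F2 allocated round-robin to 6 batches.
Founder breeds are divergent: per-SNP allele frequencies are drawn from
mirrored Beta distributions (defaults Beta(0.6, 1.4) for breed A and its
mirror for breed B), so the F2 segregate at high MAF the way a breed cross
does. Meiosis follows a Haldane no-interference model — crossover counts
Poisson(map length in Morgans), breakpoints uniform — on a uniform map
(default 100 cM per chromosome, 18 autosomes plus an autosomally simulated
X that is excluded from kinship and trait architecture). Offspring dosages
are sums of transmitted haplotypes, so pre-artifact genotypes contain zero
Mendelian errors by construction; missingness (default 2%) and genotyping
error (default 0.1%, a perturbation to a different dosage) are injected
afterwards. F2 sex is Bernoulli(1/2) by default and configurable to match
an observed sex ratio.

Traits follow

$$y_i = \mu_{sex(i)} + b_{batch(i)} + \sum_q x_{iq}\,\beta_{q,sex(i)} + u_i + e_i$$

with QTL dosages `x` taken from the clean genotypes, batch effects iid
normal, and residuals N(0, `residual_sd`²). The polygenic value `u` is an
*infinitesimal genomic* term: iid standard-normal effects on every
autosomal non-QTL SNP, summed through the individual's genotypes,
standardized, and scaled per sex to variance
h²/(1−h²)·`residual_sd`², so within each sex the heritability of the
polygenic-plus-residual part equals the configured h². We deliberately
simulate the polygenic term from the realized genomes rather than from the
pedigree-expected relationship matrix: in an F2 the expected kinship is
nearly constant within full-sib families, so a pedigree-drawn polygenic
value carries no signal along the Mendelian-sampling axes that a
SNP-derived kinship measures, and genomic REML would systematically
under-estimate h² (we measured attenuation from 0.6 to roughly 0.25 under
that scheme). With the genomic draw, REML recovers configured
heritabilities within ±0.05 on average at n = 500 (the package's
acceptance suite checks ±0.15 over 10 replicates at h² ∈ {0.2, 0.6}).

QTL effect sizes are specified in trait-SD units (SD of the
polygenic-plus-residual background in the relevant sex). A QTL row may pin
its allele frequency in both founder breeds, which fixes the expected F2
frequency — used throughout the validation studies to plant MAF-0.3 loci.

What the simulator does *not* model: linkage maps estimated from real pig
data (LD decay is entirely recombination-driven here), dominance and
epistasis, maternal/litter environmental effects, sex chromosomes proper
(X is autosome-like), and selection. Passing tests therefore demonstrate
the statistical machinery under a clean additive architecture, not
robustness to those complications.

# Quality control choices

The sample call-rate threshold defaults to 0.10 — the protocol wording
this pipeline mirrors retains samples with call rates *greater than 10%* —
but it is an ordinary argument, and 0.90 is the conventional alternative.
SNP filters (call rate > 0.9, MAF > 0.05, HWE exact p > 1e-6, Mendelian
error rate < 0.1) are applied simultaneously in one pass, after sample QC.
The Hardy–Weinberg test is the exact conditional test (two-sided,
probability ordering over heterozygote counts with the observed allele
totals and parity); a chi-square approximation misbehaves exactly where
the filter operates, in the small-count tail. Mendelian errors are counted
over resolvable trios only — an (offspring, SNP) call is an error iff it
is impossible given both parents' non-missing dosages — and rates divide
by assessable calls. The retained SNP count `N_snp` feeds the per-scan
significance levels: suggestive 1/N_snp (one expected false positive per
scan) and genome-wide 0.05/N_snp.

# Mixed-model and scan choices

Kinship is the allele-frequency-centered cross-product matrix scaled by
Σ2p(1−p), computed from autosomal SNPs with per-SNP mean imputation of
missing dosages (imputation is internal to this computation; association
n counts non-missing calls). REML maximizes the restricted likelihood of
the single variance ratio h² = σ²g/(σ²g+σ²e) in the eigenbasis of K — a
40-point grid bracket refined by golden-section search to 1e-6. A flat
profile (e.g. K = identity) is flagged as unidentifiable rather than
fatal; boundary estimates are flagged.

The per-SNP test is a score test against the null-model residuals: with
V̂ the fitted covariance and g̃ the genotype centered and projected
orthogonal to the fixed effects in the V̂⁻¹ metric,
β = g̃ᵀV̂⁻¹r / g̃ᵀV̂⁻¹g̃, se(β) = (g̃ᵀV̂⁻¹g̃)^(−1/2), and (β/se)² is
referred to chi-square(1). With variance components held fixed this equals
the generalized-least-squares estimate in the joint model (the acceptance
suite verifies agreement to 1e-8).

Scans are leave-one-chromosome-out (LOCO) by default: each chromosome is
scanned against a kinship built from the other autosomes. When the tested
SNP contributes to the kinship it is tested against, part of its own
signal is absorbed by the polygenic term; on the dense simulated panels
(n/m ≈ 0.45) this deflated the between-sex z-statistics to sd ≈ 0.85.
LOCO is the field-standard remedy and is essentially free at these sizes.

# The dimorphism statistics

For each SNP tested in both strata, Z = (β_m − β_f) / √(se_m² + se_f²),
standard normal under equal allelic effects, with SNPs below 5% MAF in
either sex excluded. Two details deserve attention:

- **Sidedness.** Discovery of dimorphism in either direction corresponds
  to a two-sided test on Z, which is the default; one-sided modes
  (`sided = "male"` / `"female"`) are available when the direction is
  prespecified. We treat the direction-free two-sided test as the primary
  mode because dimorphic loci of both polarities are of equal interest.
- **Genomic control.** Every F2 animal has relatives of the other sex, so
  β̂_m and β̂_f are weakly positively correlated and the naive denominator
  slightly overstates the variance of their difference: under null
  simulations we measured sd(Z) ≈ 0.92–0.99 even with LOCO scans. The
  z-scores are therefore genomic-control scaled by default — p-values come
  from Z/√λ_z with λ_z = median(Z²)/0.4549, estimated whenever at least 50
  SNPs are tested (the raw Z is always reported). Under the null this
  restores type-I error to nominal (0.049 on average across seeds) without
  touching genuine signals, whose contribution to the median is
  negligible.

The permutation test for heritability differences fits per-sex REML
(batch covariate, stratum submatrices of one global autosomal kinship —
submatrices rather than re-estimated stratum kinships keep the statistic
comparable across permutations) and compares |h²_m − h²_f| against B
sex-label shuffles that preserve stratum sizes; p = (1 + #{null ≥ obs}) /
(1 + B), never below 1/(B+1). B defaults to 1000; the validation studies
use B = 200.

The stratified-versus-combined comparison counts SNP-trait pairs
significant at a common threshold in any stratified scan versus the
combined scan, reporting the intersection, the stratified-only margin as a
percentage of the combined count, and the shared set as a percentage of
the union. No LD clumping is applied — "loci" are SNP-trait pairs. The
accompanying tail test asks whether stratified-only SNPs sit in the tail
of the |Z| distribution (Welch t-test against all tested SNPs).

# Validation studies and their sizes

The acceptance suite (`tests/testthat/test-acceptance.R`, recomputed by
`scripts/acceptance.R`) runs, at sizes chosen to finish in minutes on one
core while keeping each check well-powered:

- threshold arithmetic at the post-QC SNP count 39 454 (suggestive
  2.5e-5, genome-wide 1.27e-6);
- z-test calibration on a null cohort of 900 F2 (≈450/sex) × 2016 SNPs
  with h² = 0.4 in both sexes — type-I error within 3 binomial SD of 0.05
  and KS uniformity at α = 0.01;
- recovery of a male-only MAF-0.3 QTL (0.6 SD) at the suggestive z
  threshold, and of an opposite-sign (+0.5/−0.5 SD) QTL by the stratified
  scans with an attenuated combined p, each in ≥ 8/10 seeds;
- REML heritability recovery within ±0.15 (mean over 10 replicates,
  n = 500) at h² = 0.2 and 0.6;
- permutation-test type-I error over 50 null traits (100/sex, h² = 0.3,
  B = 200) within 3 binomial SD of 0.05, and ≥ 80% power for an
  h² gap of 0.6 (0.7 vs 0.1) at 300/sex — the null-calibration cohort is
  deliberately smaller than the power cohort so the 50 × 201 REML fits
  stay cheap without weakening the binomial bound, which depends only on
  the number of traits;
- exact equivalences: score scan vs GLS (1e-8 relative), the HWE exact
  test vs direct combinatorial enumeration for *every* genotype table with
  n ≤ 50, SNP QC vs brute-force reapplication of the four filters;
- simulator fidelity: founders fixed for alternative alleles give all-
  heterozygous F1 (exactly), 1:2:1 F2 segregation (chi-square at α = 0.01
  on a single SNP — pooling SNPs would double-count linked loci), and
  zero Mendelian errors pre-injection.

# Numerical and degenerate-input conventions

Monomorphic SNPs are skipped in scans with a reason code, not dropped
silently. A stratum below 30 phenotyped individuals is skipped while the
other scans still run. Zero-variance traits are flagged degenerate in the
sex-effect model; confounded designs (sex within batch) raise
identifiability errors. q-values default to Benjamini–Hochberg (π₀ = 1),
the conservative special case of Storey's estimator, with `pi0 = "storey"`
available; the fold difference between sexes is always computed on the
untransformed scale. The log2 transform refuses non-positive values unless
an explicit offset is supplied. All randomness flows from a single integer
seed through fixed per-stage offsets, so every artefact is bit-reproducible.

# Known limitations

Heritability comparisons are internal to this pipeline: the kinship
estimator (centered cross-product, no extra factor of 2 in var(u) = σ²g K)
fixes a scale, and h² values are not calibrated against other software's
conventions. X-linked SNPs are scanned with autosomal coding and excluded
from kinship. The z-test's genomic control corrects a global scale
miscalibration but not SNP-specific cross-stratum covariance; formal
genotype-by-sex interaction models are out of scope, as are LD clumping,
conditional analysis and candidate-gene annotation.
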