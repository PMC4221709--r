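Package: sexdimgwas
Title: Sex-Stratified Genome Scans and Sexual-Dimorphism Statistics for F2 Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting sexually dimorphic genetic architecture in
    experimental F2 crosses: a gene-dropping simulator of a two-breed F2
    design with sex-specific trait architectures, PLINK binary genotype
    input/output with SNP and sample quality control (exact Hardy-Weinberg
    test, Mendelian-error screening), phenotype preparation (normality
    screening with log2 transform, sex-effect linear models, FDR q-values),
    genomic-kinship REML heritability and kinship-corrected score-test
    association scans run combined and separately by sex, a z-statistic test
    for sex-differential SNP effects, and a sex-label permutation test for
    heritability differences between males and females.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
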