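#' Run the full sex-stratified analysis pipeline
#'
#' Executes simulate (optional) -> sample/SNP QC -> phenotype preparation ->
#' combined and sex-stratified scans -> z-dimorphism -> scan comparison ->
#' heritability permutation test, writing every stage's table under
#' `outdir` and returning a manifest of seeds, checksums and timings.
#'
#' @param config list with elements `simulation` (a [sim_config()]) *or*
#'   `genotypes` (PLINK prefix) + `phenotypes` + `pedigree` (file paths);
#'   optional `qc` (threshold overrides), `permutations` (B, default 1000),
#'   `maf_min` (z-test guard, default 0.05), `threshold`
#'   ("suggestive"/"genomewide"/numeric, default "suggestive").
#' @param outdir output directory (created).
#' @param seed master seed; stages derive their streams from it.
#' @return list of class `run_manifest`: `version`, `seed`, `config_hash`,
#'   `stages` (per-stage timing), `checksums` (md5 per output file),
#'   `n_snp`, `thresholds`.
#' @export
run_pipeline <- function(config, outdir, seed = 1) {
  t0 <- Sys.time()
  if (is.null(config$simulation) &&
      (is.null(config$genotypes) || is.null(config$phenotypes) ||
         is.null(config$pedigree)))
    stop("validation error: config needs a simulation block or genotype/",
         "phenotype/pedigree paths", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  tick <- function(name, expr) {
    t <- system.time(res <- force(expr))
    stages[[name]] <<- unname(t["elapsed"])
    res
  }

  if (!is.null(config$simulation)) {
    scfg <- config$simulation
    scfg$seed <- as.integer(seed)
    scfg <- do.call(sim_config, scfg[setdiff(names(scfg), NULL)])
    sim <- tick("simulate", simulate_cross(scfg))
    gsub_ids <- sim$analyzed_ids
    write_plink(sim$genotypes, file.path(outdir, "genotypes"))
    utils::write.table(sim$traits, file.path(outdir, "phenotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$pedigree, file.path(outdir, "pedigree.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    geno <- sim$genotypes
    ped <- sim$pedigree
    pheno <- sim$traits
  } else {
    geno <- tick("read", read_plink(config$genotypes))
    pheno <- utils::read.table(config$phenotypes, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    ped <- utils::read.table(config$pedigree, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    gsub_ids <- intersect(geno$samples$id, pheno$id)
  }

  qc_args <- config$qc %||% list()
  sqc <- tick("sample_qc", do.call(sample_qc, c(list(geno, ped),
    qc_args[intersect(names(qc_args), c("call_rate_min", "mendel_rate_max"))])))
  vqc <- tick("snp_qc", snp_qc(sqc$genotypes, ped))
  write_qc_report(sqc$report, file.path(outdir, "qc_samples.tsv"))
  write_qc_report(vqc$report, file.path(outdir, "qc_snps.tsv"))
  g <- vqc$genotypes
  n_snp <- vqc$report$n_snp
  thr <- significance_thresholds(n_snp)
  threshold <- config$threshold %||% "suggestive"
  if (is.character(threshold)) threshold <- thr[[threshold]]

  # restrict to analyzed individuals with phenotypes
  keep <- g$samples$id %in% intersect(gsub_ids, pheno$id)
  g <- subset_geno(g, samples = keep)
  pheno <- pheno[match(g$samples$id, pheno$id), , drop = FALSE]

  screen <- tick("pheno_prep", sex_effect_screen(pheno))
  utils::write.table(screen, file.path(outdir, "sex_effects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  K <- tick("kinship", genomic_kinship(g, autosomes_only = TRUE))
  trait_names <- setdiff(names(pheno), c("id", "sex", "batch"))
  B <- config$permutations %||% 1000
  h2_rows <- list(); strat_keys <- list(); comb_keys <- list()
  for (tn in trait_names) {
    y <- normality_screen_and_transform(pheno[[tn]])$values
    sc <- tick(paste0("scan_", tn),
               stratified_scans(g, y, pheno$sex, pheno$batch, K))
    write_assoc(sc$combined$assoc, file.path(outdir, paste0("scan_combined_",
                                                            tn, ".tsv")))
    if (is.null(sc$male$skipped) && is.null(sc$female$skipped)) {
      write_assoc(sc$male$assoc, file.path(outdir, paste0("scan_male_", tn, ".tsv")))
      write_assoc(sc$female$assoc, file.path(outdir, paste0("scan_female_", tn, ".tsv")))
      zd <- z_dimorphism(sc$male$assoc, sc$female$assoc,
                         maf_min = config$maf_min %||% 0.05)
      write_sexdim(zd, file.path(outdir, paste0("dimorphism_", tn, ".tsv")))
      strat_keys[[tn]] <- data.frame(
        key = paste(tn, sc$male$assoc$snp),
        p = pmin(sc$male$assoc$p, sc$female$assoc$p, na.rm = TRUE))
      ht <- tick(paste0("h2perm_", tn),
                 heritability_permutation_test(y, pheno$sex, pheno$batch, K,
                                               B = B, seed = seed + 7L))
      h2_rows[[tn]] <- data.frame(trait = tn, h2_male = ht$h2_male,
                                  h2_female = ht$h2_female,
                                  abs_diff = ht$observed, B = ht$B,
                                  p_perm = ht$p)
    }
    comb_keys[[tn]] <- data.frame(key = paste(tn, sc$combined$assoc$snp),
                                  p = sc$combined$assoc$p)
  }
  if (length(h2_rows)) {
    h2_tab <- do.call(rbind, h2_rows)
    utils::write.table(h2_tab, file.path(outdir, "heritability.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cmp <- compare_scans(do.call(rbind, strat_keys), do.call(rbind, comb_keys),
                       threshold)
  writeLines(utils::capture.output(print(cmp)),
             file.path(outdir, "scan_comparison.txt"))

  files <- list.files(outdir, full.names = TRUE)
  files <- files[!grepl("manifest", files)]
  manifest <- structure(list(
    version = as.character(utils::packageVersion("sexdimgwas")),
    seed = seed,
    config_hash = unname(tools::md5sum(write_config_tmp(config))),
    n_snp = n_snp, thresholds = thr,
    stages = stages,
    checksums = tools::md5sum(sort(files)),
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "run_manifest")
  jsonlite::write_json(
    list(version = manifest$version, seed = manifest$seed,
         config_hash = manifest$config_hash, n_snp = manifest$n_snp,
         checksums = as.list(manifest$checksums)),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  manifest
}

write_config_tmp <- function(config) {
  f <- tempfile(fileext = ".yaml")
  ser <- rapply(config, function(x) x, how = "replace")
  yaml::write_yaml(ser, f)
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a
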