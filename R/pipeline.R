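# End-to-end orchestration: simulate a dataset to disk, or run
# QC -> burden -> fluid g -> association grid over an on-disk dataset,
# writing every stage product as TSV.

#' Simulate a cohort and write it to disk
#'
#' @param config A [sim_config()] (or path to a YAML config file).
#' @param out_dir Output directory.
#' @return Invisibly, the named vector of written paths.
#' @export
cmd_simulate <- function(config = sim_config(), out_dir) {
  if (is.character(config)) config <- read_sim_config(config)
  sim <- simulate_cohort(config)
  paths <- write_sim_dataset(sim, out_dir)
  inform(sprintf("simulated %d samples x %d variants into %s",
                 n_samples(sim$genotypes), n_variants(sim$genotypes),
                 out_dir))
  invisible(paths)
}

#' Run the full burden-association pipeline over an on-disk dataset
#'
#' Reads a PLINK trio, annotation and phenotype table; applies the QC
#' cascade; computes burden tables at each MAF threshold; derives the fluid
#' g factor from the battery columns; fits the association sensitivity
#' grid; and writes a QC report, burden tables, g scores and loadings, the
#' association table and a descriptives table (means and s.d. of ages, MHT
#' scores and burden totals at each threshold) into `out_dir`.
#'
#' @param bed_path,bim_path,fam_path PLINK trio paths.
#' @param annotation_path Annotation TSV (`variant_id`, `class`).
#' @param phenotype_path Phenotype TSV (see [read_phenotypes()]).
#' @param out_dir Output directory.
#' @param maf_thresholds MAF thresholds for the sensitivity grid.
#' @param missing_policy Burden missing-call policy.
#' @param outlier_sd Burden-outlier rule (s.d. units).
#' @param snp_callrate,sample_callrate QC call-rate thresholds.
#' @param m Bonferroni family-size override.
#' @return Invisibly, a list with `qc_report`, `burden` (per-threshold
#'   tibbles), `gfactor`, `grid`, `descriptives`.
#' @export
cmd_run <- function(bed_path,
                    bim_path = sub("\\.bed$", ".bim", bed_path),
                    fam_path = sub("\\.bed$", ".fam", bed_path),
                    annotation_path, phenotype_path, out_dir,
                    maf_thresholds = c(0.01, 0.05),
                    missing_policy = "zero",
                    outlier_sd = 4,
                    snp_callrate = 0.97, sample_callrate = 0.97,
                    m = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  geno <- read_plink(bed_path, bim_path, fam_path)
  geno <- set_annotation(geno, read_annotation(annotation_path))

  qc <- run_qc(geno, snp_callrate, sample_callrate)
  write_qc_report(qc$report, file.path(out_dir, "qc_report.tsv"))

  cohort <- read_phenotypes(phenotype_path,
                            sample_ids = qc$genotypes$samples$sample_id)

  maf_tbl <- compute_maf(qc$genotypes)
  burden_tabs <- purrr::map(maf_thresholds, function(thr) {
    tab <- burden_table(qc$genotypes, thr, maf_tbl, missing_policy)
    readr::write_tsv(tab, file.path(out_dir,
                                    sprintf("burden_maf%s.tsv", thr)))
    tab
  })
  names(burden_tabs) <- paste0("maf_", maf_thresholds)

  gf <- derive_fluid_g(cohort)
  write_gfactor(gf, file.path(out_dir, "gfactor.tsv"))
  cohort <- cohort %>% left_join(gf$scores, by = "sample_id")

  grid <- run_model_grid(cohort, qc$genotypes,
                         maf_thresholds = maf_thresholds,
                         missing_policy = missing_policy,
                         outlier_sd = outlier_sd, m = m)
  readr::write_tsv(as_tibble(grid), file.path(out_dir, "associations.tsv"))

  desc <- cohort_descriptives(cohort, burden_tabs, maf_thresholds)
  readr::write_tsv(desc, file.path(out_dir, "descriptives.tsv"))

  inform(sprintf("pipeline complete: %d association models written to %s",
                 nrow(grid), out_dir))
  invisible(list(qc_report = qc$report, burden = burden_tabs, gfactor = gf,
                 grid = grid, descriptives = desc))
}

#' Descriptive summary of a cohort
#'
#' Means and standard deviations of ages, MHT scores, the g factor and the
#' combined rare-allele burden at each threshold, with per-measure n — the
#' usual first table of a cohort analysis.
#'
#' @param cohort Cohort tibble (with `g` merged in if available).
#' @param burden_tabs Named list of [burden_table()] outputs.
#' @param maf_thresholds Thresholds matching `burden_tabs`.
#' @return A tibble: `measure`, `n`, `mean`, `sd`.
#' @export
cohort_descriptives <- function(cohort, burden_tabs, maf_thresholds) {
  one <- function(name, v) {
    v <- v[!is.na(v)]
    tibble(measure = name, n = length(v), mean = mean(v), sd = sd(v))
  }
  rows <- list(
    one("childhood age (years)", cohort$age_child),
    one("late-life age (years)", cohort$age_late),
    one("Moray House Test (childhood)", cohort$mht_child),
    one("Moray House Test (late life)", cohort$mht_late)
  )
  if ("g" %in% names(cohort)) {
    rows <- c(rows, list(one("fluid general cognitive ability, g", cohort$g)))
  }
  for (i in seq_along(maf_thresholds)) {
    joined <- cohort %>%
      left_join(burden_tabs[[i]], by = "sample_id")
    rows <- c(rows, list(one(
      sprintf("total number of rare alleles (MAF <= %g)", maf_thresholds[i]),
      joined$burden_total
    )))
  }
  bind_rows(rows)
}
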