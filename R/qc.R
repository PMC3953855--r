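# Second-stage exome-chip QC. Consortium-level first-stage QC (sample
# identity, plate effects, cluster review) is assumed done upstream; this
# module implements the in-cohort cascade: haploid heterozygous calls set
# missing, monomorphic variants removed, then call-rate filters for variants
# and samples, in that fixed order, one pass.

#' Set haploid heterozygous calls to missing
#'
#' A heterozygous call at a haploid locus (male X chromosome) is necessarily
#' a genotyping error and is set to `NA`. Autosomes and female calls are
#' untouched.
#'
#' @param geno A [genotype_matrix()].
#' @return A list: `genotypes` (modified matrix), `n_set_missing` (count of
#'   calls changed).
#' @export
set_haploid_het_missing <- function(geno) {
  xv <- is_x_variant(geno)
  if (!any(xv)) return(list(genotypes = geno, n_set_missing = 0L))
  if (any(is.na(geno$samples$sex))) {
    abort("sample sex is unknown but X-chromosome variants are present; cannot adjudicate haploidy.")
  }
  male <- is_male(geno)
  sub <- geno$dosage[male, xv, drop = FALSE]
  het <- !is.na(sub) & sub == 1L
  sub[het] <- NA_integer_
  geno$dosage[male, xv] <- sub
  list(genotypes = geno, n_set_missing = sum(het))
}

#' Remove monomorphic variants
#'
#' A variant is monomorphic when its observed non-missing calls carry a
#' single allele: all dosages 0, all dosages 2, or no non-missing calls at
#' all. Judged on the matrix as passed (i.e. after haploid-het calls have
#' been set missing, when run inside [run_qc()]).
#'
#' @param geno A [genotype_matrix()].
#' @return A list: `genotypes`, `n_removed`.
#' @export
remove_monomorphic <- function(geno) {
  d <- geno$dosage
  any1 <- colSums(!is.na(d) & d == 1L) > 0
  any0 <- colSums(!is.na(d) & d == 0L) > 0
  any2 <- colSums(!is.na(d) & d == 2L) > 0
  poly <- any1 | (any0 & any2)
  list(
    genotypes = subset_genotypes(geno, variants = which(poly)),
    n_removed = sum(!poly)
  )
}

#' Remove variants with low call rate
#'
#' Call rate is the fraction of non-missing calls across samples. The
#' comparison is strict: a variant is removed when its call rate is
#' *less than* `threshold`, so a rate exactly at the threshold is kept.
#'
#' @param geno A [genotype_matrix()].
#' @param threshold Minimum acceptable call rate, in (0, 1\]; default 0.97.
#' @return A list: `genotypes`, `n_removed`.
#' @export
filter_variant_callrate <- function(geno, threshold = 0.97) {
  stopifnot(threshold > 0, threshold <= 1)
  cr <- colMeans(!is.na(geno$dosage))
  keep <- cr >= threshold
  list(
    genotypes = subset_genotypes(geno, variants = which(keep)),
    n_removed = sum(!keep)
  )
}

#' Remove samples with low call rate
#'
#' Mirror of [filter_variant_callrate()] along the sample axis.
#'
#' @inheritParams filter_variant_callrate
#' @return A list: `genotypes`, `n_removed`.
#' @export
filter_sample_callrate <- function(geno, threshold = 0.97) {
  stopifnot(threshold > 0, threshold <= 1)
  if (n_variants(geno) == 0) {
    abort("no variants left; cannot compute sample call rates.")
  }
  cr <- rowMeans(!is.na(geno$dosage))
  keep <- cr >= threshold
  if (!any(keep)) abort("all samples removed by the call-rate filter.")
  list(
    genotypes = subset_genotypes(geno, samples = which(keep)),
    n_removed = sum(!keep)
  )
}

#' Run the full second-stage QC cascade
#'
#' Applies, in order and in a single pass: haploid heterozygous calls set to
#' missing; monomorphic variants removed; variants with call rate < 97%
#' removed; samples with call rate < 97% removed. Missingness created in
#' stage 1 counts against the call rates, and monomorphism is judged on the
#' post-stage-1 matrix; call rates are not re-evaluated between the variant
#' and sample filters.
#'
#' @param geno A [genotype_matrix()].
#' @param snp_callrate,sample_callrate Call-rate thresholds (strict `<`
#'   removal), both 0.97 by default.
#' @return A list: `genotypes` (cleaned matrix) and `report` (a `qc_report`).
#' @examples
#' sim <- simulate_cohort(sim_config(n_samples = 60, n_variants = 400))
#' qc <- run_qc(sim$genotypes)
#' qc$report
#' @export
run_qc <- function(geno, snp_callrate = 0.97, sample_callrate = 0.97) {
  n_snps_in <- n_variants(geno)
  n_samples_in <- n_samples(geno)

  s1 <- set_haploid_het_missing(geno)
  s2 <- remove_monomorphic(s1$genotypes)
  s3 <- filter_variant_callrate(s2$genotypes, snp_callrate)
  s4 <- filter_sample_callrate(s3$genotypes, sample_callrate)

  report <- structure(
    list(
      n_snps_in = n_snps_in,
      n_samples_in = n_samples_in,
      n_haploid_het_set_missing = s1$n_set_missing,
      n_monomorphic_removed = s2$n_removed,
      n_snps_callrate_removed = s3$n_removed,
      n_samples_callrate_removed = s4$n_removed,
      n_snps_out = n_variants(s4$genotypes),
      n_samples_out = n_samples(s4$genotypes),
      snp_callrate_threshold = snp_callrate,
      sample_callrate_threshold = sample_callrate
    ),
    class = "qc_report"
  )
  stopifnot(
    report$n_snps_out ==
      n_snps_in - report$n_monomorphic_removed - report$n_snps_callrate_removed,
    report$n_samples_out == n_samples_in - report$n_samples_callrate_removed
  )
  inform(sprintf(
    paste0("QC: %d haploid het calls set missing; %d monomorphic, ",
           "%d low-call-rate variants and %d low-call-rate samples removed; ",
           "%d variants x %d samples retained"),
    report$n_haploid_het_set_missing, report$n_monomorphic_removed,
    report$n_snps_callrate_removed, report$n_samples_callrate_removed,
    report$n_snps_out, report$n_samples_out
  ))
  list(genotypes = s4$genotypes, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}

#' @rdname run_qc
#' @param x A `qc_report`.
#' @param ... Unused.
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) {
  tibble(
    stage = c("haploid_het_set_missing", "monomorphic_removed",
              "snp_callrate_removed", "sample_callrate_removed"),
    unit = c("calls", "variants", "variants", "samples"),
    n = c(x$n_haploid_het_set_missing, x$n_monomorphic_removed,
          x$n_snps_callrate_removed, x$n_samples_callrate_removed)
  )
}

#' @rdname run_qc
#' @method glance qc_report
#' @export
glance.qc_report <- function(x, ...) {
  tibble(
    n_snps_in = x$n_snps_in, n_snps_out = x$n_snps_out,
    n_samples_in = x$n_samples_in, n_samples_out = x$n_samples_out,
    snp_callrate_threshold = x$snp_callrate_threshold,
    sample_callrate_threshold = x$sample_callrate_threshold
  )
}

#' Write a QC report as TSV
#'
#' @param report A `qc_report`.
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  readr::write_tsv(
    bind_cols(tidy(report) %>%
                select("stage", "n") %>%
                tidyr::pivot_wider(names_from = "stage", values_from = "n"),
              glance(report)),
    path
  )
  invisible(path)
}
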