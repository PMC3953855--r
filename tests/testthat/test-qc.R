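test_that("haploid heterozygous calls are set missing only for males on X", {
  geno <- make_geno(random_dosage(6, 4))
  res <- set_haploid_het_missing(geno)
  expect_equal(res$n_set_missing, 0)
  expect_identical(res$genotypes$dosage, geno$dosage)

  # 4 males x 3 X variants with 5 injected het calls, plus female hets and
  # autosomal male hets that must survive
  d <- matrix(0L, 6, 4)
  d[1, 1] <- 1L; d[1, 2] <- 1L; d[2, 1] <- 1L; d[3, 2] <- 1L; d[4, 3] <- 1L
  d[5, 1] <- 1L  # female on X: kept
  d[1, 4] <- 1L  # male on autosome: kept
  geno2 <- make_geno(d, sex = c(rep("male", 4), "female", "female"),
                     chrom = c("X", "X", "X", "7"))
  res2 <- set_haploid_het_missing(geno2)
  expect_equal(res2$n_set_missing, 5)
  expect_true(all(is.na(res2$genotypes$dosage[cbind(c(1, 1, 2, 3, 4),
                                                    c(1, 2, 1, 2, 3))])))
  expect_equal(res2$genotypes$dosage[5, 1], 1L)
  expect_equal(res2$genotypes$dosage[1, 4], 1L)

  geno3 <- make_geno(d, sex = c(rep(NA_character_, 4), "female", "female"),
                     chrom = c("X", "X", "X", "7"))
  expect_error(set_haploid_het_missing(geno3), "sex is unknown")
})

test_that("monomorphic removal judges observed alleles", {
  d <- cbind(
    rep(0L, 4),          # all reference: monomorphic
    c(0L, 1L, 0L, 0L),   # het present: kept
    rep(2L, 4),          # all alternate homozygote: monomorphic
    c(NA, NA, NA, NA),   # all missing: monomorphic
    c(0L, 2L, 0L, 0L),   # both homozygotes: kept
    c(2L, 2L, NA, 2L)    # single allele observed: monomorphic
  )
  res <- remove_monomorphic(make_geno(d))
  expect_equal(res$n_removed, 4)
  expect_identical(res$genotypes$variants$variant_id, c("v002", "v005"))
})

test_that("call-rate filters use a strict < threshold", {
  d <- random_dosage(100, 3)
  d[, 1][sample(100, 4)] <- NA_integer_  # 0.96: removed
  d[, 2][sample(100, 3)] <- NA_integer_  # 0.97 exactly: kept
  d[is.na(d[, 3]), 3] <- 0L              # fully called: kept
  res <- filter_variant_callrate(make_geno(d), 0.97)
  expect_equal(res$n_removed, 1)
  expect_identical(res$genotypes$variants$variant_id, c("v002", "v003"))

  d2 <- random_dosage(3, 100)
  d2[1, sample(100, 4)] <- NA_integer_
  d2[2, sample(100, 3)] <- NA_integer_
  d2[3, is.na(d2[3, ])] <- 0L
  res2 <- filter_sample_callrate(make_geno(d2), 0.97)
  expect_equal(res2$n_removed, 1)
  expect_identical(res2$genotypes$samples$sample_id, c("s002", "s003"))

  empty <- make_geno(matrix(NA_integer_, 3, 2))
  expect_error(filter_sample_callrate(remove_monomorphic(empty)$genotypes),
               "no variants")
})

test_that("run_qc reports counts matching direct enumeration on the input", {
  sim <- simulate_cohort(test_config(missing_rate = 0.01,
                                     haploid_het_rate = 0.1,
                                     frac_x_chromosome = 0.2))
  geno <- sim$genotypes
  male <- geno$samples$sex == "male"
  xv <- geno$variants$chrom == "X"

  # independent enumeration of each stage on a copy of the matrix
  exp_het <- sum(geno$dosage[male, xv] == 1L, na.rm = TRUE)
  d <- geno$dosage
  d[male, xv][!is.na(d[male, xv]) & d[male, xv] == 1L] <- NA_integer_
  mono <- vapply(seq_len(ncol(d)), function(j) {
    v <- d[, j][!is.na(d[, j])]
    length(unique(v)) == 0 || all(v == 0L) || all(v == 2L)
  }, logical(1))
  cr <- colMeans(!is.na(d[, !mono, drop = FALSE]))
  exp_snp_cr <- sum(cr < 0.97)

  suppressMessages(qc <- run_qc(geno))
  expect_equal(qc$report$n_haploid_het_set_missing, exp_het)
  expect_equal(qc$report$n_monomorphic_removed, sum(mono))
  expect_equal(qc$report$n_snps_callrate_removed, exp_snp_cr)
  expect_equal(qc$report$n_snps_out,
               n_variants(geno) - qc$report$n_monomorphic_removed -
                 qc$report$n_snps_callrate_removed)
  expect_equal(qc$report$n_samples_out,
               n_samples(geno) - qc$report$n_samples_callrate_removed)
})

test_that("run_qc is idempotent and clean input passes untouched", {
  d <- random_dosage(20, 30)
  clean <- make_geno(d)  # autosomal, fully called, all polymorphic w.h.p.
  poly <- remove_monomorphic(clean)$genotypes
  suppressMessages(qc1 <- run_qc(poly))
  expect_equal(qc1$report$n_haploid_het_set_missing, 0)
  expect_equal(qc1$report$n_monomorphic_removed, 0)
  expect_equal(qc1$report$n_snps_callrate_removed, 0)
  expect_equal(qc1$report$n_samples_callrate_removed, 0)

  # idempotence holds whenever the sample filter removes nobody (removing
  # a singleton carrier can create fresh monomorphic variants, which the
  # deliberate single-pass design does not chase)
  sim <- simulate_cohort(test_config(missing_rate = 0.003,
                                     haploid_het_rate = 0.05,
                                     frac_x_chromosome = 0.2))
  suppressMessages(first <- run_qc(sim$genotypes))
  expect_equal(first$report$n_samples_callrate_removed, 0)
  suppressMessages(second <- run_qc(first$genotypes))
  expect_equal(second$report$n_haploid_het_set_missing, 0)
  expect_equal(second$report$n_monomorphic_removed, 0)
  expect_equal(second$report$n_snps_callrate_removed, 0)
  expect_equal(second$report$n_samples_callrate_removed, 0)
  expect_identical(second$genotypes$dosage, first$genotypes$dosage)
})

test_that("qc report tidies and serializes", {
  sim <- simulate_cohort(test_config())
  suppressMessages(qc <- run_qc(sim$genotypes))
  td <- tidy(qc$report)
  expect_equal(nrow(td), 4)
  expect_true(all(td$n >= 0))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_qc_report(qc$report, p)
  back <- readr::read_tsv(p, show_col_types = FALSE)
  expect_equal(back$n_snps_out, qc$report$n_snps_out)
})
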