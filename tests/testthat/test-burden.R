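test_that("MAF computation counts alleles correctly, including on X", {
  m <- compute_maf(make_geno(cbind(c(0L, 0L, 1L), c(2L, 2L, 2L))))
  expect_equal(m$f_a1, c(1 / 6, 1))
  expect_equal(m$maf, c(1 / 6, 0))
  expect_identical(m$minor_is_a1, c(TRUE, FALSE))

  # X variant: 2 females (diploid) + 3 males (haploid, coded 0/2)
  # female dosages 1, 2 -> 3 A1 alleles of 4; male dosages 2, 0, 2 -> 2 of 3
  # f = (3 + 2) / (4 + 3) = 5/7, MAF = 2/7 with minor = A2
  d <- matrix(c(1L, 2L, 2L, 0L, 2L), ncol = 1)
  geno <- make_geno(d, sex = c("female", "female", rep("male", 3)),
                    chrom = "X")
  mx <- compute_maf(geno)
  expect_equal(mx$f_a1, 5 / 7)
  expect_equal(mx$maf, 2 / 7)
  expect_false(mx$minor_is_a1)

  all_missing <- make_geno(matrix(NA_integer_, 3, 1))
  expect_error(compute_maf(all_missing), "no non-missing")
})

test_that("rare-variant selection is MAF-inclusive and class-aware", {
  maf_tbl <- tibble::tibble(
    variant_id = c("a", "b", "c", "d", "e"),
    func_class = c("missense", "splice", "synonymous", "missense", "splice"),
    f_a1 = c(0.01, 0.05, 0.005, 0, 0.2),
    maf = c(0.01, 0.05, 0.005, 0, 0.2),
    minor_is_a1 = TRUE
  )
  # boundary: MAF exactly at the threshold is rare ("less than or equal to")
  expect_identical(select_rare_variants(maf_tbl, 0.01), "a")
  expect_identical(select_rare_variants(maf_tbl, 0.05), c("a", "b"))
  # monomorphic (maf 0) never selected even though 0 <= threshold
  expect_false("d" %in% select_rare_variants(maf_tbl, 0.05))
  expect_identical(
    select_rare_variants(maf_tbl, 0.05, class_set = "synonymous"), "c")
  expect_warning(select_rare_variants(maf_tbl, 0.05, "stop_gain_loss"),
                 "no variants")
})

test_that("burden totals equal direct sums and the per-cell loop oracle", {
  # hand example: minor dosages [[0,1,2],[1,0,0]] -> burdens 3, 1
  d <- rbind(c(0L, 1L, 2L), c(1L, 0L, 0L))
  geno <- make_geno(d)
  maf_tbl <- compute_maf(geno)
  expect_true(all(maf_tbl$minor_is_a1))
  b <- compute_burden(geno, geno$variants$variant_id, maf_tbl)
  expect_equal(b$burden, c(3, 1))

  zero <- make_geno(matrix(0L, 4, 3))
  mz <- tibble::tibble(variant_id = zero$variants$variant_id,
                       func_class = "missense", f_a1 = 0.2, maf = 0.2,
                       minor_is_a1 = TRUE)
  expect_equal(compute_burden(zero, zero$variants$variant_id, mz)$burden,
               rep(0, 4))

  # randomized equivalence with the brute-force per-cell oracle, both policies
  withr::local_seed(42)
  for (rep in 1:5) {
    geno <- make_geno(random_dosage(50, 200, miss_rate = 0.05),
                      func_class = sample(c("missense", "splice", "synonymous"),
                                          200, replace = TRUE))
    keep <- colSums(!is.na(geno$dosage)) > 0
    geno <- subset_genotypes(geno, variants = which(keep))
    maf_tbl <- compute_maf(geno)
    ids <- sample(geno$variants$variant_id, 60)
    for (policy in c("zero", "mean_impute")) {
      b <- compute_burden(geno, ids, maf_tbl, missing_policy = policy)
      expect_equal(b$burden, oracle_burden(geno, ids, maf_tbl, policy),
                   tolerance = 1e-12)
    }
  }
})

test_that("burden is monotone in the MAF threshold and additive over classes", {
  sim <- simulate_cohort(test_config(missing_rate = 0.01))
  suppressMessages(geno <- run_qc(sim$genotypes)$genotypes)
  maf_tbl <- compute_maf(geno)
  tab01 <- burden_table(geno, 0.01, maf_tbl)
  tab05 <- burden_table(geno, 0.05, maf_tbl)
  expect_true(all(tab05$burden_total >= tab01$burden_total))
  expect_gt(mean(tab05$burden_total), mean(tab01$burden_total))

  expect_equal(
    tab01$burden_total,
    tab01$burden_stop_gain_loss + tab01$burden_splice + tab01$burden_missense
  )
  expect_true(all(tab01$burden_all_incl_synonymous >= tab01$burden_total))
})

test_that("outlier rule removes planted extremes and nothing else", {
  withr::local_seed(7)
  burdens <- tibble::tibble(sample_id = sprintf("s%03d", 1:500),
                            burden = rnorm(500, 185, 15))
  res <- remove_burden_outliers(burdens)
  expect_length(res$removed, 0)

  burdens$burden[100] <- 185 + 10 * 15
  suppressMessages(res2 <- remove_burden_outliers(burdens))
  expect_identical(res2$removed, "s100")
  expect_length(res2$kept, 499)

  res3 <- remove_burden_outliers(burdens, n_sd = Inf)
  expect_length(res3$removed, 0)
  expect_error(remove_burden_outliers(burdens[1:5, ]), "at least 10")
})
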