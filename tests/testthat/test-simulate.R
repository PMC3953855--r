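test_that("variant simulation honours class proportions and spectrum controls", {
  cfg <- sim_config(n_samples = 10, n_variants = 10,
                    class_proportions = c(stop_gain_loss = 0, splice = 0,
                                          missense = 1, synonymous = 0))
  v <- simulate_variants(cfg, seed = 1)
  expect_equal(nrow(v), 10)
  expect_true(all(v$func_class == "missense"))

  cfg2 <- sim_config(n_samples = 10, n_variants = 50, monomorphic_rate = 1)
  v2 <- simulate_variants(cfg2, seed = 2)
  expect_true(all(v2$true_maf == 0))

  # law-of-large-numbers check on the default proportions
  v3 <- simulate_variants(sim_config(n_variants = 50000L), seed = 1)
  frac <- table(v3$func_class) / 50000
  cp <- sim_config()$class_proportions
  expect_true(all(abs(frac[names(cp)] - cp) < 0.01))
})

test_that("variant positions are 1-based and strictly increasing within chromosome", {
  v <- simulate_variants(test_config(), seed = 3)
  expect_true(all(v$pos >= 1))
  by_chr <- split(v$pos, v$chrom)
  expect_true(all(vapply(by_chr, function(p) all(diff(p) > 0), logical(1))))
})

test_that("genotype sampling matches its binomial model", {
  cfg <- sim_config(n_samples = 50, n_variants = 20, monomorphic_rate = 1,
                    missing_rate = 0)
  v <- simulate_variants(cfg, seed = 4)
  g <- simulate_genotypes(v, cfg, seed = 4)
  expect_true(all(g$dosage == 0L))

  cfg2 <- sim_config(n_samples = 30, n_variants = 20, missing_rate = 1)
  v2 <- simulate_variants(cfg2, seed = 5)
  g2 <- simulate_genotypes(v2, cfg2, seed = 5)
  expect_true(all(is.na(g2$dosage)))

  # single autosomal variant at known frequency: binomial s.e. oracle
  cfg3 <- sim_config(n_samples = 1000, n_variants = 1, frac_x_chromosome = 0,
                     monomorphic_rate = 0, missing_rate = 0,
                     sample_maf_dispersion = 0)
  v3 <- simulate_variants(cfg3, seed = 7)
  g3 <- simulate_genotypes(v3, cfg3, true_mafs = 0.25, seed = 7)
  f_hat <- mean(g3$dosage) / 2
  se <- sqrt(0.25 * 0.75 / (2 * 1000))
  expect_lt(abs(f_hat - 0.25), 3 * se)
})

test_that("male X calls are haploid-coded with the configured error rate", {
  cfg <- sim_config(n_samples = 400, n_variants = 50, frac_x_chromosome = 1,
                    monomorphic_rate = 0, missing_rate = 0,
                    haploid_het_rate = 0)
  v <- simulate_variants(cfg, seed = 8)
  g <- simulate_genotypes(v, cfg, seed = 8)
  male <- g$samples$sex == "male"
  expect_true(all(g$dosage[male, ] %in% c(0L, 2L)))
  expect_true(any(g$dosage[!male, ] == 1L))

  cfg2 <- sim_config(n_samples = 400, n_variants = 50, frac_x_chromosome = 1,
                     monomorphic_rate = 0, missing_rate = 0,
                     haploid_het_rate = 0.2)
  g2 <- simulate_genotypes(v, cfg2, seed = 8)
  male2 <- g2$samples$sex == "male"
  het_rate <- mean(g2$dosage[male2, ] == 1L)
  expect_gt(het_rate, 0.15)
  expect_lt(het_rate, 0.25)
})

test_that("ground-truth burden round-trips through the burden module when error injection is off", {
  cfg <- test_config(missing_rate = 0, haploid_het_rate = 0)
  sim <- simulate_cohort(cfg)
  maf <- compute_maf(sim$genotypes)
  ids <- select_rare_variants(maf, 0.01, c("stop_gain_loss", "splice",
                                           "missense"))
  b <- compute_burden(sim$genotypes, ids, maf)
  expect_equal(b$burden, sim$truth$true_burdens)
  expect_setequal(ids, sim$truth$rare_variant_ids)
})

test_that("phenotypes carry the configured burden effect and respect the MHT range", {
  r <- vapply(1:3, function(s) {
    sim <- simulate_cohort(sim_config(n_samples = 2000, n_variants = 500,
                                      effect_per_allele = 0, seed = s))
    cor(sim$truth$true_burdens, sim$cohort$mht_child)
  }, numeric(1))
  expect_lt(abs(mean(r)), 0.05)
  expect_true(all(abs(r) < 5 / sqrt(2000)))

  for (s in c(11, 12)) {
    sim2 <- simulate_cohort(test_config(seed = s, effect_per_allele = -2))
    expect_true(all(sim2$cohort$mht_child >= 0 & sim2$cohort$mht_child <= 76))
    expect_true(all(sim2$cohort$mht_late >= 0 & sim2$cohort$mht_late <= 76))
    expect_true(all(sim2$cohort$mht_child == round(sim2$cohort$mht_child)))
  }
})

test_that("survivor selection truncates the cohort and shrinks phenotype spread", {
  sim <- simulate_cohort(sim_config(n_samples = 501, n_variants = 300,
                                    seed = 11))
  expect_identical(apply_survivor_selection(sim$cohort, 0), sim$cohort)

  kept <- apply_survivor_selection(sim$cohort, 0.5, seed = 11)
  expect_equal(nrow(kept), ceiling(0.5 * 501))
  expect_lt(sd(kept$mht_child), sd(sim$cohort$mht_child))
  expect_error(apply_survivor_selection(sim$cohort, 1), "\\[0, 1\\)")
})

test_that("simulation is deterministic in the config seed", {
  s1 <- simulate_cohort(test_config())
  s2 <- simulate_cohort(test_config())
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  expect_identical(s1$cohort, s2$cohort)
  s3 <- simulate_cohort(test_config(seed = 999))
  expect_false(identical(s1$genotypes$dosage, s3$genotypes$dosage))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_samples = 0), "n_samples")
  expect_error(sim_config(class_proportions = c(stop_gain_loss = 0.5,
                                                splice = 0.5,
                                                missense = 0.5,
                                                synonymous = 0.5)),
               "sum to 1")
  expect_error(sim_config(missing_rate = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(maf_spectrum = list(distribution = "beta_truncated",
                                              shape1 = -1, shape2 = 2)),
               "positive")
  expect_error(sim_config(maf_spectrum = list(distribution = "uniform")),
               "unknown")
})
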