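# Hand-built genotype fixtures for unit tests.

make_geno <- function(dosage, sex = rep("female", nrow(dosage)),
                      chrom = rep("1", ncol(dosage)),
                      func_class = rep("missense", ncol(dosage))) {
  n <- nrow(dosage)
  m <- ncol(dosage)
  genotype_matrix(
    dosage = dosage,
    samples = tibble::tibble(sample_id = sprintf("s%03d", seq_len(n)),
                             sex = sex),
    variants = tibble::tibble(
      variant_id = sprintf("v%03d", seq_len(m)),
      chrom = chrom,
      pos = seq_len(m) * 1000L,
      a1 = "A", a2 = "G",
      func_class = func_class
    )
  )
}

# Random dosage matrix with controllable missingness (NULL sentinel -> NA).
random_dosage <- function(n, m, miss_rate = 0) {
  d <- matrix(sample(0:2, n * m, replace = TRUE,
                     prob = c(0.7, 0.25, 0.05)), n, m)
  if (miss_rate > 0) d[runif(n * m) < miss_rate] <- NA_integer_
  d
}

# Small, fast simulation config for tests.
test_config <- function(...) {
  args <- utils::modifyList(
    list(n_samples = 80L, n_variants = 400L, seed = 101L), list(...))
  do.call(sim_config, args)
}

# Brute-force per-cell burden oracle: explicit double loop, independent of
# the matrix-algebra implementation.
oracle_burden <- function(geno, variant_ids, maf_table, policy = "zero") {
  idx <- match(variant_ids, geno$variants$variant_id)
  res <- numeric(n_samples(geno))
  for (i in seq_len(n_samples(geno))) {
    tot <- 0
    for (j in idx) {
      d <- geno$dosage[i, j]
      minor_is_a1 <- maf_table$minor_is_a1[j]
      if (is.na(d)) {
        if (policy == "mean_impute") {
          col <- geno$dosage[, j]
          col <- col[!is.na(col)]
          if (!minor_is_a1) col <- 2 - col
          tot <- tot + mean(col)
        }
      } else {
        tot <- tot + if (minor_is_a1) d else 2 - d
      }
    }
    res[i] <- tot
  }
  res
}

# Independent normal-equations OLS oracle: solve(X'X) X'y, textbook s.e.
oracle_ols <- function(y, X) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(sigma2 * xtx_inv))
  tstat <- as.numeric(beta) / se
  list(estimate = as.numeric(beta), std.error = unname(se),
       p.value = unname(2 * pt(abs(tstat), df, lower.tail = FALSE)))
}
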