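#' Simulate exome-array variants
#'
#' Draws variant identities, loci, functional classes and true minor-allele
#' frequencies. True MAFs come from the configured rare-skewed spectrum
#' (inverse-CDF sampling from a Beta distribution truncated to
#' (0, `max_maf`\]); a `monomorphic_rate` fraction is forced to frequency
#' exactly 0, mimicking the large monomorphic share of exome arrays.
#' Positions are 1-based and strictly increasing within each chromosome.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed; `NULL` (default) continues the current
#'   RNG stream, which is how [simulate_cohort()] drives all stages from one
#'   generator.
#' @return A tibble with columns `variant_id`, `chrom`, `pos`, `a1`, `a2`,
#'   `func_class`, `true_maf`.
#' @export
simulate_variants <- function(config, seed = NULL) {
  config <- validate_sim_config(config)
  if (!is.null(seed)) withr::local_seed(seed)
  n <- config$n_variants

  n_x <- round(config$frac_x_chromosome * n)
  chrom <- c(sample(as.character(1:22), n - n_x, replace = TRUE),
             rep("X", n_x))
  cp <- config$class_proportions
  func_class <- sample(names(cp), n, replace = TRUE, prob = cp)

  ms <- config$maf_spectrum
  u <- runif(n) * pbeta(ms$max_maf %||% 0.5, ms$shape1, ms$shape2)
  true_maf <- qbeta(u, ms$shape1, ms$shape2)
  n_mono <- round(config$monomorphic_rate * n)
  if (n_mono > 0) true_maf[sample.int(n, n_mono)] <- 0

  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, n, replace = TRUE)
  a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1L), character(1),
               USE.NAMES = FALSE)

  out <- tibble(
    chrom = chrom, func_class = func_class, true_maf = true_maf,
    a1 = a1, a2 = a2
  ) %>%
    mutate(.chrom_ord = match(chrom, c(as.character(1:22), "X"))) %>%
    arrange(.data$.chrom_ord) %>%
    group_by(.data$chrom) %>%
    mutate(pos = cumsum(sample(100:10000, n(), replace = TRUE))) %>%
    ungroup() %>%
    select(-".chrom_ord")
  out %>%
    mutate(variant_id = sprintf("var%06d", seq_len(n))) %>%
    select("variant_id", "chrom", "pos", "a1", "a2", "func_class", "true_maf")
}

#' Simulate genotype calls under Hardy–Weinberg sampling
#'
#' Autosomal dosages are Binomial(2, MAF) draws per individual; X-chromosome
#' male calls are haploid Bernoulli draws coded diploid (0/2), with a
#' `haploid_het_rate` fraction corrupted to heterozygous (the error class the
#' QC cascade later removes). A `missing_rate` fraction of all calls is set
#' to `NA`. A per-sample multiplier on all MAFs (s.d.
#' `sample_maf_dispersion`) overdisperses individual allele totals.
#'
#' The returned object carries a `ground_truth` attribute with the
#' per-sample rare non-synonymous allele total computed from the error-free
#' calls — the quantity every downstream recovery test is scored against.
#' "Rare" is judged on the error-free in-sample MAF at threshold 0.01.
#'
#' @param variants Variant tibble from [simulate_variants()].
#' @param config A [sim_config()].
#' @param true_mafs True frequencies; defaults to `variants$true_maf`.
#' @inheritParams simulate_variants
#' @return A [genotype_matrix()] with attribute `ground_truth`: a list with
#'   `true_mafs`, `true_burdens`, `rare_variant_ids`.
#' @export
simulate_genotypes <- function(variants, config, true_mafs = variants$true_maf,
                               seed = NULL) {
  config <- validate_sim_config(config)
  if (!is.null(seed)) withr::local_seed(seed)
  if (nrow(variants) != length(true_mafs)) {
    abort("`variants` and `true_mafs` are not aligned.")
  }
  ns <- config$n_samples
  nv <- nrow(variants)

  sample_id <- sprintf("S%05d", seq_len(ns))
  sex <- ifelse(runif(ns) < config$sex_ratio, "female", "male")
  male <- sex == "male"
  mult <- pmax(1 + rnorm(ns, 0, config$sample_maf_dispersion), 0.05)

  x_var <- variants$chrom == "X"
  nonsyn <- variants$func_class %in% NONSYN_CLASSES

  dosage <- matrix(NA_integer_, ns, nv)
  true_burden <- numeric(ns)
  rare <- logical(nv)
  n_f <- sum(!male)
  n_m <- sum(male)

  block_size <- 2000L
  for (start in seq(1L, nv, by = block_size)) {
    cols <- start:min(start + block_size - 1L, nv)
    p <- pmin(pmax(outer(mult, true_mafs[cols]), 0), 1)
    g <- matrix(rbinom(length(p), 2L, p), nrow = ns)
    xb <- which(x_var[cols])
    if (length(xb) && n_m > 0) {
      # males are haploid on X: one allele, coded 0/2
      g[male, xb] <- 2L * matrix(
        rbinom(n_m * length(xb), 1L, pmin(rep(true_mafs[cols][xb],
                                              each = n_m) * mult[male], 1)),
        nrow = n_m
      )
    }

    # error-free in-sample allele frequency of A1 (X-aware), for ground truth
    if (n_m > 0 && length(xb)) {
      ac <- colSums(g[!male, , drop = FALSE]) +
        colSums(g[male, , drop = FALSE]) / ifelse(seq_along(cols) %in% xb, 2, 1)
      an <- ifelse(seq_along(cols) %in% xb, 2 * n_f + n_m, 2 * ns)
    } else {
      ac <- colSums(g)
      an <- rep(2 * ns, length(cols))
    }
    f <- ac / an
    maf <- pmin(f, 1 - f)
    rare_b <- maf <= 0.01 & maf > 0 & nonsyn[cols]
    rare[cols] <- rare_b
    if (any(rare_b)) {
      minor <- g[, rare_b, drop = FALSE]
      flip <- f[rare_b] > 0.5
      if (any(flip)) minor[, flip] <- 2L - minor[, flip]
      true_burden <- true_burden + rowSums(minor)
    }

    # error injection: haploid heterozygous calls (only at segregating
    # sites; a monomorphic probe clusters cleanly), then missingness
    xb_seg <- xb[true_mafs[cols][xb] > 0]
    if (length(xb_seg) && n_m > 0 && config$haploid_het_rate > 0) {
      err <- matrix(runif(n_m * length(xb_seg)) < config$haploid_het_rate,
                    nrow = n_m)
      gm <- g[male, xb_seg, drop = FALSE]
      gm[err] <- 1L
      g[male, xb_seg] <- gm
    }
    if (config$missing_rate > 0) {
      g[runif(length(g)) < config$missing_rate] <- NA_integer_
    }
    dosage[, cols] <- g
  }

  geno <- genotype_matrix(
    dosage = dosage,
    samples = tibble(sample_id = sample_id, sex = sex),
    variants = select(variants, "variant_id", "chrom", "pos", "a1", "a2",
                      "func_class")
  )
  attr(geno, "ground_truth") <- list(
    true_mafs = true_mafs,
    true_burdens = true_burden,
    rare_variant_ids = variants$variant_id[rare]
  )
  geno
}

#' Simulate cognitive phenotypes with a configurable burden effect
#'
#' Moray House Test (MHT) scores at both waves are linear in mean-centred
#' testing age, sex and the (centred) ground-truth rare-allele burden, plus
#' Gaussian noise, then rounded half-up and clamped to the instrument's
#' \[0, 76\] range. The latent fluid factor receives the same per-allele
#' effect converted to s.d. units, and each battery test loads on it with
#' unique noise `sqrt(1 - loading^2)`.
#'
#' @param genotypes A [genotype_matrix()] from [simulate_genotypes()]
#'   (carries the ground-truth burden).
#' @param config A [sim_config()].
#' @param ground_truth Override for the genotypes' `ground_truth` attribute.
#' @inheritParams simulate_variants
#' @return A cohort tibble: `sample_id`, `sex`, `age_child`, `age_late`,
#'   `mht_child`, `mht_late`, `battery_1..k`, plus ground-truth columns
#'   `true_burden` and `latent_g` (never used by the analysis stages).
#' @export
simulate_phenotypes <- function(genotypes, config,
                                ground_truth = attr(genotypes, "ground_truth"),
                                seed = NULL) {
  config <- validate_sim_config(config)
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(ground_truth)) {
    abort("`genotypes` carries no ground_truth attribute; pass `ground_truth`.")
  }
  ns <- n_samples(genotypes)
  if (length(ground_truth$true_burdens) != ns) {
    abort("ground-truth burden length does not match the sample count.")
  }
  burden_c <- ground_truth$true_burdens - mean(ground_truth$true_burdens)
  female <- as.numeric(genotypes$samples$sex == "female")

  age_child <- rnorm(ns, config$age_child_mean, config$age_child_sd)
  age_late <- rnorm(ns, config$age_late_mean, config$age_late_sd)
  sd_child <- config$noise_sd %||% config$mht_child_sd
  sd_late <- config$noise_sd %||% config$mht_late_sd

  # one lifelong latent cognitive factor ties both MHT waves to the
  # late-life battery (rank-order stability of cognition)
  rho <- config$cog_stability
  latent_cog <- rnorm(ns)
  mht_child <- clamp_mht(
    config$mht_child_mean +
      config$age_effect_child * (age_child - config$age_child_mean) +
      config$sex_effect_child * female +
      config$effect_per_allele * burden_c +
      sd_child * (rho * latent_cog + sqrt(1 - rho^2) * rnorm(ns))
  )
  mht_late <- clamp_mht(
    config$mht_late_mean +
      config$age_effect_late * (age_late - config$age_late_mean) +
      config$sex_effect_late * female +
      config$effect_per_allele * burden_c +
      sd_late * (rho * latent_cog + sqrt(1 - rho^2) * rnorm(ns))
  )

  effect_g <- config$effect_per_allele / config$mht_late_sd
  latent_g <- effect_g * burden_c + latent_cog
  battery <- vapply(config$battery_loadings, function(lam) {
    lam * latent_g + sqrt(1 - lam^2) * rnorm(ns)
  }, numeric(ns))
  colnames(battery) <- sprintf("battery_%d", seq_len(config$battery_size))

  bind_cols(
    tibble(
      sample_id = genotypes$samples$sample_id,
      sex = genotypes$samples$sex,
      age_child = age_child, age_late = age_late,
      mht_child = mht_child, mht_late = mht_late
    ),
    as_tibble(battery),
    tibble(true_burden = ground_truth$true_burdens, latent_g = latent_g)
  )
}

# Round half-up to integer scores, clamp to the instrument range [0, 76].
clamp_mht <- function(x) pmin(pmax(floor(x + 0.5), 0), 76)

#' Drop the least-healthy fraction of a simulated cohort
#'
#' Emulates studying healthy survivors: a latent health score (the latent
#' fluid factor plus unit Gaussian noise, so health and cognition are
#' positively related) is computed, and samples below its
#' `truncation_quantile` are removed. The retained cohort's phenotype spread
#' shrinks — the range-restriction mechanism that attenuates burden–cognition
#' associations in survivor cohorts.
#'
#' @param cohort Cohort tibble from [simulate_phenotypes()] (needs the
#'   `latent_g` column).
#' @param truncation_quantile Lower quantile in \[0, 1) below which samples
#'   are dropped; 0 returns the cohort unchanged.
#' @inheritParams simulate_variants
#' @return The truncated cohort tibble (`ceiling((1 - q) * n)` rows).
#' @export
apply_survivor_selection <- function(cohort, truncation_quantile, seed = NULL) {
  if (truncation_quantile < 0 || truncation_quantile >= 1) {
    abort("`truncation_quantile` must lie in [0, 1).")
  }
  if (truncation_quantile == 0) return(cohort)
  if (!"latent_g" %in% names(cohort)) {
    abort("`cohort` lacks the latent_g column needed to score health.")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  n <- nrow(cohort)
  health <- cohort$latent_g + rnorm(n)
  n_drop <- floor(truncation_quantile * n)
  cohort[rank(health, ties.method = "first") > n_drop, , drop = FALSE]
}

#' Simulate a complete synthetic exome-array cohort
#'
#' Runs variant, genotype and phenotype simulation (and optional survivor
#' truncation) from a single seeded generator, so identical configs give
#' identical cohorts.
#'
#' @param config A [sim_config()].
#' @return A list of class `exo_sim`: `config`, `variants`, `genotypes`
#'   (a [genotype_matrix()]), `cohort` (phenotype tibble), and `truth`
#'   (list: `true_mafs`, `true_burdens`, `true_effect`, `latent_g`,
#'   `rare_variant_ids`).
#' @examples
#' sim <- simulate_cohort(sim_config(n_samples = 50, n_variants = 300))
#' nrow(sim$cohort)
#' @export
simulate_cohort <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  withr::local_seed(config$seed)
  variants <- simulate_variants(config)
  genotypes <- simulate_genotypes(variants, config)
  cohort <- simulate_phenotypes(genotypes, config)
  if (config$survivor_truncation > 0) {
    cohort <- apply_survivor_selection(cohort, config$survivor_truncation)
  }
  gt <- attr(genotypes, "ground_truth")
  structure(
    list(
      config = config,
      variants = variants,
      genotypes = genotypes,
      cohort = cohort,
      truth = list(
        true_mafs = gt$true_mafs,
        true_burdens = gt$true_burdens,
        true_effect = config$effect_per_allele,
        latent_g = cohort$latent_g,
        rare_variant_ids = gt$rare_variant_ids
      )
    ),
    class = "exo_sim"
  )
}

#' @export
print.exo_sim <- function(x, ...) {
  cat(sprintf(
    "<exo_sim> %d samples x %d variants; %d rare non-synonymous ground-truth variants\n",
    n_samples(x$genotypes), n_variants(x$genotypes),
    length(x$truth$rare_variant_ids)
  ))
  cat(sprintf("mean ground-truth rare-allele burden: %.1f (s.d. %.1f)\n",
              mean(x$truth$true_burdens), sd(x$truth$true_burdens)))
  invisible(x)
}

#' Write a simulated cohort to disk in standard formats
#'
#' Emits PLINK `.bed`/`.bim`/`.fam`, an annotation TSV (`variant_id`,
#' `class`), a phenotype TSV, a ground-truth TSV, and the config as YAML.
#' All TSVs are UTF-8, tab-delimited, with `.` for missing values.
#'
#' @param sim An `exo_sim` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param prefix Basename for the PLINK trio.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_sim_dataset <- function(sim, dir, prefix = "cohort") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    bed = file.path(dir, paste0(prefix, ".bed")),
    bim = file.path(dir, paste0(prefix, ".bim")),
    fam = file.path(dir, paste0(prefix, ".fam")),
    annotation = file.path(dir, "annotation.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    ground_truth = file.path(dir, "ground_truth.tsv"),
    config = file.path(dir, "config.yaml")
  )
  write_plink(sim$genotypes, paths["bed"], paths["bim"], paths["fam"])
  readr::write_tsv(
    sim$genotypes$variants %>%
      select(variant_id = "variant_id", class = "func_class"),
    paths["annotation"]
  )
  readr::write_tsv(
    sim$cohort %>% select(-"true_burden", -"latent_g"),
    paths["phenotypes"], na = "."
  )
  readr::write_tsv(
    sim$cohort %>% select("sample_id", "true_burden", "latent_g"),
    paths["ground_truth"]
  )
  write_sim_config(sim$config, paths["config"])
  invisible(paths)
}
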