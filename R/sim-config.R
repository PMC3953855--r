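#' Simulation configuration for a synthetic exome-array cohort
#'
#' Bundles every tunable of the cohort generator. The defaults emulate an
#' exome-array study of roughly one thousand older adults: ~50,000 assayed
#' variants dominated (96%) by protein-altering classes, a strongly
#' rare-skewed frequency spectrum in which about 78% of segregating variants
#' have minor allele frequency (MAF) at or below 0.01, per-individual
#' rare-allele totals with mean ~185 (s.d. ~15–17) at MAF <= 0.01 and
#' ~560 at MAF <= 0.05, Moray House Test (MHT) scores bounded on \[0, 76\]
#' taken at mean age 10.9 and again at mean age 69.6, and a positively
#' intercorrelated six-test late-life battery with one dominant factor.
#'
#' @param n_samples Number of individuals.
#' @param n_variants Number of assayed variants.
#' @param class_proportions Named fractions over
#'   `stop_gain_loss`, `splice`, `missense`, `synonymous`; must sum to 1.
#' @param maf_spectrum List describing the true-MAF distribution. The built-in
#'   family is `list(distribution = "beta_truncated", shape1, shape2,
#'   max_maf)`: a Beta(shape1, shape2) draw truncated to (0, max_maf\].
#' @param missing_rate Per-call probability of a missing genotype.
#' @param haploid_het_rate Probability that a male X-chromosome call is
#'   recorded heterozygous (a genotyping error; real haploid calls are
#'   homozygous-coded).
#' @param frac_x_chromosome Fraction of variants placed on chromosome X.
#' @param monomorphic_rate Fraction of variants forced to true MAF 0.
#' @param sample_maf_dispersion Standard deviation of a per-sample
#'   multiplicative factor on all MAFs (mean 1). Zero gives pure
#'   independent-binomial sampling; positive values overdisperse the
#'   per-individual allele totals the way shared ancestry does in real
#'   cohorts.
#' @param effect_per_allele Phenotype points per rare non-synonymous allele
#'   (signed; 0 simulates the null). Applies to both MHT waves; the latent
#'   fluid factor receives the same effect converted to s.d. units
#'   (divided by `mht_late_sd`).
#' @param age_child_mean,age_child_sd Childhood testing age (years).
#' @param age_late_mean,age_late_sd Late-life testing age (years).
#' @param sex_ratio Fraction female.
#' @param mht_child_mean,mht_child_sd Childhood MHT location and residual s.d.
#'   (test points).
#' @param mht_late_mean,mht_late_sd Late-life MHT location and residual s.d.
#' @param age_effect_child,age_effect_late MHT points per year of age at
#'   testing (childhood testing favours older children; late-life testing
#'   shows decline).
#' @param sex_effect_child,sex_effect_late MHT points added for females.
#' @param cog_stability Correlation of each MHT wave with the lifelong
#'   latent cognitive factor that also drives the late-life battery;
#'   cognitive ability is strongly rank-stable from childhood to old age,
#'   and this parameter carries that stability (and the health–cognition
#'   link used by survivor selection) into the simulated scores.
#' @param battery_size Number of late-life battery tests (3–6).
#' @param battery_loadings Per-test loading of the common fluid factor; `NULL`
#'   gives an equally spaced decreasing ladder from 0.85 to 0.55.
#' @param noise_sd Optional single residual s.d. overriding both
#'   `mht_child_sd` and `mht_late_sd`.
#' @param survivor_truncation Lower quantile of a latent health score below
#'   which samples are dropped (0 disables; must be < 1). Emulates studying
#'   healthy survivors, which restricts the range of both mutation load and
#'   cognition.
#' @param seed Integer seed; one generator drives all draws, and replicate
#'   `k` of a study uses `seed + k`.
#' @return A `sim_config` list, validated.
#' @examples
#' cfg <- sim_config(n_samples = 100, n_variants = 500)
#' cfg$n_variants
#' @export
sim_config <- function(n_samples = 1000L,
                       n_variants = 50000L,
                       class_proportions = c(stop_gain_loss = 0.02,
                                             splice = 0.02,
                                             missense = 0.92,
                                             synonymous = 0.04),
                       maf_spectrum = list(distribution = "beta_truncated",
                                           shape1 = 0.471,
                                           shape2 = 70.3,
                                           max_maf = 0.5),
                       missing_rate = 0.002,
                       haploid_het_rate = 0.005,
                       frac_x_chromosome = 0.04,
                       monomorphic_rate = 0.064,
                       sample_maf_dispersion = 0.035,
                       effect_per_allele = 0,
                       age_child_mean = 10.9, age_child_sd = 0.28,
                       age_late_mean = 69.6, age_late_sd = 0.84,
                       sex_ratio = 0.5,
                       mht_child_mean = 49.0, mht_child_sd = 11.8,
                       mht_late_mean = 64.3, mht_late_sd = 8.8,
                       age_effect_child = 7.5, age_effect_late = -1.5,
                       sex_effect_child = 1.75, sex_effect_late = -0.4,
                       cog_stability = 0.6,
                       battery_size = 6L,
                       battery_loadings = NULL,
                       noise_sd = NULL,
                       survivor_truncation = 0,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    n_variants = as.integer(n_variants),
    class_proportions = class_proportions,
    maf_spectrum = maf_spectrum,
    missing_rate = missing_rate,
    haploid_het_rate = haploid_het_rate,
    frac_x_chromosome = frac_x_chromosome,
    monomorphic_rate = monomorphic_rate,
    sample_maf_dispersion = sample_maf_dispersion,
    effect_per_allele = effect_per_allele,
    age_child_mean = age_child_mean, age_child_sd = age_child_sd,
    age_late_mean = age_late_mean, age_late_sd = age_late_sd,
    sex_ratio = sex_ratio,
    mht_child_mean = mht_child_mean, mht_child_sd = mht_child_sd,
    mht_late_mean = mht_late_mean, mht_late_sd = mht_late_sd,
    age_effect_child = age_effect_child, age_effect_late = age_effect_late,
    sex_effect_child = sex_effect_child, sex_effect_late = sex_effect_late,
    cog_stability = cog_stability,
    battery_size = as.integer(battery_size),
    battery_loadings = battery_loadings %||%
      seq(0.85, 0.55, length.out = as.integer(battery_size)),
    noise_sd = noise_sd,
    survivor_truncation = survivor_truncation,
    seed = as.integer(seed)
  )
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$n_samples) || cfg$n_samples <= 0L) {
    abort("`n_samples` must be a positive integer.")
  }
  if (is.na(cfg$n_variants) || cfg$n_variants <= 0L) {
    abort("`n_variants` must be a positive integer.")
  }
  cp <- cfg$class_proportions
  need <- c("stop_gain_loss", "splice", "missense", "synonymous")
  if (!all(need %in% names(cp))) {
    abort("`class_proportions` must name stop_gain_loss, splice, missense, synonymous.")
  }
  if (abs(sum(cp) - 1) > 1e-12) abort("`class_proportions` must sum to 1.")
  if (any(cp < 0)) abort("`class_proportions` must be non-negative.")
  rates <- c(missing_rate = cfg$missing_rate,
             haploid_het_rate = cfg$haploid_het_rate,
             frac_x_chromosome = cfg$frac_x_chromosome,
             monomorphic_rate = cfg$monomorphic_rate,
             sex_ratio = cfg$sex_ratio)
  bad <- names(rates)[rates < 0 | rates > 1]
  if (length(bad)) {
    abort(paste0("rate fields must lie in [0, 1]: ", paste(bad, collapse = ", ")))
  }
  if (cfg$sample_maf_dispersion < 0) abort("`sample_maf_dispersion` must be >= 0.")
  if (cfg$cog_stability < 0 || cfg$cog_stability >= 1) {
    abort("`cog_stability` must lie in [0, 1).")
  }
  ms <- cfg$maf_spectrum
  if (!identical(ms$distribution, "beta_truncated")) {
    abort(sprintf("unknown maf_spectrum distribution '%s'.", ms$distribution))
  }
  if (is.null(ms$shape1) || is.null(ms$shape2) ||
      ms$shape1 <= 0 || ms$shape2 <= 0) {
    abort("maf_spectrum beta shapes must be positive.")
  }
  ms$max_maf <- ms$max_maf %||% 0.5
  if (ms$max_maf <= 0 || ms$max_maf > 0.5) {
    abort("maf_spectrum support must lie in (0, 0.5].")
  }
  cfg$maf_spectrum <- ms
  if (cfg$battery_size < 3L || cfg$battery_size > 6L) {
    abort("`battery_size` must be between 3 and 6.")
  }
  if (length(cfg$battery_loadings) != cfg$battery_size) {
    abort("`battery_loadings` must have length `battery_size`.")
  }
  if (any(cfg$battery_loadings <= 0 | cfg$battery_loadings >= 1)) {
    abort("`battery_loadings` must lie in (0, 1).")
  }
  if (cfg$survivor_truncation < 0 || cfg$survivor_truncation >= 1) {
    abort("`survivor_truncation` must lie in [0, 1).")
  }
  cfg
}

#' Read or write a simulation configuration as flat YAML
#'
#' The file mirrors [sim_config()] field names; `class_proportions`,
#' `maf_spectrum` and `battery_loadings` are nested keys.
#'
#' @param path File path.
#' @return `read_sim_config()` returns a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    warn(paste0("ignoring unknown config keys: ", paste(extra, collapse = ", ")))
    raw <- raw[intersect(names(raw), known)]
  }
  if (!is.null(raw$class_proportions)) {
    raw$class_proportions <- unlist(raw$class_proportions)
  }
  exec(sim_config, !!!raw)
}

#' @rdname read_sim_config
#' @param config A `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  out <- unclass(config)
  # named vectors must become maps, not bare sequences
  out$class_proportions <- as.list(out$class_proportions)
  yaml::write_yaml(out, path)
  invisible(path)
}
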