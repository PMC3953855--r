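---
title: "Rare-variant burden and cognitive ability: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant burden and cognitive ability: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exoburden)
```

## The question and the statistic

Cognitive ability correlates with fitness components across the lifespan, so
standing genetic variation in it is a puzzle: directional selection should
deplete it. Under mutation–selection balance that variation is maintained by
a steady inflow of new, mostly deleterious mutations. If that model holds
and the mutational target is large, an individual's *total* load of rare,
protein-altering variants — rather than any single causal locus — should
predict cognitive ability negatively.

The statistic is deliberately simple. For individual $i$ and a selected
variant set $S$,

$$B_i = \sum_{j \in S} g_{ij},$$

where $g_{ij} \in \{0, 1, 2\}$ counts minor alleles. $S$ is defined by a
functional class set (stop-gain/loss, splice, missense — "non-synonymous" in
the burden-test sense — optionally plus synonymous as a negative-control
class) and an in-sample minor-allele-frequency ceiling (MAF $\le 0.01$;
$\le 0.05$ as a sensitivity setting). There are no per-variant weights and
no gene-level collapsing: the hypothesis is about total load, and an
exome-wide sum is also immune to the multiple-testing burden of per-gene
tests.

Burden then enters an ordinary least-squares model per phenotype:

$$y_i = \beta_0 + \beta_a(\text{age}_i - \overline{\text{age}}) +
  \beta_s \, \text{female}_i + \beta_b B_i + \varepsilon_i,$$

with age mean-centred on the analysis subset and sex coded female = 1. The
phenotypes are the Moray House Test (MHT, scored 0–76) taken in childhood
and again in late life, and a late-life fluid general-ability factor $g$:
the z-standardized first principal component of a 3–6 test battery. The
default sensitivity grid crosses 2 MAF thresholds × 5 class sets × 3
phenotypes = 30 models; the burden p-values are Bonferroni-corrected with
$m$ equal to the number of models actually run (reported explicitly,
overridable, because the "right" family — one grid, one cohort, all tables —
is an analysis choice, not a statistical fact).

## The QC cascade

Exome arrays arrive with consortium-level QC already done; this package
implements the in-cohort second stage, in a fixed order and a single pass:

1. heterozygous calls at haploid loci (male X) are set to missing — such a
   call is necessarily a genotyping error;
2. monomorphic variants are removed, judged on *observed* non-missing calls
   (an all-missing variant counts as monomorphic);
3. variants with call rate below 97% are removed (strict `<`: a variant at
   exactly 0.97 is kept);
4. samples with call rate below 97% are removed, mirror rule.

Missingness created in stage 1 counts against the later call rates, and
call rates are not re-evaluated between stages 3 and 4. Rerunning the
cascade on its own output is a no-op *provided stage 4 removed nobody*;
when a sample carrying a singleton minor allele is removed, the variant it
carried becomes monomorphic and only a second pass would catch it. The
single-pass design accepts this: the accounting ledger
(`n_out = n_in − removed`, by stage) stays exact and the residual effect on
an exome-wide sum is negligible.

MAF is computed in-sample on the post-QC matrix (no external reference
panel), X-aware — males contribute one allele (dosage/2), females two — and
the minor-allele orientation is frozen at that point, so burden counts minor
alleles regardless of how the file oriented A1/A2. Ties at $f = 0.5$ orient
to A1; under rare thresholds this is unreachable. Missing calls contribute 0
to the sum under the default `zero` policy (a missing call contributes no
*counted* alleles); `mean_impute` substitutes the variant's mean observed
minor dosage, for users who prefer an unbiased-in-expectation total. Before
modelling, burden outliers are removed by a single-pass 4-s.d. rule on the
primary burden (combined classes, smallest threshold), computed once with no
re-iteration; on a Gaussian burden distribution this removes essentially
nobody, so only gross artefacts are touched. The rule, and the set of
excluded samples, apply to every model in the grid.

## What the simulator emulates

No genotype-level data from such cohorts are deposited, so the package is
developed and validated against a synthetic cohort generator whose defaults
are the study conditions the pipeline targets (a late-1930s birth cohort
followed into old age, ~1000 participants, ~50,000 assayed exome variants):

* **MAF spectrum**: true frequencies from Beta(0.471, 70.3) truncated to
  (0, 0.5], with 6.4% of probes forced monomorphic. These two shape
  parameters were fitted to two constraints: ~78% of segregating variants
  rare (MAF ≤ 0.01), and a 3.04 ratio between the expected burden at the
  0.05 and 0.01 thresholds. With 96% of variants in protein-altering
  classes (2/2/92/4% stop-gain/loss / splice / missense / synonymous), the
  default cohort has a mean rare-allele burden of ~185 at MAF ≤ 0.01 and
  ~560 at ≤ 0.05.
* **Overdispersion**: a sum of independent binomials caps the burden s.d.
  at $\sqrt{\text{mean}} \approx 13.6$; real cohorts show ~16.7. A
  per-sample multiplicative factor on all MAFs (s.d. 0.035, the
  `sample_maf_dispersion` knob) emulates the shared-ancestry overdispersion,
  giving s.d. ≈ 15 at the 0.01 threshold and ≈ 30 at 0.05 — a deliberate
  compromise, since one global multiplier cannot match both thresholds
  exactly.
* **Genotyping error**: per-call missingness (0.2%), and male X calls
  recorded heterozygous at rate 0.5% at segregating sites (monomorphic
  probes cluster cleanly). Ground-truth burdens are banked *before* error
  injection, so QC and burden recovery can be scored exactly.
* **Phenotypes**: MHT scores are linear in mean-centred age (≈ +7.5
  points/year in childhood, −1.5 in late life), sex (female +1.75 childhood,
  −0.4 late life), and centred true burden, plus Gaussian noise, then
  rounded half-up and clamped to the instrument's [0, 76] range (the only
  distributional fact the instrument fixes). A lifelong latent cognitive
  factor with correlation `cog_stability` (default 0.6) to each MHT wave
  also drives the battery, carrying the rank-order stability of cognition —
  without it, survivor selection on health could not restrict the range of
  childhood scores, which is precisely the mechanism of interest. The
  battery has one dominant factor with a loading ladder 0.85–0.55 and unique
  noise $\sqrt{1-\lambda^2}$.
* **Effect scale**: `effect_per_allele` is in MHT points per rare allele
  (so −0.05 means a 1-s.d. burden difference of ~15 alleles costs ~0.75
  points); the latent factor receives the same effect divided by the
  late-life MHT s.d., converting points to s.d. units.
* **Survivor selection**: optionally, the bottom quantile of a latent
  health score (latent g plus unit noise) is dropped, emulating a cohort of
  healthy survivors and the range restriction that attenuates burden
  effects.

What the generator deliberately does **not** contain: linkage
disequilibrium, relatedness, population structure, de novo trio events, or
CNVs. Passing tests therefore demonstrate correctness of the pipeline's
arithmetic and calibration of its inference under independent-variant
sampling; they do not certify behaviour under cryptic relatedness or
stratification, which real analyses must handle upstream.

## Numerical and design choices

* **PCA for g** uses the correlation structure (each test z-scored with the
  $n-1$ divisor) rather than covariance, because battery tests live on
  heterogeneous scales; extraction is then invariant to positive rescaling
  of any test. Complete cases only. The first component's sign is flipped
  when its loading sum is negative, so higher g always means better
  performance; scores are re-standardized to mean 0, variance 1.
* **OLS** is delegated to `stats::lm` on an explicit design matrix;
  standard errors are $\hat\sigma^2 (X^\top X)^{-1}$ with
  $\hat\sigma^2 = \mathrm{RSS}/(n-k)$ and two-sided t p-values. Rank
  deficiency is an error naming the collinear columns, never a silently
  dropped coefficient. No robust/sandwich errors.
* **Diagnostics** are numeric surrogates for the usual residual plots:
  residual mean, skewness, max |standardized residual| with a flag at 4. A
  numerically perfect fit (residual scale below machine precision) reports
  no outliers rather than dividing by ~0.
* **Determinism**: one seed in the config drives all draws through a single
  generator; replicate $k$ of a study uses `seed + k`. Identical config and
  seed give byte-identical output files.
* **Problem sizes in the test-suite**: the replicated calibration checks
  run at reduced scale — 500 null cohorts of n = 500 × 5000 variants for
  type-I calibration, 500 cohorts of n = 1000 × 2000 variants for effect
  recovery (bias within 2 Monte-Carlo s.e.; 95% CI coverage in
  [0.92, 0.98]) — sizes chosen so the whole suite runs on a laptop in
  minutes while leaving Monte-Carlo error well below the tolerances being
  asserted. The per-allele effect scale does not depend on the variant
  count, so recovery conclusions transfer to full-size cohorts.

## Known limitations

* In-sample MAF at n ≈ 1000 is a noisy estimator near the 0.01 boundary;
  variants hop across the threshold between samples of the same population.
  This is faithful to the target analysis (which also used in-sample
  frequencies) but means burden totals are not comparable across cohorts
  genotyped separately.
* The Bonferroni family size is a reporting convention here, not a claim
  about the uniquely correct correction; `m` is printed with every grid.
* The burden statistic aggregates; it cannot localize. A null result
  constrains the *total-load* model, not any per-gene hypothesis.
* The generator's monomorphic fraction (6.4%) is far below a real exome
  array's (~69%) to keep simulated matrices small; monomorphic variants are
  removed unconditionally by QC, so only the removal count, not any
  downstream number, depends on this rate.
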