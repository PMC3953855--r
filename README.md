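# exoburden

Does an individual's total load of rare, protein-altering exome variants
predict a quantitative trait? Under mutation–selection balance, genetic
variation in fitness-correlated traits such as general cognitive ability is
maintained by a steady inflow of new deleterious mutations scattered across
a large mutational target, so the *sum* of rare variants an individual
carries — not any single locus — is the natural predictor. `exoburden`
implements that analysis end to end for exome-array cohorts, together with
a calibrated synthetic-cohort generator so every stage is testable without
access to restricted genotype data.

The core statistic is the unweighted exome-wide burden

> B_i = Σ_{j ∈ S} g_ij,

the count of minor alleles individual *i* carries over the variant set *S*
defined by functional class (stop-gain/loss, splice, missense; optionally
plus synonymous) and in-sample minor allele frequency (MAF ≤ 0.01; 0.05 as
a sensitivity setting). Burden enters an OLS model per phenotype,

> y = β₀ + β_a (age − mean age) + β_s female + β_b B + ε,

reported as unstandardized *b*, s.e. and two-sided *p*, with Bonferroni
correction over the executed model grid (2 thresholds × 5 class sets × 3
phenotypes = 30 models by default). Phenotypes are the Moray House Test
(0–76) in childhood and late life, and a late-life fluid factor *g*: the
z-standardized first principal component of a cognitive battery.

The package is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, and `autoplot()` for the g factor and
the association grid.

## What is in the box

| stage | functions |
|---|---|
| synthetic cohorts | `sim_config()`, `simulate_cohort()`, `write_sim_dataset()`, `apply_survivor_selection()` |
| genotype I/O | `read_plink()` / `write_plink()` (PLINK 1 .bed/.bim/.fam), `read_annotation()`, `read_phenotypes()` |
| quality control | `run_qc()` (haploid-het → monomorphic → variant call rate → sample call rate, single pass, full accounting) |
| burden scoring | `compute_maf()`, `select_rare_variants()`, `compute_burden()`, `burden_table()`, `remove_burden_outliers()` |
| phenotype factor | `derive_fluid_g()` |
| association | `fit_ols()`, `run_burden_model()`, `run_model_grid()`, `bonferroni()`, `diagnostics()` |
| orchestration | `cmd_simulate()`, `cmd_run()`, plus the `exec/exoburden` command-line script |

## Worked example

Simulate a cohort of 500 with a planted effect of −0.05 MHT points per
rare allele, run QC, derive the fluid factor, and fit the grid:

```r
library(exoburden)

cfg <- sim_config(n_samples = 500, n_variants = 5000,
                  effect_per_allele = -0.05, seed = 7)
sim <- simulate_cohort(cfg)
sim
#> <exo_sim> 500 samples x 5000 variants; 2295 rare non-synonymous ground-truth variants
#> mean ground-truth rare-allele burden: 18.1 (s.d. 4.2)

qc <- run_qc(sim$genotypes)
#> QC: 220 haploid het calls set missing; 1581 monomorphic, 0 low-call-rate
#> variants and 0 low-call-rate samples removed; 3419 variants x 500 samples retained

gf <- derive_fluid_g(sim$cohort)
gf
#> <gfactor> first principal component of 6 tests, 500 complete cases
#> variance explained: 58.7%

cohort <- dplyr::left_join(sim$cohort, gf$scores, by = "sample_id")
grid <- run_model_grid(cohort, qc$genotypes)
dplyr::filter(grid, class_set == "combined", maf_threshold == 0.01) |>
  dplyr::select(phenotype, n, b_burden, se_burden, p_burden, p_bonferroni)
#> # A tibble: 3 × 6
#>   phenotype     n b_burden se_burden p_burden p_bonferroni
#>   <chr>     <int>    <dbl>     <dbl>    <dbl>        <dbl>
#> 1 mht_child   500 -0.268      0.126    0.0348            1
#> 2 mht_late    500  0.0260     0.0932   0.780             1
#> 3 g           500 -0.00537    0.0109   0.623             1
```

Reading it: each row is one model. `b_burden` is the change in the
phenotype per additional rare allele — the childhood-MHT estimate (−0.27)
is nominally significant (*p* = 0.035) at this deliberately small scale,
but does not survive Bonferroni correction over the 30-model grid
(`p_bonferroni` = 1), which is exactly how a modest total-load signal looks
in an underpowered cohort. At full scale (50,000 variants, mean burden
~185), the same per-allele effect is estimated against a burden s.d. of
~15 rather than ~4.

From the shell, the same pipeline is:

```sh
exec/exoburden simulate --seed 1 --out simdir
exec/exoburden run --bed simdir/cohort.bed --annotation simdir/annotation.tsv \
    --phenotypes simdir/phenotypes.tsv --out rundir
```

`rundir/` then contains `qc_report.tsv`, per-threshold burden tables,
`gfactor.tsv` (+ loadings), `associations.tsv` (one row per model) and
`descriptives.tsv` (the cohort summary table).

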