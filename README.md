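# gradexpr

Pooled-library RNA-seq differential expression and carcass-trait analysis
across USDA beef quality grades.

## The problem

Quality grade (Standard < Select < Choice) prices beef carcasses and is
driven largely by marbling. Pilot transcriptome studies that relate grade
to muscle gene expression typically sequence *pooled* libraries — here,
each animal's longissimus library randomly allocated to one of two pools
per grade (16 steers: 6 Choice, 5 Select, 5 Standard) — and compare grades
at the pool level, alongside conventional carcass and Warner–Bratzler
shear-force analysis on the unequal-sized groups.

`gradexpr` implements that analysis end to end, for anyone who works with
pooled count data or grade-structured phenotypes:

* **Pooled z-test DE.** Per gene, condition-summed counts `x` and library
  totals `N` are compared via

  `Z = (√(x₁/N₁) − √(x₂/N₂)) / √(1/(4N₁) + 1/(4N₂))`,
  `p = 2Φ(Z)` (Z < 0) or `2(1 − Φ(Z))`,

  the square-root transform being variance-stabilizing for count
  proportions (Var √(x/N) ≈ 1/(4N) under Poisson sampling). Bonferroni
  correction over tested genes; fold change `≥ 1` with up/down direction
  relative to the first condition; two list rules: raw p < 0.05 (broad DE
  list) and Bonferroni p ≤ 0.01 with > 2-fold change (high-confidence
  subset). A `raw`-proportion variant of the statistic is available behind
  a flag.
* **Gene-set over-representation** of the up/down subsets against any GMT
  collection: exact hypergeometric (Fisher) tail or the conservative EASE
  variant (overlap discounted by one gene), background defaulting to all
  tested genes, terms flagged at raw p < 0.1.
* **Carcass statistics.** Fixed-effects OLS with marginal (type III) F
  tests, least-squares means (equal-weight marginals, appropriate for
  unequal group sizes), unadjusted pairwise comparisons rendered as
  compact superscript letters, and a grade × aging interaction screen
  that decides between interaction and main-effects models.
* **A calibrated synthetic-data generator**: negative-binomial per-animal
  counts with known spiked genes, balanced random pooling, and additive
  grade + aging phenotypes calibrated to the published grade/aging tables
  — so the whole pipeline runs, and is tested, without any download.

## Worked example

```r
library(gradexpr)

# study-scale cohort: 16 animals, two pools per grade, ~1M reads/animal,
# 5% of 2000 genes spiked (fold 4 in Choice vs Standard)
design <- design_spec()
config <- count_sim_config(n_genes = 2000, baseline_mean = 100,
                           dispersion = 0.05, de_fraction = 0.05,
                           effect_folds = c(Standard = 1, Select = 2, Choice = 4),
                           library_depth = 1e6)
animal <- simulate_animal_counts(config, design, seed = 11)
pools  <- assign_pools(design, seed = 12)
cm     <- form_pool_libraries(animal, pools)

de <- run_de(cm, c("Choice", "Standard"))
head(de[, c("gene", "cpm1", "cpm2", "Z", "p_bonf", "fold", "direction")], 3)
#>      gene cpm1  cpm2     Z    p_bonf  fold direction
#> 1 g000006 2088 457.1 80.27 4.45e-305 4.566        up
#> 2 g000012 1673 532.1 58.87 4.45e-305 3.143        up
#> 3 g000034 1798 572.1 61.02 4.45e-305 3.142        up
```

Of 2000 tested genes, 1636 fall in the broad raw p < 0.05 list but only
100 in the > 2-fold, Bonferroni p ≤ 0.01 subset — exactly the 100 spiked
genes, with zero false positives. The gap is instructive: with a fixed
sequencing budget, spiking 5% of genes reallocates read proportions of
every *null* gene by ~15%, and at multi-million-read depth the z-test has
power to see that shift; the fold-change filter is what restores
specificity. (This same mechanism is why pool-level tests on real data
report DE lists in the thousands.)

```r
model <- calibrate_phenotype_model()   # from the shipped grade/aging tables
ph    <- simulate_phenotypes(model, design, seed = 13)

interaction_screen(ph$shear, "shear_n", "grade", "aging_day")[c("F", "p", "decision")]
#> F = 1.44, p = 0.20 -> "main_effects"

fit <- fit_carcass_model(ph$shear, "shear_n", c("grade", "aging_day"))
pairwise_letters(ls_means(fit, "grade"))
#>      level lsmean    se letters
#> 1   Select  83.77 2.336       a
#> 2   Choice  72.32 2.132       b
#> 3 Standard  69.09 2.336       b
```

The simulated cohort reproduces the published tenderness structure:
steaks from Select carcasses shear hardest and separate (letter `a`),
while Choice and Standard share a letter at this sample size.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (`01_simulate.R` → `02_differential_expression.R` →
`03_enrichment.R` → `04_carcass_stats.R`), writing tables under
`results/`; `run_pipeline()` does all of it from one validated YAML
config with a reproducibility manifest.

## Package layout

* `R/` — all computation: generator (`design.R`, `calibration.R`,
  `simulate_*.R`), DE (`pooled_de.R`), enrichment (`enrichment.R`),
  phenotype models (`carcass_stats.R`), I/O and orchestration (`io.R`,
  `pipeline.R`).
* `analysis/` — numbered workflow drivers over the package.
* `vignettes/grade-expression-methods.Rmd` — the methods account: model
  assumptions, calibration details, design decisions, limitations.
* `inst/extdata/` — the phenotype calibration (YAML) and a small
  synthetic GMT collection for demonstrations.
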