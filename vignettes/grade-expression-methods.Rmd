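---
title: "Methods: pooled-library differential expression and carcass-trait analysis across beef quality grades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-library differential expression and carcass-trait analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradexpr)
```

## The problem this package addresses

Beef carcasses are priced largely by USDA quality grade (Standard < Select <
Choice), which is driven by marbling — intramuscular fat — and maturity.
A pilot design that asks whether muscle gene expression at harvest differs
between grades faces two statistical constraints: individual animal RNA
libraries are pooled (two pools per grade, as biological replicates), so
per-animal biological variance is unobservable and a pool-level test on
summed read counts is the only option; and group sizes are small and
unequal (6 Choice, 5 Select, 5 Standard steers), so carcass and tenderness
comparisons need model-based marginal means rather than raw group means.

`gradexpr` implements that full analysis as testable code: a pooled z-test
for differential expression between grade-level libraries with Bonferroni
correction and fold-change classification, gene-set over-representation of
the resulting up/down lists, fixed-effects LS-means summaries of carcass
and Warner–Bratzler shear-force traits with compact letter displays, and a
synthetic-data generator calibrated to the published phenotype tables so
every stage runs and is verified without any external download.

## The pooled z-test

For one gene and two conditions, let $x_1, x_2$ be the gene's read counts
summed over each condition's pools and $N_1, N_2$ the summed library totals
(total aligned reads). The test compares the read proportions $x_i/N_i$
with the statistic

$$Z = \frac{\sqrt{x_1/N_1} - \sqrt{x_2/N_2}}
           {\sqrt{\tfrac{1}{4N_1} + \tfrac{1}{4N_2}}},
\qquad
p = \begin{cases} 2\,\Phi(Z) & Z < 0\\ 2\,(1 - \Phi(Z)) & Z \ge 0.\end{cases}$$

The square-root transform is the variance-stabilizing transform for count
proportions: if $x \sim \mathrm{Poisson}(N\pi)$ then
$\mathrm{Var}\,\sqrt{x/N} \approx 1/(4N)$ to first order, independent of
$\pi$, which is exactly the denominator's per-condition term. This makes
the statistic standard normal under the null for any expression level, and
the package's null-calibration test confirms a 5% rejection rate at the
nominal 0.05 level with Poisson counts.

A `raw` variant with untransformed proportions in the numerator (same
denominator) is provided behind `variant = "raw"`. For proportions below
$1/4$ — i.e. all transcript-scale proportions — it is strictly more
conservative, because
$p_1 - p_2 = (\sqrt{p_1}-\sqrt{p_2})(\sqrt{p_1}+\sqrt{p_2})$ and
$\sqrt{p_1}+\sqrt{p_2} < 1$; at typical per-gene proportions of $10^{-4}$
it essentially never rejects. The `sqrt` variant is therefore the default:
it is the only reading under which the $1/(4N)$ variance is coherent.

Multiple testing uses Bonferroni, $p_{\text{bonf}} = \min(1, m\,p)$, with
$m$ the number of genes actually tested. Genes with $x_1 + x_2 <$
`min_total_count` (default 10) are excluded from testing and from $m$;
the universe behind a published gene count is rarely stated, so the family
is defined operationally as "genes with enough reads to test" and the
default is overridable down to 1.

Two gene lists are defined, mirroring the reporting conventions of
pool-based pilot studies: the broad DE list (raw $p < 0.05$) and the
high-confidence subset (Bonferroni $p \le 0.01$ **and** fold change $> 2$).
Fold change is the ratio of pseudocount-stabilized rates
$r_i = (x_i + 0.5)/N_i$, reported $\ge 1$ with a direction (`up`/`down`)
relative to the first-named condition; the pseudocount (default 0.5,
settable to 0) keeps zero-count genes finite, and a gene with zero counts
in both conditions under pseudocount 0 is reported `untestable` rather
than propagating NaN. Normalized abundances are reported as counts per
million of the condition total. Output rows are sorted by raw p with ties
broken by gene id so reruns are byte-identical.

### Numerical notes

$\Phi$ is evaluated with R's `pnorm` (verified in the test suite against
an independent quadrature oracle to $10^{-12}$ absolute over
$[-8, 8]$). For extreme statistics ($|Z| \gtrsim 38$) the two-sided p
underflows double precision; it is floored at the smallest positive
normalized double so p remains in $(0, 1]$ and downstream corrections
never see a zero.

## Gene-set over-representation

The functional-analysis stage is a from-scratch over-representation test
over user-supplied GMT collections (KEGG, GO, or any export), not a client
of any hosted annotation service. For a list of $n$ background genes, a
term with $K$ background members, and an overlap of $k$,

$$p_{\text{fisher}} = P(X \ge k), \qquad X \sim
\mathrm{Hypergeom}(M, K, n),$$

computed exactly via the hypergeometric tail (no normal approximation);
the test suite verifies it against full enumeration of all
$\binom{M}{n}$ draws for every table with $M \le 12$. The EASE mode is
the conservative modified Fisher score used by DAVID-style tools: the
observed overlap is discounted by one gene ($k \mapsto \max(k-1, 0)$), so
single-gene overlaps are never significant; EASE $\ge$ Fisher for every
table. Both modes are provided because published tables rarely state
which score they report.

Design choices made here, where the convention is genuinely open:

* **Background** defaults to the genes actually tested for DE — the
  universe the list was drawn from — and is overridable.
* **Which list feeds enrichment**: the high-confidence up and down lists,
  run separately, mirroring the separate upregulated/downregulated tables
  such studies print.
* **No correction across terms**: results are flagged at raw $p < 0.1$,
  the convention of the tables being emulated; this is reported, not
  hidden, and the returned p column is raw in both modes.

## Carcass and tenderness statistics

Responses (shear force in newtons per steak aging cell, and per-carcass
traits: hot carcass weight, fat depth, ribeye area, KPH %, yield grade,
marbling score) are continuous, so "GLM" here is ordinary least squares
with fixed categorical effects — no link function. F tests are marginal
(type III, via sum-to-zero contrasts), chosen over sequential sums of
squares because the design is unbalanced and the factor tests should not
depend on entry order.

**LS means** give each level of the other factor equal weight — the model
prediction averaged over a balanced grid, not over the observed (unequal)
cell counts. For a one-way model the LS mean reduces to the group mean,
which the suite asserts as a property over random unbalanced data; the
two-factor unbalanced case is checked against an explicit normal-equations
oracle to $10^{-8}$. Computation is delegated to `emmeans` on the `lm`
fit; standard errors come from the coefficient covariance.

**Pairwise comparisons** are unadjusted t-tests on LS-mean differences at
the residual df (the PDIFF convention that published superscript letters
encode); Tukey adjustment is available behind `adjust = "tukey"` but off
by default. Letters are assigned by an insert-and-absorb algorithm
(implemented in the package): start with one class holding all levels,
split any class containing a significantly different pair, absorb classes
contained in others, then letter the classes in descending-mean order so
the highest mean is `a`. The resulting partition is invariant to input
row order.

**Interaction screening** fits the grade × aging-day model first and
records a decision: if the interaction is not significant at $\alpha =
0.05$ the pipeline proceeds with main-effects models (the analysis path
taken when aging does not modify grade differences); otherwise it flags
that the interaction must be kept. The decision, F and p are recorded in
the run manifest.

Steak-level shear records are treated as independent observations (no
animal random effect), consistent with a main-effects fixed-model
analysis of averaged shear measurements; mixed models are out of scope.

## The synthetic-data generator

The generator exists so the whole pipeline is testable at study scale and
beyond, with known ground truth. It emulates, in order:

1. **Cohort**: 16 animals, 6/5/5 across Choice/Select/Standard (the
   default `design_spec()`), extensible to arbitrary designs.
2. **Per-animal counts**: negative binomial with mean $\mu$ and variance
   $\mu + \alpha\mu^2$; $\alpha = 0$ is drawn as exact Poisson. Default
   $\alpha = 0.05$, a typical within-cohort RNA-seq overdispersion for
   genetically similar, identically managed animals. A random
   `de_fraction` of genes is spiked by a per-grade fold multiplier
   (reference grade 1); spiked identities are returned as ground truth.
3. **Depth normalization**: each grade's per-gene means are rescaled so
   the expected per-animal total equals `library_depth` ($10^6$ by
   default). Sequencing yields a fixed read budget, so spiking genes up
   reallocates proportions instead of adding reads. A consequence worth
   stating plainly: spiking shifts the proportions of *null* genes too
   (by ~15% when 5% of genes carry fold 4), and at multi-million-read
   depths the z-test has power to see that shift — the broad raw-p list
   therefore inflates, exactly as pool-level tests do on real data, and
   it is the fold-change filter in the high-confidence subset that
   restores specificity (the spike-recovery test: 10/10 spikes, ≤ 1 false
   positive).
4. **Pooling**: each grade's animals are randomly split into pools whose
   sizes differ by at most one (6 → 3+3, 5 → 3+2); pool counts are the
   member sums. "Random allocation" to pools is all the study states, so
   the balanced split is a design choice. An optional multinomial
   downsampling on gene proportions equalizes pool depths; exact
   hypergeometric thinning was rejected as indistinguishable at these
   depths. Whether real pools were equimolar RNA mixtures or summed
   libraries is unknowable from the record; sum-then-downsample is one
   defensible reading and is documented as such.
5. **Phenotypes**: shear force follows the additive model
   $y = \mu + g_{\text{grade}} + a_{\text{day}} + \varepsilon$,
   $\varepsilon \sim N(0, \sigma_{\text{grade}}^2)$, with effects
   calibrated from the published marginal tables: the grand mean is the
   unweighted mean of the five aging-day means (73.96 N), aging effects
   are exact deviations (summing to zero), and grade effects are
   deviations of the grade means from the same grand mean. The two
   published margins are rounded independently and imply grand means
   differing by 0.007 N; calibration verifies they agree within 0.1 N and
   carries the residual imbalance rather than forcing effects to sum to
   zero, so each grade's simulated marginal mean matches its printed
   value. Non-aged traits are independent normal draws per grade with the
   printed mean and SD, truncated below at 0 (marbling at 100, the scale
   floor below "Traces"). The marginal-over-aging reading of the grade
   shear means is assumed — consistent with the interaction having been
   tested against aging and dropped.

All randomness flows from one explicit integer seed through a local RNG
scope; nothing touches or depends on the global random state, and equal
seeds give bit-identical outputs across every generator operation.

### What the generator does not emulate

Traits are drawn independently within grade — the published tables print
no covariances, so none are modeled; real HCW/REA/fat/marbling are
correlated. Grade is a design label, not derived from simulated marbling:
the study sampled animals by realized grade, and simulating the grading
process itself is out of scope. There is no RIN-dependent degradation,
ribosomal-depletion bias, batch structure, isoform structure, or read-level
(FASTQ/alignment) simulation. Passing tests on synthetic data therefore
demonstrate the statistical machinery and its calibration, not robustness
to those real-data artifacts.

## Verification strategy and problem sizes

The test suite checks each stage against an independent oracle: quadrature
for the normal CDF (grid of 1,000 points, $10^{-10}$), a separate
arithmetic path for the z statistic, full enumeration for hypergeometric
tails ($M \le 12$), and explicit normal equations for F, p, LS means and
SEs ($10^{-8}$). Statistical behavior is checked by simulation: null
calibration on 10,000 Poisson genes at depth $10^6$ (rejection rate
0.05 ± 0.01; KS distance to uniform < 0.02), spike-in recovery (200
genes, 10 spiked at fold 4, Poisson), and recovery of the published
phenotype means from 20,000 simulated animals per grade, each within
3 Monte-Carlo standard errors.

One subtlety: the published superscript pattern for shear (Select `a`,
Choice `b`, Standard `b`) is a property of the *study-scale* cohort. The
calibrated generator gives Choice and Standard truly different means
(71.3 vs 66.3 N), so at 20,000 animals per grade every pairwise difference
is significant and the letters must read `a`/`b`/`c`; at n = 16 the 5 N
gap sits within noise (≈ 0.7 probability of sharing a letter per cohort)
while Select separates almost surely. The suite therefore asserts the
printed pattern as the modal pattern over 200 replicate study-sized
cohorts, which is stable under any seed, rather than as a single-draw
assertion that would be false at scale and flaky at n = 16.

## Known limitations

* The pooled z-test models only sampling (Poisson-scale) noise between
  pooled libraries; with two pools per grade, true inter-animal variance
  is not estimable, and p-values are anticonservative in its presence.
  That is a property of the design being implemented, not a remediable
  implementation detail; dispersion-aware tests are deliberately out of
  scope.
* Bonferroni's family is "genes tested", which depends on the min-count
  filter; users comparing against published counts should set the filter
  to their universe definition.
* Enrichment p-values are raw; with many terms, the p < 0.1 flag will
  mark ~10% of null terms.
* The compact letter display uses unadjusted pairwise tests by default,
  as the superscript convention implies; family-wise error over pairs is
  not controlled unless `adjust = "tukey"` is chosen.
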