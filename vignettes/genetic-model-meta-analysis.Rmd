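---
title: "Pooling case-control SNP studies from genotype counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling case-control SNP studies from genotype counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genemeta)
```

## The problem

Candidate-gene association studies report, for one single-nucleotide
polymorphism (SNP), the genotype counts of cases and controls:
$(n_{11}, n_{12}, n_{22})$ subjects carrying zero, one or two copies of the
risk allele. Individual studies are small and their results conflict, so the
field pools them. genemeta implements that pipeline end to end for genotype
count data, with the Fas/FasL promoter polymorphisms in preeclampsia as its
packaged worked example: apoptosis of placental trophoblasts is disturbed in
preeclampsia, making the Fas (CD95) receptor-ligand axis a natural candidate
pathway, and nine case-control study arms (834 cases, 1072 controls) have
examined the Fas -670 A/G promoter variant alone.

## Genetic models

A 3x2 genotype table is dichotomised into a 2x2 table before pooling.
With allele 2 the risk allele, `build_contrast()` supports the five standard
contrasts:

| model | exposed | unexposed |
|---|---|---|
| allele | $2 n_{22} + n_{12}$ | $2 n_{11} + n_{12}$ |
| dominant | $n_{22} + n_{12}$ | $n_{11}$ |
| recessive | $n_{22}$ | $n_{12} + n_{11}$ |
| homozygote | $n_{22}$ | $n_{11}$ |
| heterozygote | $n_{12}$ | $n_{11}$ |

The allele model treats each subject as two independent alleles, the usual
convention (and the one that reproduces the packaged dataset's published
single-study values). Exposure is always allele 2, so pooled odds ratios
above 1 mean the variant confers risk. No additive/trend model is provided.

## Per-study effects and pooling

Per-study effects are Woolf log odds ratios, $\hat\theta_i = \log(a d / b c)$
with $SE_i = \sqrt{1/a + 1/b + 1/c + 1/d}$. A table containing a zero cell
gets the Haldane-Anscombe correction (0.5 added to all four cells, flagged in
the output); the packaged dataset has no zero cells, so its results are
unaffected.

Fixed-effect pooling (`pool_fixed_mh()`) is Mantel-Haenszel,
$OR_{MH} = \sum_i a_i d_i / n_i \; / \; \sum_i b_i c_i / n_i$, with the
Robins-Breslow-Greenland variance for $\log OR_{MH}$ — the stratified
estimator that tolerates sparse cells and the default of the major
meta-analysis packages this workflow mirrors. Heterogeneity is Cochran's
$Q = \sum_i w_i (\hat\theta_i - \bar\theta_{IV})^2$ with inverse-variance
weights $w_i = 1/SE_i^2$ about the inverse-variance fixed mean, summarised as
$I^2 = \max(0, (Q - df)/Q)$. Random-effects pooling (`pool_random_dl()`) is
DerSimonian-Laird: the moment estimator
$\hat\tau^2 = \max\{0, (Q - df) / (\sum w_i - \sum w_i^2 / \sum w_i)\}$
re-weights studies by $1/(SE_i^2 + \hat\tau^2)$.

**Method selection.** `select_method()` chooses random effects when
$I^2 \ge 50\%$, else fixed. The published analysis this package reproduces
stated its rule as "$I^2 < 50\%$ or $p > 0.1$ means fixed", but its own
result rows use random effects at $p_{het} = 0.117$ ($I^2 \approx 59\%$) and
fixed at $p_{het} = 0.083$ ($I^2 \approx 43\%$); only the $I^2$ criterion is
consistent with every row, so it is the default, with the threshold exposed
as `i2_threshold`.

**Subgroups.** `subgroup_analysis()` re-selects the method within each
subgroup from that subgroup's own $I^2$ (a subgroup is its own
meta-analysis). Published tables sometimes instead carry the total
analysis's method into every subgroup; pass `method = "fixed"` or
`"random"` to reproduce that behaviour. Singleton subgroups are passed
through as the single study's Woolf estimate, flagged `single`, never pooled.

## Hardy-Weinberg screening

`hwe_test()` is the plain Pearson chi-square (no continuity correction) of
the observed control genotypes against $(1-q)^2, 2q(1-q), q^2$ at the
observed allele frequency, 1 df, $\alpha = 0.05$. Studies out of equilibrium
are flagged and reported but **not** excluded from pooling — the packaged
analysis pools the FasL -844 C/T studies despite both control arms failing
the screen, and dropping them is the analyst's call, not the package's.
A monomorphic arm has nothing to test and is returned as in-equilibrium with
a `monomorphic` flag and a warning. An exact test is deliberately out of
scope; the chi-square is what this literature reports.

## Publication bias

`egger_test()` regresses the standardized effect $\hat\theta_i / SE_i$ on
precision $1/SE_i$ by ordinary least squares and tests the intercept with a
t reference on $k - 2$ df (the classical 1997 formulation). `begg_test()`
rank-correlates the variance-stabilized deviations from the fixed pooled
mean with the sampling variances and uses the continuity-corrected normal
approximation of Kendall's tau (the 1994 formulation). Both refuse to run on
fewer than 3 studies; with so few studies their power is minimal, which is
why the pipeline reports them alongside, not instead of, the estimates.

## The synthetic-data generator

`simulate_dataset()` draws a whole meta-analysis with known truth. Study i
receives $\theta_i = \log OR + N(0, \tau^2)$; the case allele frequency
follows on the odds scale, $q_{1i} = q_0 e^{\theta_i} / (1 - q_0 + q_0
e^{\theta_i})$, which cannot leave $(0, 1)$; genotypes are multinomial under
Hardy-Weinberg proportions at $q_0$ (controls) and $q_{1i}$ (cases). The
truth is injected on the allelic-odds scale only — dominant and recessive
"truths" are implied, not set, keeping a single coherent parameterisation.
Defaults (k = 9 studies of 150/150, $q_0 = 0.3$, OR = 1.5, $\tau = 0$)
mirror a realistic promoter-SNP meta-analysis of the packaged dataset's
shape: nine arms, control risk-allele frequency near 0.30, allelic OR near
1.5. All draws come from one seeded stream in fixed study order, so a seed
pins down the dataset exactly; no per-study substreams are needed at these
sizes.

What the generator emulates: multinomial genotype sampling under HWE,
between-study heterogeneity on the log-OR scale, unbalanced arm sizes,
metadata composition. What it does not: departure from HWE in controls,
genotyping error, confounding, linkage between SNPs, or correlated study
arms (each simulated study is independent, unlike the packaged dataset's
shared Sziller control arm). Calibration results on simulated data therefore
validate the estimators, not the epidemiology of any real dataset.

The validation suite checks, at sizes chosen to keep the whole test run in
tens of seconds: DL interval coverage of the true OR over 1000 simulated
meta-analyses (93-97% band), type-I error of the Q test over 1000 null
replicates (3-7%), bias of the pooled DL log-OR below 0.02 over 1000
replicates at $\tau = 0.2$, and the nominal 5% rejection rate of the HWE
screen across 300 simulated control arms.

## Numerical choices and degenerate inputs

* 95% intervals use the normal quantile 1.96...; all computation is at full
  precision, and only the markdown writer rounds (OR to 2 decimals, p to 3,
  `<0.001` below that).
* $I^2$ is clamped to $[0, 100]$ and $\hat\tau^2$ to $[0, \infty)$; $Q = 0$
  with a single pair of identical studies gives $I^2 = 0$, fixed effects.
* k = 1 anywhere in the pipeline means pass-through: the study's own Woolf
  estimate, labelled `single`/"not pooled"; heterogeneity is reported as the
  degenerate (Q = 0, df = 0, p = 1) convention with a flag.
* Mantel-Haenszel pooling runs on uncorrected cells (it tolerates zeros);
  the continuity correction only affects per-study display estimates and the
  inverse-variance machinery.
* Zero cells in *every* study of a contrast would make $\sum a_i d_i / n_i$
  or $\sum b_i c_i / n_i$ vanish; that degenerate case errors rather than
  returning an infinite OR.

## Known limitations

* No Peto OR, Hartung-Knapp adjustment, meta-regression, trim-and-fill, or
  trial sequential analysis.
* Mantel-Haenszel and inverse-variance fixed estimates can differ by a few
  percent when k is small and homozygote cells are single-digit (observable
  on the packaged FasL SNPs); the package reports MH for fixed pooling
  throughout, and exports `pool_fixed_iv()` so the gap can be inspected.
* The heterozygote-model analysis of the packaged dataset is a case study in
  why reanalysis from counts matters: the published pooled value for that
  model cannot be derived from the published genotype counts (the
  population-based single-study row is internally inconsistent with its own
  counts), and this package reports what the counts actually give.
* Forest and funnel output are data tables (`forest_data()`), not figures.

## Problem sizes

Everything the package computes on the packaged 15-record dataset runs in
well under a second. The simulation-based calibration checks use 1000
replicates of 9-study meta-analyses (150-300 subjects per arm), sized so the
full test suite completes in under a minute on one CPU.
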