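---
title: "Divergence–convergence analysis of multi-tissue lifespan transcriptomes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence–convergence analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made.

## The question and the two-period model

Multi-tissue, whole-lifespan designs sample several tissues (here four:
cortex, liver, lung, muscle) from the same individuals across the whole
lifespan. The lifespan is split into **development** (before sexual
maturity) and **ageing** at a boundary of 90 days (mouse). The boundary
is configurable (`period_boundary`); any boundary between the oldest
juvenile and youngest adult sample produces the same split, and period
assignment is a pure function of age and boundary.

All trajectory statistics are Spearman correlations with age, computed
separately per period. Rank correlation is deliberate: trends in this
design are assumed monotone within a period but not linear, and Spearman
is invariant to any monotone transform of age (so log-age versus raw age
does not matter for detection).

## The DiCo statistic

For gene $g$ and individual $i$, the inter-tissue coefficient of
variation is

$$\mathrm{CoV}(g,i) = \frac{\mathrm{sd}_t\, x(g,i,t)}{\mathrm{mean}_t\, x(g,i,t)},$$

with the sample ($n-1$) standard deviation — the default of the
statistical environment this analysis tradition uses — and only
individuals possessing *all* tissues contribute (an individual missing a
tissue is dropped with a message). A gene whose across-tissue mean is 0
for an individual has no defined CoV there; its trend is computed on the
remaining individuals if at least `min_individuals = 3` remain.

A gene is **divergent** in a period if its CoV–age Spearman rho is
positive, **convergent** if negative, and **DiCo** if divergent in
development and convergent in ageing — by default *without* a
significance level, with a significant-only variant (BH q < 0.1 within
each period's trend family) behind `q_cutoff`. Exactly zero rho is
treated as undefined rather than assigned a side; with continuous data
this is a measure-zero event.

## Dependence-preserving permutations

Tissues of one animal are not independent samples, so every significance
test shuffles **individual ages, once per round, identically across
tissues**. Reversal and DiCo tests additionally keep development fixed
and permute ages only among ageing-period individuals, because their
statistics condition on the developmental direction. p-values are raw
proportions of rounds at least as extreme (they can be exactly 0); the
$(k+1)/(B+1)$ correction is available behind `add_one`. The estimated
false-positive proportion (eFPP) is the null median divided by the
observed statistic.

One property of this scheme is worth knowing before interpreting small
p-values: with ~9 ageing animals, a single shared shuffle per round means
that when genes are strongly correlated with one another (as in noiseless
synthetic data), the null distribution of set-level statistics becomes
bimodal — rounds whose permutation happens to be rank-aligned with true
age reproduce the observed pattern nearly exactly. The test is then
honest but coarse. On noisy data, per-gene trends decorrelate and the
null concentrates; the package's calibration checks (200 replicate null
datasets, B = 200 rounds) verify that all four tests reject at the
nominal 5% rate within the binomial band.

The permutation RNG is a single seeded R stream consumed sequentially
(`set.seed(seed)` then one `sample()` per round). A counter-based
generator keyed by (seed, round) would make rounds order-independent and
parallelisable; base R has no such generator, nothing in the package
consumes rounds out of order, and a single stream keeps reruns exactly
reproducible, so the simpler scheme was chosen.

## Preprocessing

Genes undetected (value 0) in 25% or more of all samples are removed
(`max_zero_fraction = 0.25`, "25% or more" implemented as
`zero fraction >= threshold`). Values are then log2(x+1)-transformed and
quantile-normalised across **all samples jointly**. Quantile
normalisation dialects differ in tie handling; here tied entries receive
the mean of the reference distribution over their tied rank positions
(the "average" convention). This is part of the contract and is tested
against a brute-force oracle, with `limma::normalizeQuantiles` as an
independent cross-check on tie-free data (limma interpolates at the
average rank, which differs for odd tie groups of three or more).

A caveat surfaced by testing: on low-dimensional, strongly structured
synthetic data, forcing identical column distributions redistributes the
planted age structure into genes that had none, which costs DiCo
precision while leaving sensitivity and the transcriptome-wide CoV signs
intact. With real transcriptome dimensionality the per-gene effect is
far smaller, but recovery benchmarks in this package are therefore run
on the generator's native (already log-scale) values.

## Spearman p-values and multiple testing

Rho is the Pearson correlation of mid-ranks (ties averaged); the
two-sided p uses the t-approximation on $n-2$ degrees of freedom,
matching `cor.test(exact = FALSE)` to numerical precision (tested to
1e-10). At $n = 7$–$9$ per period the approximation is crude but is what
standard implementations return; its miscalibration is slight (verified
on null data: the fraction of p < 0.1 stays near 0.1) and all
significance statements downstream either use BH control or a
permutation null. BH adjustment is `stats::p.adjust(method = "BH")`,
applied within each tissue × period family (the family in which
per-tissue significant counts are reported); constant-expression genes
carry `NA` and are excluded from reversal/overlap denominators.

## Tissue specificity and identity loss

Effect sizes are Cohen's d with pooled standard deviation, computed on
development samples only (ageing is precisely where specificity is
hypothesised to erode, so it must not inform the calling). Each gene is
assigned to its highest-d tissue — ties broken deterministically to the
first tissue in sort order — and the top quartile (> Q3, type-7
quantile, the environment default) of each assigned group is flagged
specific, so by construction each tissue contributes 25% (± one gene) of
its assigned genes.

"Maximum expression change during ageing" is interpreted as the maximum
**absolute** OLS slope of expression on log2(age); a signed-maximum
variant sits behind `signed_max`. The 2×2 table crosses the sign of that
maximal change with whether it occurs in the native tissue; the odds
ratio is the conditional maximum-likelihood estimate from
`fisher.test` (the sample cross-product OR is also reported, and the
two-sided p is verified against exhaustive hypergeometric enumeration).

## Heteroscedasticity checks

Convergence in ageing could in principle be an artefact of noise rising
with age (regression toward the mean). Two per-gene measures are
computed in every tissue: the Spearman correlation of absolute OLS
residuals (expression on log2 age) with age, and the Cook–Weisberg score
test (squared residuals scaled by the ML error variance, regressed on
fitted values; statistic = half the regression sum of squares, $\chi^2_1$
reference). The score test is implemented vectorised over genes and is
verified to agree with `car::ncvTest` to 1e-10; it is invariant to
scaling of the response. DiCo and DiDi gene sets are compared per tissue
by two-sided KS tests.

## Deconvolution

Bulk profiles are regressed on cell-type signature means over shared
genes, with an intercept and **unconstrained** coefficients — a plain
linear model, so negative coefficients are possible and meaningful as
relative (not compositional) contributions. An NNLS variant is provided
behind `nonnegative = TRUE` for users who want proportion-like output;
it is not the default model. No rescaling is applied before regression:
bulk and signature are assumed to be on a shared normalised scale, and
the resampling test (random gene sets of the same size as the DiCo set)
is in any case invariant to gene-wise monotone rescaling of the
comparison. Rank-deficient signatures abort with the collinear cell
types named. Cross-tissue cell-type pairs are fixed at the youngest
(reference) age group and their correlations tracked across age groups;
within-tissue convergence applies the same CoV machinery across cell
types instead of tissues.

## The synthetic generator

The generator defines the study conditions for every test: 4 tissues ×
16 individuals (7 development ages 2–61 d, 9 ageing ages 93–904 d,
roughly log-spaced, one individual per age), gene classes
DiCo/DiDi/UD/DU/flat, i.i.d. Gaussian noise, baselines uniform on
8–12 (log2-like units).

All planted trends are linear in log2(age) and continuous at the period
boundary. Two pivot geometries keep the classes identifiable:

- **DiCo/DiDi** genes pivot at the youngest age: one outlier tissue's
  expression departs at slope ± `effect_size` through development, so
  inter-tissue spread grows; in ageing the outlier returns 90% of the way
  back (DiCo) or keeps departing at a quarter rate (DiDi). The 90%
  return keeps the spread strictly positive (no crossing, hence a
  monotone CoV); the reduced DiDi ageing rate keeps the planted
  *transcriptome-wide* mean-CoV trend negative in ageing whenever the
  DiCo fraction is at least the DiDi fraction.
- **Reversal (UD/DU)** genes pivot at the boundary with all-tissue
  slopes of common sign but ±30% (development) / ±15% (ageing)
  tissue heterogeneity: their tissue profiles converge to a common value
  at the boundary and fan out again in ageing. This makes the reversal
  classes decisively convergent-then-divergent in CoV space, so they
  cannot masquerade as DiCo, while their per-tissue expression still
  reverses sign exactly.
- **Tissue-specific** genes receive a constant native-tissue elevation of
  3 × `effect_size`; with probability odds/(1+odds) their planted
  dominant ageing slope (± 2.5 × `effect_size`, large enough to win the
  max-|slope| comparison) is identity-losing (down in native tissue or up
  in a foreign one), otherwise identity-preserving.

Default class fractions are DiCo 0.25, DiDi 0.20, UD 0.175, DU 0.175,
flat 0.20, with `noise_sd = effect_size/3` — a regime in which planted
trends are clearly detectable but truly flat genes still produce the
expected 25% accidental sign-pattern matches. The DiCo-recovery
benchmark uses 5000 genes with the DiCo fraction set to 0.20 and no
tissue-specific overlay, isolating trajectory-class recovery from the
identity-loss overlay (which deliberately perturbs ageing slopes);
identity-loss benchmarks use a composition without DiCo/DiDi classes so
that specificity calling is not confounded by trend-driven effect sizes.
Values are floored at 0 after noise, as expression cannot be negative;
with the default baselines flooring is a tail event.

What the generator does **not** emulate: count-level (negative binomial)
sampling and library-size artefacts, batch effects, correlated gene
modules beyond the planted class structure, missing tissues (available
in tests by subsetting), or non-monotone within-period trajectories.
Passing the recovery benchmarks therefore demonstrates correctness of
the statistical machinery under the stated model, not robustness to
every artefact of real RNA-seq.

An age-proportional noise mode (`hetero_strength > 0`) scales the noise
sd linearly in log-age position and exists solely to give the
heteroscedasticity module planted positive cases.

## Numerical conventions

- PCA components have deterministic sign (largest-magnitude loading
  positive), so trend signs of PC scores and distances are reproducible
  across platforms. Inter-tissue Euclidean distances use raw scores of
  the retained components (PC1–4 by default); distances are invariant to
  orthogonal rotation within the retained block.
- Degenerate inputs are flagged, not silently coerced: constant genes
  give `NA` trends; zero pooled sd gives `NA` effect sizes; zero-margin
  contingency tables give p = 1 and undefined OR; jackknife iterations
  with zero significant genes are excluded from the reported range with
  a warning.
- Problem sizes in the shipped checks were chosen to exercise the study's
  scale while keeping a full run comfortable on one CPU: the end-to-end
  determinism check runs the complete pipeline twice on 15,063 genes with
  100 permutation rounds; calibration uses 200 replicate datasets of 500
  genes with 200 rounds each.

## Known limitations

- With one shared age shuffle per round and ~9 ageing animals, set-level
  permutation tests have coarse granularity on strongly correlated gene
  sets (see above); p-values near 1/B should be read with that in mind.
- The t-approximation p at n = 7 is approximate; exact permutation
  p-values for single genes are easy to add but were not needed, as no
  headline claim rests on a single-gene p.
- Quantile normalisation is a strong assumption (identical expression
  distributions across tissues and ages); the package treats it as the
  contract of the upstream tradition rather than a recommendation.
- Deconvolution assumes the signature's cell types span the bulk
  composition and share the bulk's measurement scale; unconstrained
  coefficients absorb, rather than flag, violations.
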