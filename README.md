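# dicoverge

Do the tissues of one individual become transcriptionally more alike or
more different as it ages? `dicoverge` implements the statistical
machinery for answering that question from multi-tissue, whole-lifespan
bulk RNA-seq: per-gene expression–age trajectories split into a
developmental and an ageing period, expression-reversal classification,
the inter-tissue coefficient-of-variation (CoV) divergence–convergence
("DiCo") statistic with dependence-preserving permutation tests,
tissue-specificity and identity-loss contingency tests,
heteroscedasticity checks, and signature-regression deconvolution of bulk
profiles into cell-type contributions. It is aimed at researchers
studying ageing transcriptomes in designs where several tissues are
sampled from the same individuals across the lifespan.

## The statistics at the core

For gene *g* and individual *i* with expression *x(g, i, t)* measured in
tissues *t = 1…T* (log2, quantile-normalised):

- **Inter-tissue CoV**: CoV(g, i) = sd over tissues / mean over tissues —
  a dimensionless dispersion of the gene across one animal's tissues.
- **Trajectories**: Spearman's correlation rho between expression (or
  CoV) and age, computed separately in development (age < 90 d in mouse)
  and ageing (≥ 90 d), with Benjamini–Hochberg correction per
  tissue × period family.
- **DiCo genes**: CoV–age rho > 0 in development and < 0 in ageing —
  tissues first diverge, then reconverge.
- **Reversals**: UD% = UD/(UU+UD) and DU% = DU/(DD+DU), the proportions of
  developmentally up-(down-)regulated genes whose trend flips in ageing.
- **Permutation scheme**: individual ages are shuffled once per round and
  applied identically to every tissue of that individual, preserving the
  within-animal dependence; reversal and DiCo tests permute ageing-period
  ages only. p is the raw proportion of rounds at least as extreme;
  eFPP = median(null)/observed.
- **Tissue specificity**: each gene is assigned to the tissue with the
  highest Cohen's d (focal vs pooled other tissues, development samples
  only); the top effect-size quartile of each assigned group is called
  tissue-specific. The **identity-loss** test asks, per tissue-specific
  gene, whether the largest-magnitude ageing slope (on log2 age) is a
  loss in the native tissue or a gain elsewhere (2×2 Fisher's exact
  odds ratio).
- **Deconvolution**: each bulk profile is regressed on cell-type
  signature profiles, `Y = a + b_1 X_1 + … + b_n X_n`; the unconstrained
  OLS coefficients serve as relative cell-type contributions, and their
  Spearman trends with age describe compositional change.

A fully tested synthetic-data generator plants DiCo/DiDi/reversal/flat
gene classes, tissue-specific elevation and identity-loss structure into
a 4-tissue, 16-individual lifespan design, so every stage is verifiable
against known truth without downloading anything.

## Worked example

```r
library(dicoverge)

sp  <- synthetic_spec(n_genes = 2000, seed = 1)
sim <- generate_dataset(sp)
sim$dataset
#> <expr_dataset> 2000 genes x 64 samples
#>   tissues: cortex, liver, lung, muscle
#>   individuals: 16; ages 2-904 days (boundary 90 d)

cov <- compute_cov(sim$dataset)
dev <- cov_age_trends(cov, "development")
age <- cov_age_trends(cov, "ageing")
print(dev$summary, digits = 3)
#>   period      statistic    rho        p
#> 1 development mean_cov   1     2.49e-40
#> 2 development median_cov 0.857 1.37e- 2
print(age$summary, digits = 3)
#>   period statistic     rho       p
#> 1 ageing mean_cov   -0.667 0.0499
#> 2 ageing median_cov -0.833 0.00527
```

The transcriptome-wide mean CoV rises monotonically through development
(rho = 1) and falls through ageing (rho = −0.67): tissues diverge, then
converge. Per-gene calls recover the planted DiCo class:

```r
calls <- call_dico(dev$gene_trends, age$gene_trends)
table(planted = sim$truth$class == "DiCo", called = calls$is_dico)
#>        called
#> planted FALSE TRUE
#>   FALSE  1387  113
#>   TRUE     37  463
```

463 of the 500 planted DiCo genes are recalled (sensitivity 0.93) at
precision 0.80. With identity-loss structure planted at odds 5, the
native-loss contingency test recovers it decisively:

```r
sp2  <- synthetic_spec(n_genes = 2000,
                       fractions = c(flat = 0.6, UD = 0.2, DU = 0.2),
                       tissue_specific_fraction = 0.3,
                       identity_loss_odds = 5, seed = 7)
sim2 <- generate_dataset(sp2)
nl <- native_loss_test(sim2$dataset, call_tissue_specific(sim2$dataset))
print(nl, digits = 3)
#>   odds_ratio sample_or        p   n11   n12   n21   n22
#> 1       25.8      26.1 2.34e-55   208    41    41   211
```

An odds ratio of 25.8 means the largest ageing change of a
tissue-specific gene is overwhelmingly either a decline in its native
tissue or a gain in a foreign one — the identity-loss signature.

`run_pipeline(pipeline_config(...), dataset)` chains every stage
(preprocess → trends → permutation tests → reversal → DiCo → PCA
structure → specificity → heteroscedasticity → deconvolution), writes
each stage table as TSV, and emits a machine-readable `summary.json`;
reruns under the same seed are byte-identical.

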