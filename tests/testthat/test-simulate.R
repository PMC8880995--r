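test_that("generation is deterministic under a fixed seed", {
  sp <- synthetic_spec(n_genes = 50, seed = 9)
  g1 <- generate_dataset(sp)
  g2 <- generate_dataset(sp)
  expect_identical(g1$dataset$values, g2$dataset$values)
  expect_identical(g1$truth, g2$truth)
  expect_identical(generate_null_dataset(sp)$values,
                   generate_null_dataset(sp)$values)
})

test_that("noise-free flat genes are constant across ages", {
  sp <- synthetic_spec(n_genes = 30, fractions = c(flat = 1),
                       tissue_specific_fraction = 0, noise_sd = 0, seed = 2)
  g <- generate_dataset(sp)
  per_gene_range <- apply(g$dataset$values, 1L, function(x) diff(range(x)))
  expect_true(all(per_gene_range == 0))
  tr <- age_trend_table(g$dataset)
  expect_true(all(is.na(tr$rho)))
})

test_that("a noise-free DiCo gene's CoV rises in development and falls in ageing", {
  sp <- synthetic_spec(n_genes = 8, fractions = c(DiCo = 1),
                       tissue_specific_fraction = 0, noise_sd = 0, seed = 3)
  g <- generate_dataset(sp)
  cov <- compute_cov(g$dataset)
  dev_cols <- cov$individuals$period == "development"
  for (gene in seq_len(8)) {
    dev_cov <- cov$cov[gene, dev_cols]
    age_cov <- cov$cov[gene, !dev_cols]
    expect_true(all(diff(dev_cov) > 0))
    expect_true(all(diff(age_cov) < 0))
  }
})

test_that("the noise-free pipeline recovers every planted class exactly", {
  sp <- synthetic_spec(n_genes = 400, tissue_specific_fraction = 0,
                       noise_sd = 0, seed = 4)
  g <- generate_dataset(sp)
  cov <- compute_cov(g$dataset)
  dev <- cov_age_trends(cov, "development")$gene_trends
  age <- cov_age_trends(cov, "ageing")$gene_trends
  calls <- call_dico(dev, age)
  expect_identical(calls$is_dico, g$truth$class == "DiCo")
  expect_identical(calls$is_didi, g$truth$class == "DiDi")

  rt <- reversal_table(age_trend_table(g$dataset))
  for (t in unique(rt$tissue)) {
    rtt <- rt[rt$tissue == t, ]
    expect_true(all(rtt$class[g$truth$class == "UD"] == "UD"))
    expect_true(all(rtt$class[g$truth$class == "DU"] == "DU"))
    expect_true(all(is.na(rtt$class[g$truth$class == "flat"])))
  }
})

test_that("planted mean-CoV trend diverges then converges when DiCo outweighs DiDi", {
  sp <- synthetic_spec(n_genes = 1500, seed = 5)  # defaults: DiCo > DiDi
  g <- generate_dataset(sp)
  cov <- compute_cov(g$dataset)
  dev <- cov_age_trends(cov, "development")$summary
  age <- cov_age_trends(cov, "ageing")$summary
  expect_gt(dev$rho[dev$statistic == "mean_cov"], 0)
  expect_lt(age$rho[age$statistic == "mean_cov"], 0)
})

test_that("null datasets carry no age signal", {
  sp <- synthetic_spec(n_genes = 1000, seed = 6)
  ds <- generate_null_dataset(sp)
  m <- meta_subset(ds, period = "ageing", tissue = "cortex")
  st <- spearman_matrix(ds$values[, m$sample_id], m$age_days)
  # p-values are approximately uniform: the t-approximation on a rank
  # statistic at n = 9 leaves a small systematic wobble, so we check
  # calibration in bands rather than by a distribution-identity test
  expect_lt(abs(mean(st$p) - 0.5), 0.05)
  expect_gt(mean(st$p < 0.1), 0.05)
  expect_lt(mean(st$p < 0.1), 0.16)
  expect_lte(sum(bh_adjust(st$p) < 0.1), 0.02 * length(st$p))
})

test_that("mixtures reproduce the signature under identity proportions", {
  sig <- simulate_signature(n_genes = 60, cell_types = c("a", "b", "c"),
                            seed = 7)
  ds <- generate_mixtures(sig, diag(3), noise_sd = 0)
  expect_equal(unname(ds$values), unname(sig$values), tolerance = 1e-12)
  expect_error(generate_mixtures(sig, matrix(c(0.5, 0.4, 0.0), 1)),
               "sum to 1")
  d1 <- generate_mixtures(sig, diag(3), noise_sd = 1, seed = 8)
  d2 <- generate_mixtures(sig, diag(3), noise_sd = 1, seed = 8)
  expect_identical(d1$values, d2$values)
})

test_that("invalid fractions are rejected", {
  expect_error(synthetic_spec(fractions = c(DiCo = 0.7, DiDi = 0.7)),
               "sum to at most 1")
  expect_error(synthetic_spec(noise_sd = -1), "noise_sd")
})
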