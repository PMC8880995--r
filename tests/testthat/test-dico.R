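test_that("inter-tissue CoV follows the sd/mean definition", {
  meta <- tibble::tibble(
    sample_id = paste0("i1_", c("A", "B", "C", "D")),
    individual_id = "i1", tissue = c("A", "B", "C", "D"), age_days = 100)
  v <- matrix(c(2, 2, 2, 2,
                1, 2, 3, 4,
                0, 0, 0, 0), 3, 4, byrow = TRUE,
              dimnames = list(c("flat", "ramp", "zero"), meta$sample_id))
  cov <- compute_cov(expr_dataset(v, meta))
  expect_equal(unname(cov$cov["flat", 1]), 0)
  expect_equal(unname(cov$cov["ramp", 1]), sqrt(5 / 3) / 2.5,
               tolerance = 1e-12)
  expect_true(is.na(cov$cov["zero", 1]))
  # the undefined gene is excluded from the individual's mean CoV
  expect_equal(unname(cov$individuals$mean_cov),
               mean(c(0, sqrt(5 / 3) / 2.5)))
})

test_that("CoV matches the brute-force oracle on random matrices", {
  set.seed(30)
  sp <- synthetic_spec(n_genes = 40, seed = 30)
  ds <- generate_null_dataset(sp)
  cov <- compute_cov(ds)
  m <- ds$meta
  for (i in sample(ncol(cov$cov), 5)) {
    ind <- cov$individuals$individual_id[i]
    cols <- m$sample_id[m$individual_id == ind]
    for (g in sample(40, 10)) {
      expect_equal(unname(cov$cov[g, i]),
                   oracle_cov(ds$values[g, cols]), tolerance = 1e-12)
    }
  }
})

test_that("individuals missing a tissue are dropped from the CoV table", {
  sp <- synthetic_spec(n_genes = 20, seed = 31)
  g <- generate_dataset(sp)
  ds <- g$dataset
  keep <- ds$meta$sample_id[!(ds$meta$individual_id == "ind16" &
                                ds$meta$tissue == "cortex")]
  ds2 <- subset_dataset(ds, samples = keep)
  expect_message(cov <- compute_cov(ds2), "ind16")
  expect_false("ind16" %in% cov$individuals$individual_id)
  expect_equal(ncol(cov$cov), 15)
})

test_that("dico calling follows the trend-sign definition", {
  dev <- tibble::tibble(gene = c("a", "b", "c"), period = "development",
                        rho = c(0.4, 0.4, 0.5), p = 0.2, q = 0.5)
  age <- tibble::tibble(gene = c("a", "b", "c"), period = "ageing",
                        rho = c(-0.2, 0.3, NA), p = 0.2, q = 0.5)
  calls <- call_dico(dev, age)
  expect_equal(calls$is_dico, c(TRUE, FALSE, FALSE))
  expect_equal(calls$is_didi, c(FALSE, TRUE, FALSE))
  expect_equal(calls$ageing_class, c("convergent", "divergent",
                                     "undefined"))
  # significant-only variant
  dev$q <- c(0.01, 0.01, 0.5)
  age$q <- c(0.01, 0.01, 0.5)
  sig <- call_dico(dev, age, q_cutoff = 0.1)
  expect_equal(sig$is_dico, c(TRUE, FALSE, FALSE))
  expect_equal(sig$dev_class[3], "undefined")
})

test_that("ageing permutation test of DiCo% is reproducible and calibrated", {
  # noise on the order of the effect keeps permuted per-gene trends only
  # weakly coupled, so the null concentrates near 0.5 instead of echoing
  # the planted trajectories under near-monotone shuffles
  sp <- synthetic_spec(n_genes = 400,
                       fractions = c(DiCo = 0.5, flat = 0.5),
                       tissue_specific_fraction = 0, noise_sd = 1.3,
                       seed = 32)
  g <- generate_dataset(sp)
  res <- test_dico(g$dataset, n_rounds = 99, seed = 12)
  expect_lte(res$p_value, 0.05)
  res2 <- test_dico(g$dataset, n_rounds = 99, seed = 12)
  expect_identical(res$null_values, res2$null_values)

  null_ds <- generate_null_dataset(synthetic_spec(n_genes = 400, seed = 33))
  res0 <- test_dico(null_ds, n_rounds = 99, seed = 13)
  expect_gt(res0$p_value, 0.05)
  expect_lt(abs(median(res0$null_values) - 0.5), 0.15)
})

test_that("jackknife ratios reflect planted divergence and are deterministic", {
  sp <- synthetic_spec(n_genes = 600,
                       fractions = c(DiCo = 0.4, DiDi = 0.3, flat = 0.3),
                       tissue_specific_fraction = 0, seed = 34)
  g <- generate_dataset(sp)
  jk <- jackknife_ratio(g$dataset, "development")
  expect_equal(nrow(jk$pseudovalues), 7)
  valid <- jk$pseudovalues[jk$pseudovalues$valid, ]
  expect_true(all(valid$ratio > 1))   # divergence dominates development
  jk2 <- jackknife_ratio(g$dataset, "development")
  expect_identical(jk$pseudovalues, jk2$pseudovalues)
  # ageing leave-outs in the same data favour convergence
  jk_age <- jackknife_ratio(g$dataset, "ageing")
  valid_age <- jk_age$pseudovalues[jk_age$pseudovalues$valid, ]
  expect_true(all(valid_age$ratio < 1))
})

test_that("pairwise tissue correlations capture convergence structure", {
  # an individual with two identical tissue profiles correlates at 1
  meta <- tibble::tibble(
    sample_id = c("i1_A", "i1_B", "i2_A", "i2_B"),
    individual_id = c("i1", "i1", "i2", "i2"),
    tissue = c("A", "B", "A", "B"), age_days = c(100, 100, 200, 200))
  v <- matrix(c(1, 1, 5, 2,
                2, 2, 4, 9,
                3, 3, 1, 4), 3, 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), meta$sample_id))
  pw <- pairwise_tissue_correlation(expr_dataset(v, meta))
  expect_equal(pw$pairs$rho[pw$pairs$individual_id == "i1"], 1)

  sp <- synthetic_spec(n_genes = 800, tissue_specific_fraction = 0,
                       seed = 35)
  g <- generate_dataset(sp)
  pw2 <- pairwise_tissue_correlation(g$dataset)
  tr <- pw2$trends[pw2$trends$tissue1 == "mean", ]
  expect_lt(tr$rho[tr$period == "development"], 0)  # diverging
  expect_gt(tr$rho[tr$period == "ageing"], 0)       # converging
})
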