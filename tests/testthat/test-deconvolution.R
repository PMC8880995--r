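test_that("deconvolution recovers exact mixture weights", {
  sig <- simulate_signature(n_genes = 200, cell_types = paste0("ct", 1:4),
                            seed = 70)
  # a bulk sample equal to one signature column
  pure <- generate_mixtures(sig, diag(4), noise_sd = 0)
  fit <- fit_deconvolution(pure, sig)
  expect_equal(unname(fit$coefficients), diag(4), tolerance = 1e-8)
  expect_equal(unname(fit$intercepts), rep(0, 4), tolerance = 1e-8)

  props <- matrix(c(0.3, 0.7, 0, 0,
                    0.1, 0.2, 0.3, 0.4), 2, byrow = TRUE)
  mix <- generate_mixtures(sig, props, noise_sd = 0)
  fit2 <- fit_deconvolution(mix, sig)
  expect_equal(unname(fit2$coefficients), props, tolerance = 1e-8)
})

test_that("deconvolution equals the normal-equations oracle", {
  set.seed(71)
  sig <- simulate_signature(n_genes = 150, cell_types = paste0("ct", 1:5),
                            seed = 71)
  for (i in 1:100) {
    y <- rnorm(150, mean = 5)
    names(y) <- rownames(sig$values)
    meta <- tibble::tibble(sample_id = "s_bulk", individual_id = "s",
                           tissue = "bulk", age_days = 100)
    ds <- expr_dataset(matrix(pmax(y, 0), ncol = 1,
                              dimnames = list(names(y), "s_bulk")), meta)
    fit <- fit_deconvolution(ds, sig)
    X <- cbind(1, sig$values)
    beta <- oracle_lstsq(X, ds$values[, 1])
    expect_equal(unname(fit$coefficients[1, ]), unname(beta[-1]),
                 tolerance = 1e-8)
  }
})

test_that("noisy mixtures are recovered within tolerance", {
  sig <- simulate_signature(n_genes = 500, cell_types = paste0("ct", 1:6),
                            seed = 72)
  set.seed(72)
  props <- matrix(rexp(100 * 6), 100)
  props <- props / rowSums(props)
  signal_scale <- mean(sig$values %*% t(props))
  mix <- generate_mixtures(sig, props, noise_sd = 0.05 * signal_scale,
                           seed = 73)
  fit <- fit_deconvolution(mix, sig)
  expect_lt(mean(abs(fit$coefficients - props)), 0.05)
})

test_that("rank-deficient signatures are rejected with the culprit named", {
  sig <- simulate_signature(n_genes = 100, cell_types = c("a", "b"),
                            seed = 74)
  v <- cbind(sig$values, c = sig$values[, "b"])
  bulk <- generate_mixtures(sig, matrix(c(0.5, 0.5), 1), noise_sd = 0)
  expect_error(fit_deconvolution(bulk, v), "collinear")
})

test_that("coefficient age trends recover planted composition change", {
  sig <- simulate_signature(n_genes = 400, cell_types = paste0("ct", 1:3),
                            seed = 75)
  ages <- c(100, 200, 300, 450, 600, 750, 900)
  w <- seq(0.1, 0.7, length.out = 7)      # ct1 rises with age
  props <- cbind(w, 0.2, 1 - w - 0.2)
  mix <- generate_mixtures(sig, props, noise_sd = 0.5, ages = ages,
                           seed = 76)
  fit <- fit_deconvolution(mix, sig)
  tr <- coefficient_age_trend(fit, periods = "ageing")
  expect_gt(tr$rho[tr$cell_type == "ct1"], 0.8)
  expect_lt(tr$rho[tr$cell_type == "ct3"], -0.8)
  expect_gt(tr$p[tr$cell_type == "ct2"], 0.05)  # constant proportion
})

test_that("resampling test is reproducible and centres random sets", {
  sig <- simulate_signature(n_genes = 300, cell_types = paste0("ct", 1:3),
                            seed = 77)
  set.seed(77)
  props <- matrix(rexp(8 * 3), 8)
  props <- props / rowSums(props)
  mix <- generate_mixtures(sig, props, noise_sd = 0.5,
                           ages = c(95, 150, 230, 340, 480, 620, 780, 900),
                           seed = 78)
  dico_genes <- sample(rownames(sig$values), 80)
  res <- resampling_test(mix, sig, dico_genes, n_rounds = 59, seed = 79)
  expect_equal(nrow(res), 3)
  # a random "DiCo" set is exchangeable with the null draws
  expect_true(all(res$p_value > 0.01))
  res2 <- resampling_test(mix, sig, dico_genes, n_rounds = 59, seed = 79)
  expect_identical(res$p_value, res2$p_value)
})

test_that("cell-type pair trends find convergence of dissimilar partners", {
  sigs0 <- simulate_signatures_by_age(convergence = 0, seed = 80)
  tr0 <- celltype_pair_trends(sigs0)
  # combinatorics: per tissue, n_ct x (n_tissues - 1) partners, min and max
  expect_equal(nrow(tr0), 4 * 3 * 3 * 2)
  expect_true(all(tr0$trend_rho == 0))
  sigs <- simulate_signatures_by_age(convergence = 0.6, seed = 80)
  tr <- celltype_pair_trends(sigs)
  expect_true(all(tr$trend_rho[tr$kind == "min"] > 0))
})

test_that("within-tissue cell-type CoV mirrors the inter-tissue oracle", {
  set.seed(81)
  prof <- matrix(runif(50 * 6, 1, 10), 50, 6,
                 dimnames = list(paste0("g", 1:50), paste0("c", 1:6)))
  meta <- tibble::tibble(
    column_id = colnames(prof), tissue = "liver",
    cell_type = rep(c("hep", "endo", "kupffer"), 2),
    individual_id = rep(c("m1", "m2"), each = 3),
    age_days = rep(c(90, 720), each = 3))
  res <- within_tissue_cov(prof, meta)
  expect_equal(nrow(res$per_individual), 2)
  # oracle: mean over genes of sd/mean across the individual's cell types
  cols <- meta$column_id[meta$individual_id == "m1"]
  manual <- mean(apply(prof[, cols], 1L, function(x) sd(x) / mean(x)))
  expect_equal(res$per_individual$mean_cov[
    res$per_individual$individual_id == "m1"], manual, tolerance = 1e-12)
  # identical profiles give CoV zero
  prof_same <- prof
  prof_same[, 4:6] <- prof[, rep(4, 3)]
  res_same <- within_tissue_cov(prof_same, meta)
  expect_equal(res_same$per_individual$mean_cov[
    res_same$per_individual$individual_id == "m2"], 0, tolerance = 1e-12)
  # planted convergence: dissimilar young profiles, similar old ones
  old_centre <- rowMeans(prof[, 1:3])
  prof_conv <- prof
  prof_conv[, 4:6] <- 0.9 * old_centre + 0.1 * prof[, 4:6]
  meta3 <- dplyr::bind_rows(meta,
    tibble::tibble(column_id = paste0("c", 7:9), tissue = "liver",
                   cell_type = c("hep", "endo", "kupffer"),
                   individual_id = "m3", age_days = 400))
  prof9 <- cbind(prof_conv, prof_conv[, 1:3] * 0 +
                   (0.5 * old_centre + 0.5 * prof[, 1:3]))
  colnames(prof9) <- paste0("c", 1:9)
  res_conv <- within_tissue_cov(prof9, meta3)
  expect_lt(res_conv$trends$rho, 0)
})
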