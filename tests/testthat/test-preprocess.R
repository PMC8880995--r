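make_zero_ds <- function(n_zero, n_samples = 63) {
  meta <- tibble::tibble(
    sample_id = paste0("s", seq_len(n_samples)),
    individual_id = paste0("i", seq_len(n_samples)),
    tissue = "A", age_days = seq_len(n_samples) + 1)
  v <- matrix(5, 2, n_samples,
              dimnames = list(c("zeroed", "clean"), meta$sample_id))
  if (n_zero > 0) v["zeroed", seq_len(n_zero)] <- 0
  expr_dataset(v, meta)
}

test_that("detection filter removes genes with zeros in >= 25% of samples", {
  expect_false("zeroed" %in% rownames(
    filter_low_expression(make_zero_ds(16))$values))      # 16/63 = 25.4%
  expect_true("zeroed" %in% rownames(
    filter_low_expression(make_zero_ds(15))$values))      # 15/63 = 23.8%
  kept <- filter_low_expression(make_zero_ds(0))
  expect_equal(nrow(kept$values), 2)
})

test_that("quantile normalisation equalises column distributions", {
  ds <- toy_dataset(matrix(c(1, 3, 5, 2, 4, 6), 3, 8)[, c(1, 2, 1, 2,
                                                          1, 2, 1, 2)])
  # columns alternate (1,3,5) and (2,4,6); already on log scale
  norm <- log2_quantile_normalise(ds, log_transform = FALSE)
  expect_equal(unname(norm$values[, 1]), c(1.5, 3.5, 5.5))
  expect_equal(unname(norm$values[, 2]), c(1.5, 3.5, 5.5))

  # identical columns are a fixed point of the quantile step
  same <- toy_dataset(matrix(rep(c(2, 7, 11), 8), 3, 8))
  out <- log2_quantile_normalise(same)
  expect_equal(out$values, log2(same$values + 1))
})

test_that("every column holds the same value multiset after normalisation", {
  set.seed(1)
  ds <- toy_dataset(matrix(rexp(160, 0.2), 20, 8))
  norm <- log2_quantile_normalise(ds)
  sorted <- apply(norm$values, 2L, sort)
  for (j in 2:ncol(sorted)) expect_equal(sorted[, j], sorted[, 1])
  # idempotent on its own output
  again <- log2_quantile_normalise(norm, log_transform = FALSE)
  expect_equal(again$values, norm$values, tolerance = 1e-12)
})

test_that("quantile normalisation matches oracles with and without ties", {
  set.seed(2)
  for (i in 1:25) {
    m <- matrix(sample(0:6, 40, replace = TRUE) + 0, 8, 5)  # heavy ties
    expect_equal(quantile_normalise_matrix(m), oracle_qnorm(m),
                 tolerance = 1e-12)
    m2 <- matrix(rnorm(40), 8, 5)                            # tie-free
    expect_equal(quantile_normalise_matrix(m2), oracle_qnorm(m2),
                 tolerance = 1e-12)
    expect_equal(quantile_normalise_matrix(m2),
                 limma::normalizeQuantiles(m2), tolerance = 1e-12)
  }
})

test_that("preprocessing keeps planted structure detectable", {
  sp <- synthetic_spec(n_genes = 600, tissue_specific_fraction = 0,
                       seed = 12)
  g <- generate_dataset(sp)
  calls_of <- function(ds) {
    cov <- compute_cov(ds)
    call_dico(cov_age_trends(cov, "development")$gene_trends,
              cov_age_trends(cov, "ageing")$gene_trends)
  }
  before <- calls_of(g$dataset)
  # the detection filter alone never changes a retained gene's call
  filt <- filter_low_expression(g$dataset)
  after_filter <- calls_of(filt)
  shared <- intersect(before$gene, after_filter$gene)
  expect_identical(after_filter$is_dico[match(shared, after_filter$gene)],
                   before$is_dico[match(shared, before$gene)])
  # quantile normalisation redistributes rank mass across genes, which
  # costs precision on flat genes but keeps the planted signal detectable:
  # sensitivity and the transcriptome-wide CoV signs survive
  norm <- log2_quantile_normalise(filt, log_transform = FALSE)
  after <- calls_of(norm)
  truth_dico <- g$truth$class[match(after$gene, g$truth$gene)] == "DiCo"
  expect_gt(mean(after$is_dico[truth_dico]), 0.95)
  cov_n <- compute_cov(norm)
  expect_gt(cov_age_trends(cov_n, "development")$summary$rho[1], 0)
  expect_lt(cov_age_trends(cov_n, "ageing")$summary$rho[1], 0)
})
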