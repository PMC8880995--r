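test_that("Cohen's d follows the pooled-sd formula", {
  expect_equal(cohens_d(c(4, 6), c(1, 3)), 3 / sqrt(2), tolerance = 1e-12)
  expect_equal(cohens_d(c(1, 3), c(4, 6)), -3 / sqrt(2), tolerance = 1e-12)
  expect_equal(cohens_d(c(2, 4), c(2, 4)), 0)
  expect_true(is.na(cohens_d(c(2, 2), c(2, 2))))
  set.seed(50)
  for (i in 1:100) {
    a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1))
    expect_equal(cohens_d(a, b), oracle_cohens_d(a, b), tolerance = 1e-12)
  }
})

test_that("tissue-specific calling assigns elevated genes and flags quartiles", {
  sp <- synthetic_spec(n_genes = 400, tissue_specific_fraction = 0.25,
                       identity_loss_odds = 1, seed = 51)
  g <- generate_dataset(sp)
  tab <- call_tissue_specific(g$dataset)
  planted <- g$truth[!is.na(g$truth$native_tissue), ]
  hit <- tab[match(planted$gene, tab$gene), ]
  expect_gt(mean(hit$assigned_tissue == planted$native_tissue), 0.85)
  # flat-class planted genes have small within-tissue variance, so their
  # effect sizes dominate; trend-class genes dilute their own d through
  # developmental variance and are recovered less often
  flat_planted <- planted$gene[planted$class == "flat"]
  expect_gt(mean(hit$is_specific[planted$class == "flat"]), 0.9)
  expect_gt(mean(hit$is_specific), 0.3)
  # quartile contract: 25% (+/- one gene) of each assigned group flagged
  by_tissue <- split(tab$is_specific, tab$assigned_tissue)
  for (t in names(by_tissue)) {
    m <- length(by_tissue[[t]])
    expect_lte(abs(sum(by_tissue[[t]]) - 0.25 * m), 1)
  }
})

test_that("all-equal expression yields no specific gene", {
  meta <- tibble::tibble(
    sample_id = paste0("i", rep(1:3, 2), "_", rep(c("A", "B"), each = 3)),
    individual_id = rep(paste0("i", 1:3), 2),
    tissue = rep(c("A", "B"), each = 3), age_days = rep(c(5, 20, 60), 2))
  v <- matrix(7, 4, 6, dimnames = list(paste0("g", 1:4), meta$sample_id))
  tab <- call_tissue_specific(expr_dataset(v, meta))
  expect_false(any(tab$is_specific))
})

test_that("Fisher's exact test matches the hypergeometric oracle", {
  expect_equal(fisher_exact(matrix(c(10, 10, 10, 10), 2))$odds_ratio, 1,
               tolerance = 1e-6)
  expect_equal(fisher_exact(matrix(c(10, 10, 10, 10), 2))$p, 1)
  res <- fisher_exact(matrix(c(12, 3, 2, 9), 2))
  expect_equal(res$sample_or, 18)
  expect_equal(res$p, oracle_fisher_p(matrix(c(12, 3, 2, 9), 2)),
               tolerance = 1e-10)
  sep <- fisher_exact(matrix(c(5, 0, 0, 5), 2))
  expect_equal(sep$odds_ratio, Inf)
  expect_lt(sep$p, 0.01)
  zm <- fisher_exact(matrix(c(0, 0, 3, 4), 2))
  expect_equal(zm$p, 1)
  expect_true(is.na(zm$odds_ratio))
  set.seed(52)
  for (i in 1:100) {
    tab <- matrix(sample(0:25, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p, oracle_fisher_p(tab),
                 tolerance = 1e-10)
  }
})

test_that("planted identity loss drives the native-loss odds ratio up", {
  sp <- synthetic_spec(n_genes = 600,
                       fractions = c(flat = 0.6, UD = 0.2, DU = 0.2),
                       tissue_specific_fraction = 0.3,
                       identity_loss_odds = 5, seed = 53)
  g <- generate_dataset(sp)
  tab <- call_tissue_specific(g$dataset)
  res <- native_loss_test(g$dataset, tab)
  expect_gt(res$odds_ratio, 1)
  expect_lt(res$p, 0.05)
  detail <- attr(res, "detail")
  expect_equal(nrow(detail), sum(tab$is_specific))
  # restricting to a subset keeps the contract
  sub <- native_loss_test(g$dataset, tab,
                          gene_subset = tab$gene[seq(1, 600, 2)])
  expect_lte(nrow(attr(sub, "detail")), nrow(detail))
})

test_that("enrichment tests detect planted coupling and skip degenerate strata", {
  sp <- synthetic_spec(n_genes = 1200, tissue_specific_fraction = 0.2,
                       dico_specific_odds = 8, seed = 54)
  g <- generate_dataset(sp)
  cov <- compute_cov(g$dataset)
  calls <- call_dico(cov_age_trends(cov, "development")$gene_trends,
                     cov_age_trends(cov, "ageing")$gene_trends)
  spec_tab <- call_tissue_specific(g$dataset)
  rt <- reversal_table(age_trend_table(g$dataset))
  enr <- enrichment_tests(spec_tab, calls, rt)
  dico_row <- enr[enr$test == "specific_in_dico", ]
  expect_gt(dico_row$odds_ratio, 1)
  expect_lt(dico_row$p, 0.05)
  # degenerate input: everything specific -> skipped with warning
  all_spec <- spec_tab
  all_spec$is_specific <- TRUE
  expect_warning(out <- enrichment_tests(all_spec, calls, NULL),
                 "degenerate")
  expect_equal(nrow(out), 0)
})

test_that("independently planted specificity and DiCo labels give an OR near one", {
  # independence holds for the planted truth labels; the *called* labels
  # are legitimately coupled (tissue-elevated DiCo genes look specific)
  sp <- synthetic_spec(n_genes = 4000, tissue_specific_fraction = 0.15,
                       dico_specific_odds = 1, seed = 55)
  g <- generate_dataset(sp)
  tab <- table(factor(!is.na(g$truth$native_tissue), c(TRUE, FALSE)),
               factor(g$truth$class == "DiCo", c(TRUE, FALSE)))
  res <- fisher_exact(tab)
  expect_gt(res$odds_ratio, 0.6)
  expect_lt(res$odds_ratio, 1.6)
})
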