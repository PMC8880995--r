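# Independent brute-force oracles used to check the package's statistical
# primitives. Each is deliberately written from the textbook definition,
# not by reusing the implementation under test.

oracle_spearman <- function(x, y) {
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

oracle_cov <- function(x) stats::sd(x) / mean(x)

oracle_cohens_d <- function(a, b) {
  sp <- sqrt(((length(a) - 1) * stats::var(a) +
                (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
  (mean(a) - mean(b)) / sp
}

# quantile normalisation: reference = cross-column mean at each rank; a tied
# group receives the mean of the reference values over its positions
oracle_qnorm <- function(mat) {
  ref <- rowMeans(apply(mat, 2L, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    for (i in seq_len(nrow(mat))) {
      pos <- which(sort(mat[, j]) == mat[i, j])
      out[i, j] <- mean(ref[pos])
    }
  }
  out
}

oracle_lstsq <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# two-sided Fisher p by exhaustive hypergeometric enumeration, using the
# same relative tolerance as the classical implementation
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

oracle_ks_D <- function(x, y) {
  grid <- sort(c(x, y))
  Fx <- vapply(grid, function(g) mean(x <= g), numeric(1))
  Fy <- vapply(grid, function(g) mean(y <= g), numeric(1))
  max(abs(Fx - Fy))
}

# small handmade dataset: 2 tissues x 4 individuals (2 dev, 2 ageing)
toy_dataset <- function(values = NULL, n_genes = 3) {
  meta <- tibble::tibble(
    sample_id = c("i1_A", "i2_A", "i3_A", "i4_A",
                  "i1_B", "i2_B", "i3_B", "i4_B"),
    individual_id = rep(c("i1", "i2", "i3", "i4"), 2),
    tissue = rep(c("A", "B"), each = 4),
    age_days = rep(c(10, 40, 100, 400), 2))
  if (is.null(values)) {
    values <- matrix(seq_len(n_genes * 8), n_genes, 8)
  }
  rownames(values) <- paste0("g", seq_len(nrow(values)))
  colnames(values) <- meta$sample_id
  expr_dataset(values, meta)
}
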