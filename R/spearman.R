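#' Spearman correlation between one variable and many gene rows
#'
#' Vectorised Spearman correlation of each row of a matrix against a single
#' covariate (typically age), with the two-sided p-value from the
#' t-approximation on n - 2 degrees of freedom. Ties receive mid-ranks.
#' Rows with zero rank variance (constant expression) get `NA` for both rho
#' and p and are flagged for exclusion downstream.
#'
#' @param mat numeric matrix (genes x samples).
#' @param x numeric covariate, length `ncol(mat)`.
#' @return a list with numeric vectors `rho` and `p` (length `nrow(mat)`).
#' @export
spearman_matrix <- function(mat, x) {
  n <- length(x)
  if (ncol(mat) != n) abort("covariate length must match matrix columns")
  if (n < 3) abort("at least 3 samples are required")
  rx <- rank(x)
  rxc <- rx - mean(rx)
  denx <- sqrt(sum(rxc^2))
  rm <- t(apply(mat, 1L, rank))
  if (nrow(mat) == 1L) rm <- matrix(rm, nrow = 1L)
  rmc <- rm - rowMeans(rm)
  denm <- sqrt(rowSums(rmc^2))
  rho <- as.vector(rmc %*% rxc) / (denm * denx)
  rho[denm == 0 | denx == 0] <- NA_real_
  rho <- pmin(1, pmax(-1, rho))
  tval <- rho * sqrt((n - 2) / pmax(1 - rho^2, 0))
  p <- 2 * pt(-abs(tval), df = n - 2)
  p[is.finite(rho) & abs(rho) == 1] <- 0
  p[!is.finite(rho)] <- NA_real_
  list(rho = rho, p = p)
}

#' Spearman correlation between expression and age
#'
#' Scalar convenience wrapper around [spearman_matrix()]: Pearson
#' correlation of mid-ranks, two-sided p from the t-approximation —
#' the non-parametric trend statistic used for every expression-age and
#' CoV-age association in the package. Constant input yields `NA` (the
#' gene is flagged rather than assigned a sign).
#'
#' @param values numeric vector of per-sample expression.
#' @param ages numeric vector of per-sample ages (days).
#' @return a tibble with columns `rho` and `p`.
#' @export
spearman_age_trend <- function(values, ages) {
  if (length(values) != length(ages)) abort("values and ages differ in length")
  res <- spearman_matrix(matrix(values, nrow = 1L), ages)
  tibble::tibble(rho = res$rho, p = res$p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (wraps `stats::p.adjust`), with input validation.
#' `NA` entries are passed through.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return numeric vector of adjusted values, capped at 1.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

# trend wrapper safe for grouped summaries: NA instead of an error when a
# group is too small (dplyr probes summarise expressions on empty groups)
trend_or_na <- function(values, ages) {
  if (length(values) < 3) return(tibble::tibble(rho = NA_real_,
                                                p = NA_real_))
  spearman_age_trend(values, ages)
}

# OLS slope of each matrix row on a covariate (used for log2-age regression)
slope_matrix <- function(mat, x) {
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  as.vector((mat %*% xc) / sxx)
}

# standardised mid-ranks: z such that cor(a, b) = sum(z_a * z_b)
std_ranks <- function(v) {
  r <- rank(v)
  rc <- r - mean(r)
  den <- sqrt(sum(rc^2))
  if (den == 0) return(rep(NA_real_, length(v)))
  rc / den
}

# matrix of standardised row ranks (genes x samples); constant rows -> NA
std_rank_matrix <- function(mat) {
  rm <- t(apply(mat, 1L, rank))
  if (nrow(mat) == 1L) rm <- matrix(rm, nrow = 1L)
  rmc <- rm - rowMeans(rm)
  den <- sqrt(rowSums(rmc^2))
  den[den == 0] <- NA_real_
  rmc / den
}
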