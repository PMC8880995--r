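#' Age trend of absolute regression residuals
#'
#' Fits expression on log2(age) by OLS and returns the Spearman
#' correlation between the absolute residuals and age — an estimate of how
#' measurement heterogeneity changes along the lifespan. Constant
#' expression (or an exact fit) leaves the trend undefined.
#'
#' @param values numeric vector of per-sample expression.
#' @param ages numeric vector of ages (days).
#' @return Spearman rho (or `NA`).
#' @export
abs_residual_trend <- function(values, ages) {
  if (length(values) < 4) abort("need at least 4 samples")
  x <- log2(ages)
  fit <- lm.fit(cbind(1, x), values)
  r <- abs(fit$residuals)
  if (all(r < 1e-12) || sd(r) == 0) return(NA_real_)
  spearman_age_trend(r, ages)$rho
}

#' Score test for non-constant error variance
#'
#' Cook-Weisberg score test against variance increasing with the fitted
#' values of the OLS regression of expression on log2(age): squared
#' residuals scaled by the maximum-likelihood error variance are regressed
#' on the fitted values; the statistic is half the regression sum of
#' squares, referred to a chi-squared distribution with 1 df. Invariant to
#' scaling of the response.
#'
#' @inheritParams abs_residual_trend
#' @return a tibble with columns `stat` and `p` (`NA` for degenerate
#'   fits).
#' @export
ncv_score_test <- function(values, ages) {
  if (length(values) < 4) abort("need at least 4 samples")
  x <- log2(ages)
  fit <- lm.fit(cbind(1, x), values)
  e <- fit$residuals
  sigma2 <- mean(e^2)
  if (sigma2 < 1e-300) return(tibble::tibble(stat = NA_real_, p = NA_real_))
  u <- e^2 / sigma2
  yhat <- values - e
  yc <- yhat - mean(yhat)
  syy <- sum(yc^2)
  if (syy == 0) return(tibble::tibble(stat = NA_real_, p = NA_real_))
  ssreg <- sum(u * yc)^2 / syy
  stat <- ssreg / 2
  tibble::tibble(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Per-gene heteroscedasticity measures by tissue
#'
#' Applies [abs_residual_trend()] and [ncv_score_test()] to every gene in
#' every tissue across the whole age range (both measures vectorised over
#' genes).
#'
#' @param ds a normalised [expr_dataset()].
#' @param genes optional gene subset.
#' @return a `HeteroResult` tibble: `gene`, `tissue`, `abs_resid_rho`,
#'   `ncv_stat`, `ncv_p`.
#' @export
hetero_table <- function(ds, genes = NULL) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (is.null(genes)) genes <- rownames(ds$values)
  purrr::map_dfr(tissues_of(ds), function(t) {
    m <- meta_subset(ds, tissue = t)
    y <- ds$values[genes, m$sample_id, drop = FALSE]
    x <- log2(m$age_days)
    xc <- x - mean(x)
    # vectorised OLS: residual of each gene row on [1, x]
    beta <- (y %*% xc) / sum(xc^2)
    yhat <- matrix(rowMeans(y), nrow(y), ncol(y)) + beta %*% t(xc)
    e <- y - yhat
    # abs-residual Spearman trend vs age
    abs_rho <- spearman_matrix(abs(e), m$age_days)$rho
    abs_rho[rowSums(abs(e) > 1e-12) == 0] <- NA_real_
    # vectorised ncv score statistic
    sigma2 <- rowMeans(e^2)
    yc <- yhat - rowMeans(yhat)
    syy <- rowSums(yc^2)
    num <- rowSums((e^2 / sigma2) * yc)^2
    stat <- (num / syy) / 2
    stat[sigma2 < 1e-300 | syy == 0] <- NA_real_
    stat <- unname(stat)
    tibble::tibble(gene = genes, tissue = t,
                   abs_resid_rho = unname(abs_rho), ncv_stat = stat,
                   ncv_p = pchisq(stat, 1, lower.tail = FALSE))
  })
}

#' Compare heteroscedasticity of DiCo and DiDi genes
#'
#' Two-sided Kolmogorov-Smirnov test, per tissue and per measure, between
#' the heteroscedasticity-value distributions of DiCo and DiDi gene sets.
#' A null result means the ageing-phase convergence is not explained by
#' rising residual noise.
#'
#' @param hetero a [hetero_table()] result.
#' @param dico_call a [call_dico()] table.
#' @param measure `"abs_resid_rho"` or `"ncv_stat"`.
#' @return a tibble: `tissue`, `measure`, `D`, `p`, `n_dico`, `n_didi`
#'   (tissues with an empty set are skipped).
#' @export
compare_dico_didi <- function(hetero, dico_call,
                              measure = c("abs_resid_rho", "ncv_stat")) {
  measure <- match.arg(measure)
  dico_genes <- dico_call$gene[dico_call$is_dico]
  didi_genes <- dico_call$gene[dico_call$is_didi]
  purrr::map_dfr(unique(hetero$tissue), function(t) {
    ht <- hetero[hetero$tissue == t, ]
    x <- ht[[measure]][ht$gene %in% dico_genes]
    y <- ht[[measure]][ht$gene %in% didi_genes]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0 || length(y) == 0) return(NULL)
    ks <- suppressWarnings(ks.test(x, y))
    tibble::tibble(tissue = t, measure = measure,
                   D = unname(ks$statistic), p = ks$p.value,
                   n_dico = length(x), n_didi = length(y))
  })
}
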