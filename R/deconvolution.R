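#' Signature-regression deconvolution of bulk profiles
#'
#' Regresses each bulk sample's expression vector on the cell-type
#' signature profiles (shared genes only) by ordinary least squares with
#' an intercept; the regression coefficients are read as relative
#' cell-type contributions. Coefficients are unconstrained (they may be
#' negative); an NNLS-style non-negative variant is available behind a
#' flag for users who want proportions-like output.
#'
#' @param ds an [expr_dataset()] of bulk samples.
#' @param signature a [signature_matrix()] (or plain genes x cell-types
#'   matrix).
#' @param gene_set optional character vector restricting the genes used
#'   (e.g. DiCo genes or their complement).
#' @param nonnegative constrain coefficients to be non-negative (not part
#'   of the plain linear model; off by default).
#' @return an object of class `deconv_result`: list with `coefficients`
#'   (sample x cell-type matrix), `intercepts`, `meta`, `n_genes` and
#'   `cell_types`.
#' @export
fit_deconvolution <- function(ds, signature, gene_set = NULL,
                              nonnegative = FALSE) {
  stopifnot(inherits(ds, "expr_dataset"))
  sig <- if (inherits(signature, "signature_matrix")) signature$values else
    as.matrix(signature)
  genes <- intersect(rownames(ds$values), rownames(sig))
  if (!is.null(gene_set)) genes <- intersect(genes, gene_set)
  k <- ncol(sig)
  if (length(genes) < k + 2) {
    abort("need at least n_cell_types + 2 shared genes")
  }
  X <- cbind(`(intercept)` = 1, sig[genes, , drop = FALSE])
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    abort(paste0("rank-deficient signature; collinear cell type(s): ",
                 paste(bad, collapse = ", ")))
  }
  Y <- ds$values[genes, , drop = FALSE]
  if (nonnegative) {
    coef <- apply(Y, 2L, function(y) {
      nn <- nnls_coef(X[, -1, drop = FALSE], y)
      c(mean(y - X[, -1, drop = FALSE] %*% nn), nn)
    })
  } else {
    coef <- qr.coef(qrx, Y)
  }
  coef <- t(coef)
  structure(list(
    coefficients = coef[, -1, drop = FALSE],
    intercepts = coef[, 1],
    meta = ds$meta, n_genes = length(genes), cell_types = colnames(sig)
  ), class = "deconv_result")
}

# simple active-set non-negative least squares (Lawson-Hanson)
nnls_coef <- function(A, b, tol = 1e-10) {
  k <- ncol(A)
  passive <- rep(FALSE, k)
  x <- numeric(k)
  for (iter in seq_len(30 * k)) {
    w <- crossprod(A, b - A %*% x)
    w[passive] <- -Inf
    if (all(w <= tol)) break
    passive[which.max(w)] <- TRUE
    repeat {
      s <- numeric(k)
      s[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      if (all(s[passive] > tol)) {
        x <- s
        break
      }
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[x <= tol] <- FALSE
      x[!passive] <- 0
    }
  }
  x
}

#' @export
print.deconv_result <- function(x, ...) {
  cat("<deconv_result> ", nrow(x$coefficients), " samples x ",
      length(x$cell_types), " cell types (", x$n_genes, " genes)\n",
      sep = "")
  invisible(x)
}

#' Age trend of deconvolved cell-type contributions
#'
#' Spearman correlation between each cell type's regression coefficient
#' and individual age, per period.
#'
#' @param result a [fit_deconvolution()] result.
#' @param periods periods to test (default both present).
#' @return a tibble: `cell_type`, `period`, `rho`, `p`.
#' @export
coefficient_age_trend <- function(result,
                                  periods = c("development", "ageing")) {
  stopifnot(inherits(result, "deconv_result"))
  periods <- intersect(periods, unique(result$meta$period))
  purrr::map_dfr(periods, function(per) {
    sel <- result$meta$period == per
    if (sum(sel) < 3) return(NULL)
    st <- spearman_matrix(t(result$coefficients[sel, , drop = FALSE]),
                          result$meta$age_days[sel])
    tibble::tibble(cell_type = result$cell_types, period = per,
                   rho = st$rho, p = st$p)
  })
}

#' Resampling test: are DiCo genes special for composition change?
#'
#' Null distribution: for each round, a random gene set of the same size
#' as the DiCo set is drawn from the shared gene universe, deconvolution
#' is refit, and each cell type's coefficient-age trend is recorded. The
#' observed DiCo-gene trends are compared one-sidedly (direction
#' `"greater"` on the signed trend, per the original scheme).
#'
#' @param ds bulk [expr_dataset()].
#' @param signature a [signature_matrix()].
#' @param dico_genes character vector of DiCo gene ids.
#' @param period period whose coefficient-age trend is tested.
#' @param n_rounds,seed resampling rounds and seed.
#' @return a tibble with one row per cell type: `cell_type`, `observed`,
#'   `p_value`, `efpp`, list-column `test`.
#' @export
resampling_test <- function(ds, signature, dico_genes, period = "ageing",
                            n_rounds = 1000, seed = 1L) {
  sig <- if (inherits(signature, "signature_matrix")) signature$values else
    as.matrix(signature)
  universe <- intersect(rownames(ds$values), rownames(sig))
  dico_genes <- intersect(dico_genes, universe)
  n_set <- length(dico_genes)
  obs <- fit_deconvolution(ds, signature, gene_set = dico_genes) |>
    coefficient_age_trend(periods = period)
  set.seed(seed)
  null_mat <- matrix(NA_real_, n_rounds, nrow(obs))
  for (r in seq_len(n_rounds)) {
    gs <- sample(universe, n_set)
    tr <- fit_deconvolution(ds, signature, gene_set = gs) |>
      coefficient_age_trend(periods = period)
    null_mat[r, ] <- tr$rho
  }
  purrr::map_dfr(seq_len(nrow(obs)), function(j) {
    pt <- perm_test(obs$rho[j], null_mat[, j], "greater", seed,
                    paste0("composition trend (", obs$cell_type[j], ")"))
    tibble::tibble(cell_type = obs$cell_type[j], observed = pt$observed,
                   p_value = pt$p_value, efpp = pt$efpp, test = list(pt))
  })
}

#' Cross-tissue cell-type pair correlations across age groups
#'
#' At the reference (youngest) age group, finds for each cell type of each
#' tissue its minimally and maximally correlated partner cell type in
#' every other tissue (Spearman over shared genes). The identified pairs
#' are held fixed and their correlation is recomputed at every age group;
#' the reported trend is the Spearman correlation of pair similarity with
#' age. A positive trend for minimum pairs means dissimilar cell types are
#' converging.
#'
#' @param signatures_by_age named list of [signature_matrix()] objects,
#'   names interpretable as numeric ages, each with per-cell-type tissue
#'   labels and a shared gene universe.
#' @return a tibble: `tissue`, `cell_type`, `partner_tissue`, `partner`,
#'   `kind` (`"min"`/`"max"`), per-age correlations in a list-column
#'   `correlations`, and `trend_rho`.
#' @export
celltype_pair_trends <- function(signatures_by_age) {
  if (length(signatures_by_age) < 2) abort("need at least 2 age groups")
  ages <- as.numeric(names(signatures_by_age))
  if (any(is.na(ages))) abort("list names must be numeric ages")
  ord <- order(ages)
  sigs <- signatures_by_age[ord]
  ages <- ages[ord]
  genes <- Reduce(intersect, lapply(sigs, function(s) rownames(s$values)))
  cors <- lapply(sigs, function(s) {
    cor(apply(s$values[genes, , drop = FALSE], 2L, rank))
  })
  ref <- cors[[1]]
  ct_meta <- sigs[[1]]$celltypes
  out <- purrr::map_dfr(seq_len(nrow(ct_meta)), function(i) {
    ct <- ct_meta$cell_type[i]
    t_i <- ct_meta$tissue[i]
    purrr::map_dfr(setdiff(unique(ct_meta$tissue), t_i), function(t_o) {
      cand <- ct_meta$cell_type[ct_meta$tissue == t_o]
      r <- ref[ct, cand]
      purrr::map_dfr(c(min = "min", max = "max"), function(kind) {
        partner <- cand[if (kind == "min") which.min(r) else which.max(r)]
        series <- vapply(cors, function(cm) cm[ct, partner], numeric(1))
        trend <- if (sd(series) == 0) 0 else
          spearman_age_trend(series, ages)$rho
        tibble::tibble(tissue = t_i, cell_type = ct,
                       partner_tissue = t_o, partner = partner,
                       kind = kind, correlations = list(series),
                       trend_rho = trend)
      })
    })
  })
  out
}

#' Within-tissue convergence of cell types
#'
#' For each individual, the CoV of every gene across its tissue's
#' cell-type mean profiles is averaged over genes; the age trend of that
#' mean CoV (per tissue) measures whether cell types within a tissue
#' become transcriptionally more similar (negative trend) with age.
#'
#' @param profiles genes x columns matrix of per-individual cell-type mean
#'   profiles.
#' @param meta tibble describing the columns: `column_id`, `tissue`,
#'   `cell_type`, `individual_id`, `age_days`.
#' @return a list with `per_individual` (tibble: `tissue`,
#'   `individual_id`, `age_days`, `mean_cov`, `n_cell_types`) and `trends`
#'   (tibble: `tissue`, `rho`, `p`).
#' @export
within_tissue_cov <- function(profiles, meta) {
  profiles <- as.matrix(profiles)
  stopifnot(all(meta$column_id %in% colnames(profiles)))
  per_ind <- meta |>
    dplyr::group_by(.data$tissue, .data$individual_id, .data$age_days) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(
      mean_cov = {
        v <- profiles[, .data$column_id, drop = FALSE]
        mu <- rowMeans(v)
        s <- sqrt(rowSums((v - mu)^2) / (ncol(v) - 1))
        cv <- s / mu
        mean(cv[mu > 0 & is.finite(cv)])
      },
      n_cell_types = dplyr::n(), .groups = "drop")
  trends <- per_ind |>
    dplyr::group_by(.data$tissue) |>
    dplyr::filter(dplyr::n() >= 3) |>
    dplyr::summarise(trend_or_na(.data$mean_cov, .data$age_days),
                     .groups = "drop")
  list(per_individual = per_ind, trends = trends)
}
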