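#' Permutation-test result
#'
#' Container for a dependence-preserving permutation test: the observed
#' statistic, the permutation null values, the one-sided raw-proportion
#' p-value, and the estimated false-positive proportion
#' (eFPP = median(null) / observed).
#'
#' @param observed observed statistic.
#' @param null_values numeric vector, one statistic per permutation round.
#' @param direction `"greater"` (observed expected above the null) or
#'   `"less"`.
#' @param seed integer seed used for the permutations.
#' @param statistic label of the statistic.
#' @param add_one apply the (k+1)/(B+1) correction instead of the raw
#'   proportion (off by default).
#' @return an object of class `perm_test`.
#' @export
perm_test <- function(observed, null_values, direction = "greater",
                      seed = NA_integer_, statistic = "statistic",
                      add_one = FALSE) {
  pe <- permutation_p(observed, null_values, direction, add_one)
  structure(list(observed = observed, null_values = null_values,
                 p_value = pe$p, efpp = pe$efpp,
                 n_rounds = length(null_values), direction = direction,
                 seed = seed, statistic = statistic),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("<perm_test> ", x$statistic, "\n", sep = "")
  cat("  observed = ", format(x$observed), ", one-sided p = ",
      format(x$p_value), " (", x$n_rounds, " rounds, direction ",
      x$direction, ")\n  eFPP = ", format(x$efpp), "\n", sep = "")
  invisible(x)
}

#' One-sided permutation p-value and eFPP
#'
#' p is the raw proportion of permutation rounds at least as extreme as the
#' observed statistic (so it can be exactly 0); `add_one = TRUE` switches
#' to the (k+1)/(B+1) estimator. The eFPP is the median of the null values
#' divided by the observed value (undefined when the observed value is 0).
#'
#' @param observed observed statistic.
#' @param null_values numeric vector of permutation statistics.
#' @param direction `"greater"` or `"less"`.
#' @param add_one logical.
#' @return a list with elements `p` and `efpp`.
#' @export
permutation_p <- function(observed, null_values,
                          direction = c("greater", "less"),
                          add_one = FALSE) {
  direction <- match.arg(direction)
  if (length(null_values) < 1) abort("need at least one null value")
  k <- if (direction == "greater") sum(null_values >= observed)
       else sum(null_values <= observed)
  p <- if (add_one) (k + 1) / (length(null_values) + 1)
       else k / length(null_values)
  efpp <- if (!is.na(observed) && observed != 0) {
    median(null_values) / observed
  } else NA_real_
  list(p = p, efpp = efpp)
}

#' Permute individual ages consistently across tissues
#'
#' Draws one bijection from individuals to their own multiset of ages and
#' applies it to every tissue sample of each individual, so the dependence
#' of tissues sampled from the same animal is preserved under the null.
#' Consumes the current RNG stream.
#'
#' @param meta sample metadata (tibble with `individual_id`, `age_days`,
#'   and optionally `period`).
#' @param period optional: permute ages only among individuals of this
#'   period, leaving the others untouched (the ageing-only scheme used by
#'   the reversal and DiCo tests).
#' @return named numeric vector: permuted age per individual.
#' @export
permute_ages_consistent <- function(meta, period = NULL) {
  ind <- meta[!duplicated(meta$individual_id),
              c("individual_id", "age_days",
                intersect("period", names(meta)))]
  ages <- setNames(ind$age_days, ind$individual_id)
  target <- if (is.null(period)) names(ages) else
    ind$individual_id[ind$period == period]
  if (length(target) > 1) {
    ages[target] <- ages[sample(target)]
  }
  ages
}

# --- internal permutation engine ------------------------------------------
# Precomputes, per tissue within one period, the standardised row-rank
# expression matrix (genes x individuals) so a permutation round reduces to
# one matrix-vector product per tissue.
perm_engine <- function(ds, period, genes = NULL) {
  m <- meta_subset(ds, period = period)
  tiss <- tissues_of(ds)
  if (is.null(genes)) genes <- rownames(ds$values)
  per_tissue <- lapply(tiss, function(t) {
    mt <- m[m$tissue == t, , drop = FALSE]
    mt <- mt[order(mt$individual_id), , drop = FALSE]
    sr <- std_rank_matrix(ds$values[genes, mt$sample_id, drop = FALSE])
    list(sr = sr, individuals = mt$individual_id,
         ages = setNames(mt$age_days, mt$individual_id))
  })
  names(per_tissue) <- tiss
  ind <- m[!duplicated(m$individual_id), , drop = FALSE]
  list(tissues = per_tissue, genes = genes,
       ind_ages = setNames(ind$age_days, ind$individual_id))
}

# rho of every gene against an individual->age assignment, one tissue
engine_rho <- function(eng_t, ages_by_ind) {
  a <- ages_by_ind[eng_t$individuals]
  as.vector(eng_t$sr %*% std_ranks(a))
}

#' Permutation test of cross-tissue trend similarity
#'
#' Tests, per tissue pair, whether the Spearman correlation between the two
#' tissues' per-gene expression-age trend values exceeds what identical
#' age shuffles (shared across tissues, within the period) produce.
#'
#' @param ds a normalised [expr_dataset()].
#' @param period period to test.
#' @param n_rounds number of permutation rounds (default 1000).
#' @param seed integer seed.
#' @return a tibble with one row per tissue pair: `tissue1`, `tissue2`,
#'   `observed`, `p_value`, `efpp`, and the `perm_test` object in a
#'   list-column `test`.
#' @export
test_cross_tissue_similarity <- function(ds, period, n_rounds = 1000,
                                         seed = 1L) {
  eng <- perm_engine(ds, period)
  tiss <- names(eng$tissues)
  obs_rho <- vapply(eng$tissues, function(et) engine_rho(et, eng$ind_ages),
                    numeric(length(eng$genes)))
  ok <- stats::complete.cases(obs_rho)
  pair_cor <- function(rhos) {
    rr <- apply(rhos[ok, , drop = FALSE], 2L, rank)
    cor(rr)
  }
  obs <- pair_cor(obs_rho)
  set.seed(seed)
  pairs <- utils::combn(tiss, 2)
  null_mat <- matrix(NA_real_, n_rounds, ncol(pairs))
  for (r in seq_len(n_rounds)) {
    perm <- permute_ages_consistent(
      tibble::tibble(individual_id = names(eng$ind_ages),
                     age_days = eng$ind_ages))
    rhos <- vapply(eng$tissues, function(et) engine_rho(et, perm),
                   numeric(length(eng$genes)))
    pc <- pair_cor(rhos)
    null_mat[r, ] <- pc[t(pairs)]
  }
  obs_vals <- obs[t(pairs)]
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    pt <- perm_test(obs_vals[j], null_mat[, j], "greater", seed,
                    paste0("trend similarity ", pairs[1, j], "-",
                           pairs[2, j]))
    tibble::tibble(tissue1 = pairs[1, j], tissue2 = pairs[2, j],
                   observed = pt$observed, p_value = pt$p_value,
                   efpp = pt$efpp, test = list(pt))
  })
}

#' Permutation test of shared age-related expression direction
#'
#' Observed statistic: the number of genes whose expression-age trend has
#' the tested direction in every tissue. With `use_significance = TRUE`
#' each tissue contributes only its N significantly changed genes (BH
#' q < `q_cutoff`), and each permutation round takes the top/bottom N genes
#' per tissue by permuted trend rank, mirroring the observed set sizes.
#'
#' @param ds a normalised [expr_dataset()].
#' @param period period to test.
#' @param direction `"up"` or `"down"`.
#' @param use_significance restrict to per-tissue significant genes.
#' @param q_cutoff BH threshold used when `use_significance = TRUE`.
#' @param n_rounds,seed permutation rounds and seed.
#' @return a `perm_test`, or `NULL` (with a warning) when a tissue has no
#'   significant genes to contribute.
#' @export
test_shared_overlap <- function(ds, period, direction = c("up", "down"),
                                use_significance = FALSE, q_cutoff = 0.1,
                                n_rounds = 1000, seed = 1L) {
  direction <- match.arg(direction)
  sgn <- if (direction == "up") 1 else -1
  eng <- perm_engine(ds, period)
  obs_rho <- vapply(eng$tissues, function(et) engine_rho(et, eng$ind_ages),
                    numeric(length(eng$genes)))
  ok <- stats::complete.cases(obs_rho)
  obs_rho <- obs_rho[ok, , drop = FALSE]

  if (use_significance) {
    q_mat <- vapply(seq_along(eng$tissues), function(j) {
      r <- obs_rho[, j]
      nn <- length(eng$tissues[[j]]$individuals)
      tval <- r * sqrt((nn - 2) / pmax(1 - r^2, 1e-300))
      bh_adjust(2 * pt(-abs(tval), nn - 2))
    }, numeric(nrow(obs_rho)))
    n_sig <- colSums(q_mat < q_cutoff & sign(obs_rho) == sgn)
    if (any(n_sig == 0)) {
      warn("a tissue has no significant genes in this direction; test skipped")
      return(NULL)
    }
    count_overlap <- function(rhos) {
      sel <- vapply(seq_len(ncol(rhos)), function(j) {
        r <- rank(sgn * rhos[, j])
        r > length(r) - n_sig[j]   # top N by signed trend
      }, logical(nrow(rhos)))
      sum(rowSums(sel) == ncol(rhos))
    }
  } else {
    count_overlap <- function(rhos) sum(rowSums(sign(rhos) == sgn) ==
                                          ncol(rhos))
  }

  observed <- count_overlap(obs_rho)
  set.seed(seed)
  null_vals <- numeric(n_rounds)
  for (r in seq_len(n_rounds)) {
    perm <- permute_ages_consistent(
      tibble::tibble(individual_id = names(eng$ind_ages),
                     age_days = eng$ind_ages))
    rhos <- vapply(eng$tissues, function(et) engine_rho(et, perm),
                   numeric(length(eng$genes)))[ok, , drop = FALSE]
    null_vals[r] <- count_overlap(rhos)
  }
  perm_test(observed, null_vals, "greater", seed,
            paste0("shared ", direction, "-regulation overlap (", period,
                   ")"))
}
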