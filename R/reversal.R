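#' Classify a gene's development/ageing trend pair
#'
#' Maps the signs of the developmental and ageing expression-age
#' correlations to the four trajectory classes: UU (up-up), UD (up-down,
#' a reversal), DU (down-up, a reversal), DD (down-down). A zero or
#' undefined correlation in either period leaves the gene unclassified
#' (`NA`): with continuous data an exactly zero rho is measure-zero, and
#' constant-expression genes are excluded rather than assigned a sign.
#'
#' @param dev_rho,ageing_rho Spearman correlations (vectors accepted).
#' @return character vector of `"UU"`, `"UD"`, `"DU"`, `"DD"` or `NA`.
#' @export
classify_reversal <- function(dev_rho, ageing_rho) {
  out <- paste0(ifelse(dev_rho > 0, "U", "D"),
                ifelse(ageing_rho > 0, "U", "D"))
  out[is.na(dev_rho) | is.na(ageing_rho) |
        dev_rho == 0 | ageing_rho == 0] <- NA_character_
  out
}

#' Reversal classification table for every gene and tissue
#'
#' No significance cutoff is applied: every gene with defined, non-zero
#' trends in both periods is classified.
#'
#' @param trends an [age_trend_table()] with both periods.
#' @return a tibble with columns `gene`, `tissue`, `dev_rho`,
#'   `ageing_rho`, `class`.
#' @export
reversal_table <- function(trends) {
  wide <- trends |>
    dplyr::select("gene", "tissue", "period", "rho") |>
    tidyr::pivot_wider(names_from = "period", values_from = "rho")
  tibble::tibble(
    gene = wide$gene, tissue = wide$tissue,
    dev_rho = wide$development, ageing_rho = wide$ageing,
    class = classify_reversal(wide$development, wide$ageing)
  )
}

#' Reversal proportions conditioned on the developmental direction
#'
#' UD% = UD / (UU + UD) among developmentally upregulated genes and
#' DU% = DU / (DD + DU) among developmentally downregulated genes.
#'
#' @param table a [reversal_table()].
#' @param tissue optional tissue filter (default: all tissues, one row
#'   each).
#' @return a tibble with columns `tissue`, `ud_pct`, `du_pct` (proportions
#'   in \[0, 1\]; `NA` with a warning when a denominator is empty).
#' @export
reversal_proportions <- function(table, tissue = NULL) {
  tb <- if (is.null(tissue)) table else table[table$tissue %in% tissue, ]
  tb |>
    dplyr::filter(!is.na(.data$class)) |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(
      ud_pct = prop_safe(sum(.data$class == "UD"),
                         sum(.data$class %in% c("UU", "UD"))),
      du_pct = prop_safe(sum(.data$class == "DU"),
                         sum(.data$class %in% c("DD", "DU"))),
      .groups = "drop")
}

prop_safe <- function(num, den) {
  if (den == 0) {
    warn("empty denominator: proportion undefined")
    return(NA_real_)
  }
  num / den
}

#' Ageing-only permutation test of reversal proportions
#'
#' Keeps the developmental trends fixed and permutes individual ages among
#' ageing-period individuals only (shared across tissues), recomputing UD%
#' among the developmentally upregulated genes (and DU% among the
#' downregulated ones) in each round. One-sided for excess reversal.
#'
#' @param ds a normalised [expr_dataset()].
#' @param tissue tissue to test.
#' @param n_rounds,seed permutation rounds and seed.
#' @return a list with `perm_test` elements `ud` and `du`.
#' @export
test_reversal <- function(ds, tissue, n_rounds = 1000, seed = 1L) {
  m_dev <- meta_subset(ds, "development", tissue)
  dev_rho <- spearman_matrix(ds$values[, m_dev$sample_id, drop = FALSE],
                             m_dev$age_days)$rho
  eng <- perm_engine(ds, "ageing")
  et <- eng$tissues[[tissue]]
  obs_age_rho <- engine_rho(et, eng$ind_ages)
  up <- !is.na(dev_rho) & dev_rho > 0
  down <- !is.na(dev_rho) & dev_rho < 0
  ud_pct <- function(age_rho) {
    ok <- up & !is.na(age_rho) & age_rho != 0
    sum(age_rho[ok] < 0) / sum(ok)
  }
  du_pct <- function(age_rho) {
    ok <- down & !is.na(age_rho) & age_rho != 0
    sum(age_rho[ok] > 0) / sum(ok)
  }
  set.seed(seed)
  null_ud <- null_du <- numeric(n_rounds)
  for (r in seq_len(n_rounds)) {
    perm <- permute_ages_consistent(
      tibble::tibble(individual_id = names(eng$ind_ages),
                     age_days = eng$ind_ages))
    rho_r <- engine_rho(et, perm)
    null_ud[r] <- ud_pct(rho_r)
    null_du[r] <- du_pct(rho_r)
  }
  list(
    ud = perm_test(ud_pct(obs_age_rho), null_ud, "greater", seed,
                   paste0("UD% (", tissue, ")")),
    du = perm_test(du_pct(obs_age_rho), null_du, "greater", seed,
                   paste0("DU% (", tissue, ")"))
  )
}

#' Permutation test of cross-tissue shared reversal
#'
#' Among genes whose developmental trend has the tested direction in every
#' tissue, the statistic is the proportion whose ageing trend is reversed
#' in every tissue, against genes continuing in every tissue (shared UD vs
#' shared UD + shared UU, and likewise for DU). The null permutes ageing
#' ages consistently across tissues.
#'
#' @param ds a normalised [expr_dataset()].
#' @param direction `"UD"` or `"DU"`.
#' @param n_rounds,seed permutation rounds and seed.
#' @return a `perm_test`.
#' @export
test_reversal_overlap <- function(ds, direction = c("UD", "DU"),
                                  n_rounds = 1000, seed = 1L) {
  direction <- match.arg(direction)
  dev_sgn <- if (direction == "UD") 1 else -1
  eng_dev <- perm_engine(ds, "development")
  eng_age <- perm_engine(ds, "ageing")
  dev_rho <- vapply(eng_dev$tissues,
                    function(et) engine_rho(et, eng_dev$ind_ages),
                    numeric(length(eng_dev$genes)))
  shared_dev <- rowSums(sign(dev_rho) == dev_sgn) == ncol(dev_rho) &
    stats::complete.cases(dev_rho)
  shared_ratio <- function(age_rho) {
    ok <- shared_dev & stats::complete.cases(age_rho) &
      rowSums(age_rho == 0) == 0
    rev_all <- rowSums(sign(age_rho[ok, , drop = FALSE]) == -dev_sgn) ==
      ncol(age_rho)
    cont_all <- rowSums(sign(age_rho[ok, , drop = FALSE]) == dev_sgn) ==
      ncol(age_rho)
    if (sum(rev_all) + sum(cont_all) == 0) return(NA_real_)
    sum(rev_all) / (sum(rev_all) + sum(cont_all))
  }
  obs_age <- vapply(eng_age$tissues,
                    function(et) engine_rho(et, eng_age$ind_ages),
                    numeric(length(eng_age$genes)))
  observed <- shared_ratio(obs_age)
  set.seed(seed)
  null_vals <- numeric(n_rounds)
  for (r in seq_len(n_rounds)) {
    perm <- permute_ages_consistent(
      tibble::tibble(individual_id = names(eng_age$ind_ages),
                     age_days = eng_age$ind_ages))
    rhos <- vapply(eng_age$tissues, function(et) engine_rho(et, perm),
                   numeric(length(eng_age$genes)))
    null_vals[r] <- shared_ratio(rhos)
  }
  perm_test(observed, null_vals[!is.na(null_vals)], "greater", seed,
            paste0("shared ", direction, " reversal ratio"))
}
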