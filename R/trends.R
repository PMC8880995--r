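#' Per-gene expression-age trends by tissue and period
#'
#' Spearman correlation between expression and individual age, computed for
#' every gene separately in each tissue and each lifespan period, with BH
#' adjustment within each tissue x period family (the multiple-testing
#' family in which per-tissue significant counts are reported).
#'
#' @param ds a normalised [expr_dataset()].
#' @param periods which periods to compute (default both).
#' @return an `AgeTrendTable`: a tibble with columns `gene`, `tissue`,
#'   `period`, `rho`, `p`, `q`. Genes with constant expression in a tissue
#'   x period stratum carry `NA` and are excluded downstream.
#' @export
age_trend_table <- function(ds, periods = c("development", "ageing")) {
  stopifnot(inherits(ds, "expr_dataset"))
  combos <- expand.grid(tissue = tissues_of(ds), period = periods,
                        stringsAsFactors = FALSE)
  res <- purrr::pmap(combos, function(tissue, period) {
    m <- meta_subset(ds, period = period, tissue = tissue)
    if (nrow(m) < 3) return(NULL)
    st <- spearman_matrix(ds$values[, m$sample_id, drop = FALSE], m$age_days)
    tibble::tibble(gene = rownames(ds$values), tissue = tissue,
                   period = period, rho = st$rho, p = st$p,
                   q = bh_adjust(st$p))
  })
  dplyr::bind_rows(res)
}

#' Cross-tissue similarity of age-related expression change
#'
#' Spearman correlation, over genes, between the per-gene expression-age
#' trend values (rho) of each tissue pair within one period. High values
#' mean tissues share their age-related expression changes.
#'
#' @param trends an [age_trend_table()] result.
#' @param period `"development"` or `"ageing"`.
#' @return a symmetric tissue x tissue matrix with unit diagonal.
#' @export
cross_tissue_similarity <- function(trends, period) {
  tr <- trends[trends$period == period, , drop = FALSE]
  wide <- tidyr::pivot_wider(tr[, c("gene", "tissue", "rho")],
                             names_from = "tissue", values_from = "rho")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (nrow(mat) < 3) abort("fewer than 3 genes with defined trends shared")
  out <- cor(apply(mat, 2L, rank))
  diag(out) <- 1
  out
}

#' Count tissues sharing each gene's direction of age-related change
#'
#' For each gene, counts the tissues whose expression-age trend shares the
#' majority sign, split into up- and down-majorities. With `q_cutoff` set,
#' only tissues where the gene is significant (BH q below the cutoff)
#' participate.
#'
#' @param trends an [age_trend_table()] result.
#' @param period period to summarise.
#' @param q_cutoff optional BH q threshold.
#' @return a tibble with columns `gene`, `direction` (`"up"`/`"down"`),
#'   `n_tissues` (tissues sharing that direction; genes with no
#'   participating tissue are dropped).
#' @export
shared_direction_counts <- function(trends, period, q_cutoff = NULL) {
  tr <- trends[trends$period == period & !is.na(trends$rho), , drop = FALSE]
  if (!is.null(q_cutoff)) tr <- tr[!is.na(tr$q) & tr$q < q_cutoff, ,
                                   drop = FALSE]
  tr |>
    dplyr::mutate(direction = ifelse(.data$rho > 0, "up", "down")) |>
    dplyr::filter(.data$rho != 0) |>
    dplyr::count(.data$gene, .data$direction, name = "n_tissues") |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice_max(.data$n_tissues, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}
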