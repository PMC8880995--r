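#' Cohen's d of one tissue against the pooled others
#'
#' Effect size of a gene's expression in a focal tissue versus the pooled
#' other tissues: difference of the two means divided by the pooled
#' standard deviation `sqrt(((n1-1)s1^2 + (n2-1)s2^2) / (n1+n2-2))`.
#'
#' @param focal numeric vector of expression in the focal tissue.
#' @param others numeric vector of expression in the pooled other tissues.
#' @return Cohen's d (positive when the focal tissue is higher); `NA` when
#'   the pooled sd is 0.
#' @export
cohens_d <- function(focal, others) {
  n1 <- length(focal); n2 <- length(others)
  if (n1 < 2 || n2 < 2) abort("need at least 2 samples per group")
  sp <- sqrt(((n1 - 1) * var(focal) + (n2 - 1) * var(others)) /
               (n1 + n2 - 2))
  if (sp == 0) return(NA_real_)
  (mean(focal) - mean(others)) / sp
}

# vectorised Cohen's d for all genes: focal block vs pooled-others block
cohens_d_matrix <- function(focal_mat, others_mat) {
  n1 <- ncol(focal_mat); n2 <- ncol(others_mat)
  m1 <- rowMeans(focal_mat); m2 <- rowMeans(others_mat)
  v1 <- rowSums((focal_mat - m1)^2) / (n1 - 1)
  v2 <- rowSums((others_mat - m2)^2) / (n2 - 1)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  d <- (m1 - m2) / sp
  d[sp == 0] <- NA_real_
  d
}

#' Call tissue-specific genes from developmental samples
#'
#' Computes each gene's Cohen's d for every tissue versus the pooled other
#' tissues using development-period samples only, assigns the gene to the
#' tissue with the highest effect size (ties broken to the first tissue in
#' canonical sort order), and flags as tissue-specific the top effect-size
#' quartile (strictly above Q3, type-7 quantile) within each assigned
#' tissue's gene group.
#'
#' @param ds a normalised [expr_dataset()] containing development samples
#'   from every tissue.
#' @param quantile_type quantile algorithm for Q3 (default 7).
#' @return a `TissueSpecificityTable` tibble: `gene`, one `es_<tissue>`
#'   column per tissue, `assigned_tissue`, `es` (the winning effect size),
#'   `is_specific`.
#' @export
call_tissue_specific <- function(ds, quantile_type = 7) {
  stopifnot(inherits(ds, "expr_dataset"))
  m <- meta_subset(ds, period = "development")
  tiss <- tissues_of(ds)
  es <- vapply(tiss, function(t) {
    cols_f <- m$sample_id[m$tissue == t]
    cols_o <- m$sample_id[m$tissue != t]
    cohens_d_matrix(ds$values[, cols_f, drop = FALSE],
                    ds$values[, cols_o, drop = FALSE])
  }, numeric(nrow(ds$values)))
  rownames(es) <- rownames(ds$values)
  assigned <- tiss[apply(es, 1L, function(x) {
    if (all(is.na(x))) NA_integer_ else which.max(x)
  })]
  best <- es[cbind(seq_len(nrow(es)),
                   match(assigned, tiss))]
  es_named <- es
  colnames(es_named) <- paste0("es_", tiss)
  out <- dplyr::bind_cols(tibble::tibble(gene = rownames(es)),
                          tibble::as_tibble(es_named))
  out$assigned_tissue <- assigned
  out$es <- best
  out <- out |>
    dplyr::group_by(.data$assigned_tissue) |>
    dplyr::mutate(is_specific = !is.na(.data$es) &
                    .data$es > quantile(.data$es, 0.75, na.rm = TRUE,
                                        type = quantile_type)) |>
    dplyr::ungroup()
  out$is_specific[is.na(out$assigned_tissue)] <- FALSE
  out
}

#' Fisher's exact test on a 2x2 table, with both odds-ratio conventions
#'
#' Two-sided p-value and conditional maximum-likelihood odds ratio from
#' `stats::fisher.test` (the hypergeometric-likelihood convention), plus
#' the sample cross-product odds ratio `ad/bc`. A zero margin yields an
#' undefined OR and p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return a `ContingencyResult` tibble: `odds_ratio` (conditional MLE),
#'   `sample_or`, `p`, and the four cell counts `n11`, `n12`, `n21`,
#'   `n22`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) ||
      any(table != round(table))) {
    abort("need a 2x2 table of non-negative integer counts")
  }
  zero_margin <- any(rowSums(table) == 0) || any(colSums(table) == 0)
  if (zero_margin) {
    or <- NA_real_; p <- 1; sor <- NA_real_
  } else {
    ft <- fisher.test(table)
    or <- unname(ft$estimate)
    p <- ft$p.value
    sor <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  }
  tibble::tibble(odds_ratio = or, sample_or = sor, p = p,
                 n11 = table[1, 1], n12 = table[1, 2],
                 n21 = table[2, 1], n22 = table[2, 2])
}

# per-gene, per-tissue OLS slope of expression on log2(age) during ageing
ageing_slopes <- function(ds) {
  tiss <- tissues_of(ds)
  out <- vapply(tiss, function(t) {
    m <- meta_subset(ds, period = "ageing", tissue = t)
    slope_matrix(ds$values[, m$sample_id, drop = FALSE],
                 log2(m$age_days))
  }, numeric(nrow(ds$values)))
  rownames(out) <- rownames(ds$values)
  out
}

#' Identity-loss test: direction of maximal ageing change vs nativeness
#'
#' For each tissue-specific gene, the OLS slope of expression on log2(age)
#' during ageing is computed in every tissue; the tissue with the largest
#' absolute slope ("maximum expression change"; ties broken to the first
#' tissue in canonical order) gives two binary labels: whether that change
#' is negative, and whether it occurs in the gene's native (assigned)
#' tissue. The 2x2 Fisher test's OR exceeds 1 when genes tend to lose
#' expression in their native tissue and/or gain it elsewhere — the
#' identity-loss signature.
#'
#' @param ds a normalised [expr_dataset()] with ageing samples in all
#'   tissues.
#' @param specificity a [call_tissue_specific()] table.
#' @param gene_subset optional character vector restricting the tested
#'   tissue-specific genes (e.g. to DiCo genes).
#' @param signed_max use the signed maximum slope instead of the maximum
#'   absolute slope (variant, off by default).
#' @return a [fisher_exact()] result with an attached `detail` attribute
#'   (per-gene tibble: `gene`, `max_tissue`, `slope`, `native`).
#' @export
native_loss_test <- function(ds, specificity, gene_subset = NULL,
                             signed_max = FALSE) {
  spec_genes <- specificity[specificity$is_specific, , drop = FALSE]
  if (!is.null(gene_subset)) {
    spec_genes <- spec_genes[spec_genes$gene %in% gene_subset, ,
                             drop = FALSE]
  }
  if (nrow(spec_genes) == 0) abort("no tissue-specific genes to test")
  slopes <- ageing_slopes(ds)[spec_genes$gene, , drop = FALSE]
  crit <- if (signed_max) slopes else abs(slopes)
  max_idx <- apply(crit, 1L, which.max)
  tiss <- colnames(slopes)
  max_tissue <- tiss[max_idx]
  max_slope <- slopes[cbind(seq_len(nrow(slopes)), max_idx)]
  native <- max_tissue == spec_genes$assigned_tissue
  negative <- max_slope < 0
  tab <- matrix(c(sum(negative & native), sum(negative & !native),
                  sum(!negative & native), sum(!negative & !native)),
                nrow = 2, byrow = TRUE,
                dimnames = list(direction = c("negative", "positive"),
                                native = c("native", "non_native")))
  res <- fisher_exact(tab)
  attr(res, "detail") <- tibble::tibble(
    gene = spec_genes$gene, max_tissue = max_tissue, slope = max_slope,
    native = native)
  res
}

#' Enrichment of tissue specificity in DiCo and in reversal classes
#'
#' Two Fisher's exact analyses on a shared gene universe: (1) tissue
#' specificity x DiCo membership; (2) per tissue, among developmentally
#' upregulated genes of that tissue, specificity (assigned to that tissue)
#' x UD reversal. Degenerate strata (a one-level variable) are skipped
#' with a warning.
#'
#' @param specificity a [call_tissue_specific()] table.
#' @param dico_call a [call_dico()] table.
#' @param reversal a [reversal_table()] (optional; reversal tests skipped
#'   when absent).
#' @return a tibble with one row per performed test: `test`, `tissue`,
#'   and the [fisher_exact()] columns.
#' @export
enrichment_tests <- function(specificity, dico_call, reversal = NULL) {
  genes <- intersect(specificity$gene, dico_call$gene)
  sp <- specificity[match(genes, specificity$gene), ]
  dc <- dico_call[match(genes, dico_call$gene), ]
  out <- list()
  if (length(unique(sp$is_specific)) == 2 &&
      length(unique(dc$is_dico)) == 2) {
    tab <- table(factor(sp$is_specific, c(TRUE, FALSE)),
                 factor(dc$is_dico, c(TRUE, FALSE)))
    out[["dico"]] <- dplyr::bind_cols(
      tibble::tibble(test = "specific_in_dico", tissue = NA_character_),
      fisher_exact(tab))
  } else {
    warn("degenerate specificity/DiCo stratum: test skipped")
  }
  if (!is.null(reversal)) {
    for (t in unique(reversal$tissue)) {
      rv <- reversal[reversal$tissue == t &
                       reversal$class %in% c("UU", "UD"), ]
      rv <- rv[rv$gene %in% genes, ]
      sp_t <- sp$is_specific & sp$assigned_tissue == t
      names(sp_t) <- sp$gene
      is_spec <- sp_t[rv$gene]
      is_ud <- rv$class == "UD"
      if (length(unique(is_spec)) < 2 || length(unique(is_ud)) < 2) {
        warn(paste0("degenerate reversal stratum in ", t, ": skipped"))
        next
      }
      tab <- table(factor(is_spec, c(TRUE, FALSE)),
                   factor(is_ud, c(TRUE, FALSE)))
      out[[t]] <- dplyr::bind_cols(
        tibble::tibble(test = "specific_in_ud", tissue = t),
        fisher_exact(tab))
    }
  }
  dplyr::bind_rows(out)
}
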