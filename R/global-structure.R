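#' Principal-component scores of an expression dataset
#'
#' PCA of samples on the gene-centred (and by default gene-scaled)
#' expression matrix. Component signs are fixed deterministically: each
#' component is flipped so its largest-magnitude gene loading is positive,
#' making trend signs reproducible across runs and platforms. Constant
#' genes are dropped (with a warning) when scaling is requested.
#'
#' @param ds an [expr_dataset()].
#' @param scale_genes scale each gene to unit variance (default `TRUE`).
#' @param n_components number of components to retain (default all).
#' @return an object of class `pca_result`: list with `scores` (sample x
#'   component matrix), `loadings`, `explained` (variance fractions,
#'   non-increasing) and `meta` (the sample metadata).
#' @export
pca_scores <- function(ds, scale_genes = TRUE, n_components = NULL) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (ncol(ds$values) < 2) abort("need at least 2 samples")
  v <- ds$values
  if (scale_genes) {
    sds <- apply(v, 1L, sd)
    if (any(sds == 0)) {
      warn("dropping constant gene(s) before scaled PCA")
      v <- v[sds > 0, , drop = FALSE]
    }
  }
  pc <- prcomp(t(v), center = TRUE, scale. = scale_genes)
  flip <- apply(pc$rotation, 2L, function(w) sign(w[which.max(abs(w))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2L, flip, `*`)
  loadings <- sweep(pc$rotation, 2L, flip, `*`)
  if (!is.null(n_components)) {
    keep <- seq_len(min(n_components, ncol(scores)))
    scores <- scores[, keep, drop = FALSE]
    loadings <- loadings[, keep, drop = FALSE]
  }
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 explained = explained, meta = ds$meta),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$scores), " samples, first components explain ",
      paste0(round(100 * head(x$explained, 4), 1), "%", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Inter-tissue Euclidean distance in PC space, and its age trend
#'
#' For every individual with at least two tissues, the pairwise Euclidean
#' distances among its tissue samples in the retained PC block (raw scores
#' of components 1-4 by default) are averaged; the per-period Spearman
#' trend of that mean distance with age quantifies divergence (positive)
#' or convergence (negative) of the whole transcriptome.
#'
#' @param pca a [pca_scores()] result.
#' @param components integer vector of components to use (default 1:4).
#' @return a list with `distances` (tibble: `individual_id`, `age_days`,
#'   `period`, `mean_distance`) and `trends` (tibble: `period`, `rho`,
#'   `p`).
#' @export
pc_distance_trend <- function(pca, components = 1:4) {
  stopifnot(inherits(pca, "pca_result"))
  components <- components[components <= ncol(pca$scores)]
  sc <- pca$scores[, components, drop = FALSE]
  m <- pca$meta
  dists <- purrr::map_dfr(unique(m$individual_id), function(i) {
    mi <- m[m$individual_id == i, , drop = FALSE]
    if (nrow(mi) < 2) return(NULL)
    d <- dist(sc[match(mi$sample_id, m$sample_id), , drop = FALSE])
    tibble::tibble(individual_id = i, age_days = mi$age_days[1],
                   period = mi$period[1], mean_distance = mean(d))
  })
  trends <- dists |>
    dplyr::group_by(.data$period) |>
    dplyr::filter(dplyr::n() >= 3) |>
    dplyr::summarise(trend_or_na(.data$mean_distance,
                                 .data$age_days), .groups = "drop")
  list(distances = dists, trends = trends)
}

#' Remove the tissue effect by per-tissue gene standardisation
#'
#' Scales each gene to mean 0 and sd 1 within every tissue separately and
#' recombines the tissues, leaving only within-tissue (e.g. age-driven)
#' variation. Zero-variance genes within a tissue are set to 0 with a
#' warning. Idempotent up to numerical tolerance.
#'
#' @param ds an [expr_dataset()] with at least 2 samples per tissue.
#' @return an `expr_dataset` of per-tissue z-scores.
#' @export
remove_tissue_effect <- function(ds) {
  stopifnot(inherits(ds, "expr_dataset"))
  v <- ds$values
  warned <- FALSE
  for (t in tissues_of(ds)) {
    cols <- ds$meta$sample_id[ds$meta$tissue == t]
    if (length(cols) < 2) abort("need at least 2 samples per tissue")
    block <- v[, cols, drop = FALSE]
    mu <- rowMeans(block)
    s <- apply(block, 1L, sd)
    z <- (block - mu) / s
    if (any(s == 0)) {
      z[s == 0, ] <- 0
      warned <- TRUE
    }
    v[, cols] <- z
  }
  if (warned) warn("zero-variance gene(s) within a tissue set to 0")
  out <- ds
  out$values <- v
  out
}
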