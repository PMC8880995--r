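#' Tidy a permutation test
#'
#' @param x a `perm_test`.
#' @param ... unused.
#' @return one-row tibble: `statistic`, `observed`, `p_value`, `efpp`,
#'   `n_rounds`, `direction`.
#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, observed = x$observed,
                 p_value = x$p_value, efpp = x$efpp,
                 n_rounds = x$n_rounds, direction = x$direction)
}

#' @rdname tidy.perm_test
#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) tidy.perm_test(x)

#' Tidy a deconvolution result
#'
#' @param x a `deconv_result`.
#' @param ... unused.
#' @return a long tibble: `sample_id`, `individual_id`, `age_days`,
#'   `period`, `cell_type`, `coefficient`, `intercept`.
#' @method tidy deconv_result
#' @export
tidy.deconv_result <- function(x, ...) {
  long <- tibble::tibble(
    sample_id = rep(rownames(x$coefficients), times = ncol(x$coefficients)),
    cell_type = rep(x$cell_types, each = nrow(x$coefficients)),
    coefficient = as.vector(x$coefficients),
    intercept = rep(unname(x$intercepts), times = ncol(x$coefficients))
  )
  dplyr::left_join(long,
                   x$meta[, c("sample_id", "individual_id", "age_days",
                              "period")],
                   by = "sample_id")
}

#' @rdname tidy.deconv_result
#' @method glance deconv_result
#' @export
glance.deconv_result <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$coefficients),
                 n_cell_types = length(x$cell_types), n_genes = x$n_genes)
}

#' Tidy a PCA result
#'
#' @param x a `pca_result`.
#' @param ... unused.
#' @return tibble of scores joined to sample metadata, one row per sample
#'   x component.
#' @method tidy pca_result
#' @export
tidy.pca_result <- function(x, ...) {
  sc <- tibble::as_tibble(x$scores)
  sc$sample_id <- rownames(x$scores)
  long <- tidyr::pivot_longer(sc, -"sample_id", names_to = "component",
                              values_to = "score")
  dplyr::left_join(long, x$meta, by = "sample_id")
}

#' @rdname tidy.pca_result
#' @method glance pca_result
#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(component = paste0("PC", seq_along(x$explained)),
                 explained_fraction = x$explained)
}

#' Tidy a CoV table
#'
#' @param x a `cov_table`.
#' @param ... unused.
#' @return the per-individual summary tibble (`individual_id`, `age_days`,
#'   `period`, `mean_cov`, `median_cov`).
#' @method tidy cov_table
#' @export
tidy.cov_table <- function(x, ...) x$individuals
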