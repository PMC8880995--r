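#' Plot the transcriptome-wide inter-tissue CoV trajectory
#'
#' Mean (or median) CoV per individual against age on a log2 axis, split
#' by period — the signature divergence-then-convergence figure.
#'
#' @param object a `cov_table`.
#' @param statistic `"mean_cov"` or `"median_cov"`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot cov_table
#' @export
autoplot.cov_table <- function(object, statistic = "mean_cov", ...) {
  df <- object$individuals
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_days,
                                   y = .data[[statistic]],
                                   colour = .data$period)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", se = FALSE,
                         formula = y ~ x, linewidth = 0.6) +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "age (days, log2 scale)",
                  y = "inter-tissue CoV (per-individual mean)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot PCA scores coloured by tissue
#'
#' @param object a `pca_result`.
#' @param components two components to display (default PC1 vs PC2).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pca_result
#' @export
autoplot.pca_result <- function(object, components = c(1, 2), ...) {
  df <- tibble::tibble(
    x = object$scores[, components[1]],
    y = object$scores[, components[2]],
    tissue = object$meta$tissue, period = object$meta$period)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$tissue,
                                   shape = .data$period)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", components[1],
                  100 * object$explained[components[1]]),
      y = sprintf("PC%d (%.1f%%)", components[2],
                  100 * object$explained[components[2]])) +
    ggplot2::theme_minimal()
}

#' Plot a permutation null with the observed statistic
#'
#' @param object a `perm_test`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot perm_test
#' @export
autoplot.perm_test <- function(object, ...) {
  df <- tibble::tibble(null = object$null_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red",
                        linewidth = 0.8) +
    ggplot2::labs(x = object$statistic,
                  title = sprintf("observed vs %d permutations (p = %s)",
                                  object$n_rounds,
                                  format(object$p_value)),
                  y = "rounds") +
    ggplot2::theme_minimal()
}

#' Bar chart of reversal proportions per tissue
#'
#' @param proportions a [reversal_proportions()] tibble.
#' @return a ggplot.
#' @export
plot_reversal_proportions <- function(proportions) {
  df <- tidyr::pivot_longer(proportions, c("ud_pct", "du_pct"),
                            names_to = "direction", values_to = "pct")
  df$direction <- ifelse(df$direction == "ud_pct", "UD%", "DU%")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tissue, y = .data$pct,
                                   fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "reversal proportion", fill = NULL) +
    ggplot2::theme_minimal()
}
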