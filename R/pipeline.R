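#' Configuration for the full divergence-convergence pipeline
#'
#' All parameters of a pipeline run in one validated list. Can be
#' round-tripped through YAML with [read_pipeline_config()].
#'
#' @param matrix_path,meta_path input files for [read_expression()]
#'   (ignored when a dataset is passed to [run_pipeline()] directly).
#' @param period_boundary days separating development from ageing.
#' @param q_cutoff BH threshold used wherever significance is invoked
#'   (must lie in (0, 1)).
#' @param n_rounds permutation rounds for every permutation test (>= 1).
#' @param seed integer master seed; every randomised stage derives its
#'   seed from it.
#' @param normalise run [filter_low_expression()] +
#'   [log2_quantile_normalise()] first.
#' @param log_transform passed to [log2_quantile_normalise()]; set `FALSE`
#'   for data already on a log scale.
#' @param max_zero_fraction detection filter threshold.
#' @param stages character vector of enabled stages, a subset of
#'   `c("trends", "permutation", "reversal", "dico", "structure",
#'   "specificity", "hetero", "deconvolution")`.
#' @param signature optional [signature_matrix()] (or path to a TSV,
#'   genes x cell types); required only for the deconvolution stage.
#' @param out_dir optional directory: every stage table plus
#'   `summary.json` is written there.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix_path = NULL, meta_path = NULL,
                            period_boundary = 90, q_cutoff = 0.1,
                            n_rounds = 1000, seed = 1L, normalise = TRUE,
                            log_transform = TRUE, max_zero_fraction = 0.25,
                            stages = c("trends", "permutation", "reversal",
                                       "dico", "structure", "specificity",
                                       "hetero", "deconvolution"),
                            signature = NULL, out_dir = NULL) {
  if (q_cutoff <= 0 || q_cutoff >= 1) abort("q_cutoff must be in (0, 1)")
  if (n_rounds < 1) abort("n_rounds must be at least 1")
  known <- c("trends", "permutation", "reversal", "dico", "structure",
             "specificity", "hetero", "deconvolution")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) abort(paste0("unknown stage(s): ",
                                    paste(bad, collapse = ", ")))
  structure(list(
    matrix_path = matrix_path, meta_path = meta_path,
    period_boundary = period_boundary, q_cutoff = q_cutoff,
    n_rounds = as.integer(n_rounds), seed = as.integer(seed),
    normalise = normalise, log_transform = log_transform,
    max_zero_fraction = max_zero_fraction, stages = stages,
    signature = signature, out_dir = out_dir
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the
#' [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) abort(paste0("unknown config key(s): ",
                                    paste(bad, collapse = ", ")))
  do.call(pipeline_config, vals)
}

#' Run the full divergence-convergence analysis
#'
#' Executes the enabled stages in dependency order on a dataset (passed
#' directly or read from the configured paths): preprocessing, per-gene
#' age trends, dependence-preserving permutation tests, reversal
#' classification and tests, the CoV divergence-convergence machinery
#' with its permutation test and jackknife, PCA structure, tissue
#' specificity with identity-loss and enrichment tests,
#' heteroscedasticity checks, and (when a signature is supplied)
#' deconvolution. Every stage table is returned (and written to
#' `out_dir` when set) together with a machine-readable summary of the
#' headline statistics; reruns under the same config and data are
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param dataset optional [expr_dataset()]; otherwise read from the
#'   config paths.
#' @return a list of class `dico_pipeline` with elements `dataset`,
#'   `trends`, `permutation`, `reversal`, `dico`, `structure`,
#'   `specificity`, `hetero`, `deconvolution` (stages not run are `NULL`)
#'   and `summary` (named list).
#' @export
run_pipeline <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(dataset)) {
    if (is.null(config$matrix_path) || is.null(config$meta_path)) {
      abort("either a dataset or matrix_path + meta_path is required")
    }
    dataset <- read_expression(config$matrix_path, config$meta_path,
                               config$period_boundary)
  }
  seed <- config$seed
  qc <- config$q_cutoff
  B <- config$n_rounds
  on_stage <- function(s) s %in% config$stages
  out <- list()
  summary <- list(seed = seed, n_rounds = B, q_cutoff = qc,
                  n_genes_input = nrow(dataset$values),
                  n_samples = ncol(dataset$values))

  if (config$normalise) {
    dataset <- filter_low_expression(dataset, config$max_zero_fraction)
    dataset <- log2_quantile_normalise(dataset, config$log_transform)
  }
  summary$n_genes_retained <- nrow(dataset$values)
  out$dataset <- dataset

  trends <- NULL
  if (on_stage("trends") || on_stage("reversal") ||
      on_stage("specificity")) {
    trends <- age_trend_table(dataset)
    out$trends <- trends
    sig_counts <- trends |>
      dplyr::filter(!is.na(.data$q), .data$q < qc) |>
      dplyr::count(.data$tissue, .data$period)
    summary$n_significant_age_genes <- setNames(
      as.list(sig_counts$n), paste(sig_counts$tissue, sig_counts$period,
                                   sep = "_"))
  }

  if (on_stage("permutation")) {
    perm <- list()
    for (per in c("development", "ageing")) {
      perm[[paste0("similarity_", per)]] <-
        test_cross_tissue_similarity(dataset, per, B, seed + 11L)
      for (dir in c("up", "down")) {
        perm[[paste0("overlap_", dir, "_", per)]] <-
          test_shared_overlap(dataset, per, dir, use_significance = FALSE,
                              n_rounds = B, seed = seed + 13L)
      }
    }
    out$permutation <- perm
    summary$similarity_min_p <- min(vapply(
      grep("^similarity", names(perm), value = TRUE),
      function(k) min(perm[[k]]$p_value), numeric(1)))
    summary$overlap_p <- lapply(
      grep("^overlap", names(perm), value = TRUE),
      function(k) perm[[k]]$p_value) |>
      setNames(grep("^overlap", names(perm), value = TRUE))
  }

  if (on_stage("reversal")) {
    rt <- reversal_table(trends)
    props <- reversal_proportions(rt)
    rev_tests <- lapply(tissues_of(dataset), function(t) {
      test_reversal(dataset, t, n_rounds = B, seed = seed + 17L)
    })
    names(rev_tests) <- tissues_of(dataset)
    out$reversal <- list(table = rt, proportions = props,
                         tests = rev_tests)
    summary$ud_pct <- setNames(as.list(props$ud_pct), props$tissue)
    summary$du_pct <- setNames(as.list(props$du_pct), props$tissue)
    summary$ud_test_p <- lapply(rev_tests, function(x) x$ud$p_value)
    summary$du_test_p <- lapply(rev_tests, function(x) x$du$p_value)
  }

  if (on_stage("dico")) {
    cov <- compute_cov(dataset)
    dev_tr <- cov_age_trends(cov, "development")
    age_tr <- cov_age_trends(cov, "ageing")
    calls <- call_dico(dev_tr$gene_trends, age_tr$gene_trends)
    calls_sig <- call_dico(dev_tr$gene_trends, age_tr$gene_trends,
                           q_cutoff = qc)
    dico_test <- test_dico(dataset, n_rounds = B, seed = seed + 19L)
    jk_dev <- jackknife_ratio(cov, "development", qc)
    jk_age <- jackknife_ratio(cov, "ageing", qc)
    pw <- pairwise_tissue_correlation(dataset)
    out$dico <- list(cov = cov, dev_trends = dev_tr, ageing_trends = age_tr,
                     calls = calls, calls_significant = calls_sig,
                     test = dico_test, jackknife_development = jk_dev,
                     jackknife_ageing = jk_age, pairwise = pw)
    summ_tr <- dplyr::bind_rows(dev_tr$summary, age_tr$summary)
    summary$mean_cov_rho <- setNames(
      as.list(summ_tr$rho[summ_tr$statistic == "mean_cov"]),
      summ_tr$period[summ_tr$statistic == "mean_cov"])
    summary$n_dico <- sum(calls$is_dico)
    summary$n_dev_divergent <- sum(calls$dev_class == "divergent")
    summary$n_significant_divergent <- list(
      development = unname(jk_dev$full$n_divergent),
      ageing = unname(jk_age$full$n_divergent))
    summary$n_significant_convergent <- list(
      development = unname(jk_dev$full$n_convergent),
      ageing = unname(jk_age$full$n_convergent))
    summary$dico_test_p <- dico_test$p_value
    summary$jackknife_ratio_range <- list(
      development = unname(jk_dev$range), ageing = unname(jk_age$range))
  }

  if (on_stage("structure")) {
    pca <- pca_scores(dataset)
    pcd <- pc_distance_trend(pca)
    tfree <- remove_tissue_effect(dataset)
    out$structure <- list(pca = pca, distance = pcd,
                          tissue_free = tfree)
    summary$pc_explained <- head(pca$explained, 4)
    summary$pc_distance_rho <- setNames(as.list(pcd$trends$rho),
                                        pcd$trends$period)
  }

  if (on_stage("specificity")) {
    spec_tab <- call_tissue_specific(dataset)
    nl <- native_loss_test(dataset, spec_tab)
    out$specificity <- list(table = spec_tab, native_loss = nl)
    summary$n_tissue_specific <- spec_tab |>
      dplyr::filter(.data$is_specific) |>
      dplyr::count(.data$assigned_tissue) |>
      (\(d) setNames(as.list(d$n), d$assigned_tissue))()
    summary$native_loss_or <- nl$odds_ratio
    summary$native_loss_p <- nl$p
    if (on_stage("dico")) {
      nl_dico <- native_loss_test(
        dataset, spec_tab,
        gene_subset = out$dico$calls$gene[out$dico$calls$is_dico])
      enr <- enrichment_tests(spec_tab, out$dico$calls,
                              out$reversal$table)
      out$specificity$native_loss_dico <- nl_dico
      out$specificity$enrichment <- enr
      summary$native_loss_dico_or <- nl_dico$odds_ratio
      summary$dico_enrichment_or <-
        enr$odds_ratio[enr$test == "specific_in_dico"][1]
      summary$dico_enrichment_p <- enr$p[enr$test == "specific_in_dico"][1]
    }
  }

  if (on_stage("hetero") && on_stage("dico")) {
    het_genes <- out$dico$calls$gene[out$dico$calls$is_dico |
                                       out$dico$calls$is_didi]
    het <- hetero_table(dataset, genes = het_genes)
    ks_abs <- compare_dico_didi(het, out$dico$calls, "abs_resid_rho")
    ks_ncv <- compare_dico_didi(het, out$dico$calls, "ncv_stat")
    out$hetero <- list(table = het, ks_abs_resid = ks_abs,
                       ks_ncv = ks_ncv)
    summary$hetero_ks_min_p <- min(c(ks_abs$p, ks_ncv$p))
  }

  if (on_stage("deconvolution") && !is.null(config$signature)) {
    sig <- config$signature
    if (is.character(sig)) {
      tb <- read_table_tsv(sig)
      v <- as.matrix(tb[, -1]); rownames(v) <- tb[[1]]
      sig <- signature_matrix(v)
    }
    fit <- fit_deconvolution(dataset, sig)
    ctr <- coefficient_age_trend(fit)
    out$deconvolution <- list(fit = fit, trends = ctr)
    summary$deconv_trend_rho <- setNames(
      as.list(ctr$rho), paste(ctr$cell_type, ctr$period, sep = "_"))
  }

  out$summary <- summary
  class(out) <- "dico_pipeline"
  if (!is.null(config$out_dir)) write_pipeline(out, config$out_dir)
  out
}

# write every tabular stage output plus the JSON summary
write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, name) write_table(x, file.path(out_dir,
                                                   paste0(name, ".tsv")))
  if (!is.null(result$trends)) wt(result$trends, "age_trends")
  if (!is.null(result$reversal)) {
    wt(result$reversal$table, "reversal")
    wt(result$reversal$proportions, "reversal_proportions")
  }
  if (!is.null(result$dico)) {
    wt(result$dico$cov$cov, "cov_matrix")
    wt(result$dico$calls, "dico_calls")
    wt(dplyr::bind_rows(result$dico$dev_trends$gene_trends,
                        result$dico$ageing_trends$gene_trends),
       "cov_trends")
  }
  if (!is.null(result$specificity)) wt(result$specificity$table,
                                       "tissue_specificity")
  if (!is.null(result$hetero)) wt(result$hetero$table, "hetero")
  jsonlite::write_json(result$summary,
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.dico_pipeline <- function(x, ...) {
  cat("<dico_pipeline> stages run: ",
      paste(setdiff(names(x)[!vapply(x, is.null, logical(1))],
                    c("dataset", "summary")), collapse = ", "), "\n",
      sep = "")
  if (!is.null(x$summary$n_dico)) {
    cat("  DiCo genes: ", x$summary$n_dico, " of ",
        x$summary$n_dev_divergent, " developmentally divergent\n",
        sep = "")
  }
  invisible(x)
}
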