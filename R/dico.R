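#' Inter-tissue coefficient of variation per gene and individual
#'
#' For every individual possessing all tissues, the CoV of each gene is the
#' sample standard deviation of its normalised expression across that
#' individual's tissues divided by the mean. Individuals missing a tissue
#' are dropped with a message (as when a study lacks one tissue for one
#' animal); genes whose across-tissue mean is 0 for an individual get `NA`
#' there and are excluded from that individual's mean CoV.
#'
#' @param ds a normalised [expr_dataset()].
#' @return an object of class `cov_table`: list with `cov` (gene x
#'   individual matrix), `individuals` (tibble: `individual_id`,
#'   `age_days`, `period`, `mean_cov`, `median_cov`).
#' @export
compute_cov <- function(ds) {
  stopifnot(inherits(ds, "expr_dataset"))
  tiss <- tissues_of(ds)
  m <- ds$meta
  counts <- table(m$individual_id)
  complete <- names(counts)[counts == length(tiss)]
  dropped <- setdiff(unique(m$individual_id), complete)
  if (length(dropped) > 0) {
    message("dropping individual(s) missing a tissue: ",
            paste(dropped, collapse = ", "))
  }
  ind <- m[!duplicated(m$individual_id) & m$individual_id %in% complete, ,
           drop = FALSE]
  ind <- ind[order(ind$age_days, ind$individual_id), , drop = FALSE]
  covm <- vapply(ind$individual_id, function(i) {
    cols <- m$sample_id[m$individual_id == i]
    v <- ds$values[, cols, drop = FALSE]
    mu <- rowMeans(v)
    s <- sqrt(rowSums((v - mu)^2) / (ncol(v) - 1))
    out <- s / mu
    out[mu == 0] <- NA_real_
    out
  }, numeric(nrow(ds$values)))
  rownames(covm) <- rownames(ds$values)
  individuals <- tibble::tibble(
    individual_id = ind$individual_id, age_days = ind$age_days,
    period = ind$period,
    mean_cov = colMeans(covm, na.rm = TRUE),
    median_cov = apply(covm, 2L, median, na.rm = TRUE)
  )
  structure(list(cov = covm, individuals = individuals),
            class = "cov_table")
}

#' @export
print.cov_table <- function(x, ...) {
  cat("<cov_table> ", nrow(x$cov), " genes x ", ncol(x$cov),
      " individuals\n", sep = "")
  invisible(x)
}

#' CoV-age trends: per gene and transcriptome-wide
#'
#' Spearman correlation between each gene's inter-tissue CoV and individual
#' age within one period (BH-adjusted across genes), plus the dataset-level
#' trends of the mean and median CoV across genes. A positive per-gene
#' trend is "divergent", a negative one "convergent".
#'
#' @param cov a [compute_cov()] result.
#' @param period `"development"` or `"ageing"`.
#' @param min_individuals genes with fewer non-missing CoV values than this
#'   are left `NA`.
#' @return a list with `gene_trends` (tibble: `gene`, `period`, `rho`,
#'   `p`, `q`) and `summary` (tibble: `period`, `statistic`
#'   (`"mean_cov"`/`"median_cov"`), `rho`, `p`).
#' @export
cov_age_trends <- function(cov, period, min_individuals = 3) {
  stopifnot(inherits(cov, "cov_table"))
  sel <- cov$individuals$period == period
  if (sum(sel) < min_individuals) abort("too few individuals in period")
  ages <- cov$individuals$age_days[sel]
  mat <- cov$cov[, sel, drop = FALSE]
  complete <- !apply(mat, 1L, anyNA)
  rho <- p <- rep(NA_real_, nrow(mat))
  if (any(complete)) {
    st <- spearman_matrix(mat[complete, , drop = FALSE], ages)
    rho[complete] <- st$rho
    p[complete] <- st$p
  }
  for (g in which(!complete)) {
    ok <- !is.na(mat[g, ])
    if (sum(ok) >= min_individuals) {
      st <- spearman_matrix(mat[g, ok, drop = FALSE], ages[ok])
      rho[g] <- st$rho
      p[g] <- st$p
    }
  }
  gene_trends <- tibble::tibble(gene = rownames(mat), period = period,
                                rho = rho, p = p, q = bh_adjust(p))
  summ <- purrr::map_dfr(c("mean_cov", "median_cov"), function(stat) {
    st <- spearman_age_trend(cov$individuals[[stat]][sel], ages)
    tibble::tibble(period = period, statistic = stat, rho = st$rho,
                   p = st$p)
  })
  list(gene_trends = gene_trends, summary = summ)
}

#' Call divergent/convergent classes and DiCo genes
#'
#' A gene is "divergent" in a period when its CoV-age trend is positive and
#' "convergent" when negative; DiCo = divergent in development and
#' convergent in ageing. By default no significance level is used; with
#' `q_cutoff` set, only trends with BH q below the cutoff count and the
#' rest are `"undefined"`.
#'
#' @param dev_trends,ageing_trends `gene_trends` tibbles from
#'   [cov_age_trends()] for the two periods.
#' @param q_cutoff optional BH q threshold for the significant-only
#'   variant.
#' @return a `DiCoCall` tibble: `gene`, `dev_class`, `ageing_class`,
#'   `is_dico`, plus `is_didi` for convenience.
#' @export
call_dico <- function(dev_trends, ageing_trends, q_cutoff = NULL) {
  classify <- function(rho, q) {
    cls <- dplyr::case_when(
      is.na(rho) | rho == 0 ~ "undefined",
      rho > 0 ~ "divergent",
      TRUE ~ "convergent"
    )
    if (!is.null(q_cutoff)) cls[is.na(q) | q >= q_cutoff] <- "undefined"
    cls
  }
  stopifnot(identical(dev_trends$gene, ageing_trends$gene))
  dev_class <- classify(dev_trends$rho, dev_trends$q)
  ageing_class <- classify(ageing_trends$rho, ageing_trends$q)
  tibble::tibble(
    gene = dev_trends$gene, dev_class = dev_class,
    ageing_class = ageing_class,
    is_dico = dev_class == "divergent" & ageing_class == "convergent",
    is_didi = dev_class == "divergent" & ageing_class == "divergent"
  )
}

#' Ageing-only permutation test of the DiCo proportion
#'
#' Fixes the developmentally divergent gene set from the observed data
#' (no significance cutoff), then permutes individual ages among
#' ageing-period individuals and recomputes the fraction of that set whose
#' ageing CoV trend is convergent ("DiCo%") in each round. One-sided for
#' excess convergence.
#'
#' @param ds a normalised [expr_dataset()].
#' @param n_rounds,seed permutation rounds and seed.
#' @return a `perm_test`.
#' @export
test_dico <- function(ds, n_rounds = 1000, seed = 1L) {
  cov <- compute_cov(ds)
  dev <- cov_age_trends(cov, "development")$gene_trends
  div_dev <- !is.na(dev$rho) & dev$rho > 0
  sel <- cov$individuals$period == "ageing"
  ages <- setNames(cov$individuals$age_days[sel],
                   cov$individuals$individual_id[sel])
  mat <- cov$cov[div_dev, sel, drop = FALSE]
  complete <- !apply(mat, 1L, anyNA)
  sr <- std_rank_matrix(mat[complete, , drop = FALSE])
  dico_pct <- function(a) {
    rho <- as.vector(sr %*% std_ranks(a))
    ok <- !is.na(rho) & rho != 0
    sum(rho[ok] < 0) / sum(ok)
  }
  observed <- dico_pct(ages)
  set.seed(seed)
  null_vals <- numeric(n_rounds)
  for (r in seq_len(n_rounds)) {
    null_vals[r] <- dico_pct(sample(ages))
  }
  perm_test(observed, null_vals, "greater", seed, "DiCo%")
}

#' Jackknife range of the divergent/convergent gene ratio
#'
#' Leaves out one individual of the period at a time and recomputes the
#' numbers of significantly divergent and convergent genes (BH
#' q < `q_cutoff` on the CoV-age trend) and their ratio. Iterations with a
#' zero count are flagged invalid and excluded from the reported range
#' (mirroring the loss of power when the youngest adults are dropped).
#'
#' @param ds a normalised [expr_dataset()] (or a `cov_table`).
#' @param period period to jackknife.
#' @param q_cutoff BH threshold (default 0.1).
#' @return a list with `pseudovalues` (tibble: `left_out`, `n_divergent`,
#'   `n_convergent`, `ratio` (div/conv), `log2_ratio`, `valid`), `full`
#'   (same statistics on all individuals) and `range` (range of valid
#'   ratios).
#' @export
jackknife_ratio <- function(ds, period, q_cutoff = 0.1) {
  cov <- if (inherits(ds, "cov_table")) ds else compute_cov(ds)
  sel <- which(cov$individuals$period == period)
  if (length(sel) < 3) abort("need at least 3 individuals in period")
  count_ratio <- function(cols) {
    ages <- cov$individuals$age_days[cols]
    mat <- cov$cov[, cols, drop = FALSE]
    complete <- !apply(mat, 1L, anyNA)
    st <- spearman_matrix(mat[complete, , drop = FALSE], ages)
    q <- bh_adjust(st$p)
    sig <- !is.na(q) & q < q_cutoff
    c(n_div = sum(sig & st$rho > 0), n_conv = sum(sig & st$rho < 0))
  }
  full_counts <- count_ratio(sel)
  pseudo <- purrr::map_dfr(seq_along(sel), function(i) {
    cts <- count_ratio(sel[-i])
    tibble::tibble(left_out = cov$individuals$individual_id[sel[i]],
                   n_divergent = cts["n_div"], n_convergent = cts["n_conv"])
  })
  pseudo$valid <- pseudo$n_divergent > 0 & pseudo$n_convergent > 0
  if (any(!pseudo$valid)) {
    warn("iteration(s) with zero significant genes excluded from range")
  }
  pseudo$ratio <- ifelse(pseudo$valid,
                         pseudo$n_divergent / pseudo$n_convergent, NA_real_)
  pseudo$log2_ratio <- log2(pseudo$ratio)
  full <- tibble::tibble(
    n_divergent = full_counts["n_div"], n_convergent = full_counts["n_conv"],
    ratio = ifelse(full_counts["n_conv"] > 0,
                   full_counts["n_div"] / full_counts["n_conv"], NA_real_))
  list(pseudovalues = pseudo, full = full,
       range = if (any(pseudo$valid)) range(pseudo$ratio[pseudo$valid])
       else c(NA_real_, NA_real_))
}

#' Per-individual pairwise inter-tissue expression correlations
#'
#' Spearman correlation between the expression profiles (all genes) of
#' every tissue pair of the same individual, their per-individual mean and
#' median, and the age trend of each pair (and of the mean/median) within
#' each period. Rising correlations mean the tissues' transcriptomes are
#' converging.
#'
#' @param ds a normalised [expr_dataset()].
#' @return a list with `pairs` (tibble: `individual_id`, `age_days`,
#'   `period`, `tissue1`, `tissue2`, `rho`), `per_individual` (tibble with
#'   `mean_rho`, `median_rho`) and `trends` (tibble: `period`, `tissue1`,
#'   `tissue2` (or `"mean"`/`"median"` summaries), `rho`, `p`).
#' @export
pairwise_tissue_correlation <- function(ds) {
  stopifnot(inherits(ds, "expr_dataset"))
  m <- ds$meta
  inds <- unique(m$individual_id)
  pairs <- purrr::map_dfr(inds, function(i) {
    mi <- m[m$individual_id == i, , drop = FALSE]
    if (nrow(mi) < 2) return(NULL)
    mi <- mi[order(mi$tissue), , drop = FALSE]
    rmat <- apply(ds$values[, mi$sample_id, drop = FALSE], 2L, rank)
    cc <- cor(rmat)
    cmb <- utils::combn(seq_len(nrow(mi)), 2)
    tibble::tibble(
      individual_id = i, age_days = mi$age_days[1], period = mi$period[1],
      tissue1 = mi$tissue[cmb[1, ]], tissue2 = mi$tissue[cmb[2, ]],
      rho = cc[t(cmb)])
  })
  per_ind <- pairs |>
    dplyr::group_by(.data$individual_id, .data$age_days, .data$period) |>
    dplyr::summarise(mean_rho = mean(.data$rho),
                     median_rho = median(.data$rho), .groups = "drop")
  trends <- dplyr::bind_rows(
    pairs |>
      dplyr::group_by(.data$period, .data$tissue1, .data$tissue2) |>
      dplyr::filter(dplyr::n() >= 3) |>
      dplyr::summarise(trend_or_na(.data$rho, .data$age_days),
                       .groups = "drop"),
    per_ind |>
      tidyr::pivot_longer(c("mean_rho", "median_rho"),
                          names_to = "tissue1", values_to = "value") |>
      dplyr::group_by(.data$period, .data$tissue1) |>
      dplyr::filter(dplyr::n() >= 3) |>
      dplyr::summarise(trend_or_na(.data$value, .data$age_days),
                       .groups = "drop") |>
      dplyr::mutate(tissue1 = sub("_rho$", "", .data$tissue1),
                    tissue2 = "summary")
  )
  list(pairs = pairs, per_individual = per_ind, trends = trends)
}
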