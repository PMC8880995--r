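#' Specification for the synthetic multi-tissue lifespan generator
#'
#' Describes a synthetic experiment mimicking the structure of a
#' multi-tissue whole-lifespan bulk transcriptome study: a handful of
#' tissues sampled from the same individuals, ages spanning postnatal
#' development and ageing, genes planted with divergence-convergence
#' (DiCo), lifelong-divergence (DiDi), expression-reversal (UD/DU) or flat
#' trajectories, tissue-specific baseline elevation, and identity-loss
#' structure in the ageing slopes of tissue-specific genes.
#'
#' All planted trends are linear in log2(age). DiCo/DiDi genes pivot at the
#' youngest age so inter-tissue spread grows through development; reversal
#' genes pivot at the period boundary so their tissue profiles meet at the
#' boundary (convergent-then-divergent in CoV space), which keeps the
#' expression-reversal classes from masquerading as DiCo.
#'
#' @param n_genes number of genes.
#' @param tissues character vector of tissue labels (default 4 tissues).
#' @param dev_ages,ageing_ages ages in days of the development and ageing
#'   individuals (defaults: 7 ages 2-61 d and 9 ages 93-904 d).
#' @param fractions named proportions over classes
#'   `c(DiCo=, DiDi=, UD=, DU=, flat=)`; must sum to at most 1, the
#'   remainder is flat.
#' @param tissue_specific_fraction fraction of genes given a native-tissue
#'   baseline elevation of `3 * effect_size`.
#' @param effect_size slope magnitude on log2(age), in expression units.
#' @param noise_sd standard deviation of the i.i.d. Gaussian noise.
#' @param identity_loss_odds odds that a tissue-specific gene's planted
#'   largest ageing slope is "identity-losing" (down in native tissue or up
#'   in a non-native tissue) rather than the reverse. 1 = no association.
#' @param dico_specific_odds relative odds that the tissue-specific flag
#'   lands on a DiCo-class gene (1 = specificity independent of class).
#' @param hetero_strength age-proportional noise mode: sample noise sd is
#'   `noise_sd * (1 + hetero_strength * (l - l_min)/(l_max - l_min))` with
#'   `l = log2(age)`; 0 (default) is homoscedastic.
#' @param period_boundary boundary between periods, days.
#' @param baseline_range range of per-gene baseline expression (log2-like
#'   scale units).
#' @param seed integer seed used by [generate_dataset()] and
#'   [generate_null_dataset()].
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 1000,
                           tissues = c("cortex", "liver", "lung", "muscle"),
                           dev_ages = c(2, 5, 9, 16, 26, 42, 61),
                           ageing_ages = c(93, 131, 185, 261, 368, 519, 642,
                                           766, 904),
                           fractions = c(DiCo = 0.25, DiDi = 0.2, UD = 0.175,
                                         DU = 0.175, flat = 0.2),
                           tissue_specific_fraction = 0.1,
                           effect_size = 1,
                           noise_sd = effect_size / 3,
                           identity_loss_odds = 1,
                           dico_specific_odds = 1,
                           hetero_strength = 0,
                           period_boundary = 90,
                           baseline_range = c(8, 12),
                           seed = 1L) {
  fr <- c(DiCo = 0, DiDi = 0, UD = 0, DU = 0, flat = 0)
  fr[names(fractions)] <- fractions
  if (any(fr < 0) || sum(fr) > 1 + 1e-12) {
    abort("class fractions must be non-negative and sum to at most 1")
  }
  fr["flat"] <- fr["flat"] + (1 - sum(fr))
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (any(dev_ages >= period_boundary) || any(ageing_ages < period_boundary)) {
    abort("dev_ages must fall below and ageing_ages at/above the boundary")
  }
  structure(list(
    n_genes = n_genes, tissues = tissues, dev_ages = dev_ages,
    ageing_ages = ageing_ages, fractions = fr,
    tissue_specific_fraction = tissue_specific_fraction,
    effect_size = effect_size, noise_sd = noise_sd,
    identity_loss_odds = identity_loss_odds,
    dico_specific_odds = dico_specific_odds,
    hetero_strength = hetero_strength,
    period_boundary = period_boundary,
    baseline_range = baseline_range, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# sample metadata grid for a synthetic spec: one individual per age,
# every tissue sampled from every individual
synthetic_meta <- function(spec) {
  ages <- c(spec$dev_ages, spec$ageing_ages)
  ind <- sprintf("ind%02d", seq_along(ages))
  grid <- expand.grid(individual_id = ind, tissue = spec$tissues,
                      stringsAsFactors = FALSE)
  grid$age_days <- ages[match(grid$individual_id, ind)]
  grid$sample_id <- paste(grid$individual_id, grid$tissue, sep = "_")
  tibble::as_tibble(grid[, c("sample_id", "individual_id", "tissue",
                             "age_days")])
}

#' Generate a synthetic lifespan dataset with planted truth
#'
#' Each gene's expectation is piecewise linear in log2(age), continuous at
#' the period boundary, with class-determined slope structure (see
#' [synthetic_spec()]); i.i.d. Gaussian noise is added and values are
#' floored at zero.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed (defaults to `spec$seed`).
#' @return a list with elements `dataset` (an [expr_dataset()]) and `truth`
#'   (a tibble with one row per gene: `gene`, `class`, `native_tissue`,
#'   `loss_config`, `outlier_tissue`, `trend_sign`, and list-columns
#'   `dev_slopes` / `ageing_slopes` of per-tissue slopes).
#' @export
generate_dataset <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  n <- spec$n_genes
  tiss <- spec$tissues
  nt <- length(tiss)
  e <- spec$effect_size
  meta <- synthetic_meta(spec)
  l <- log2(meta$age_days)
  l_min <- log2(min(spec$dev_ages))
  l_bnd <- log2(spec$period_boundary)
  l_max <- log2(max(spec$ageing_ages))
  L1 <- l_bnd - l_min

  counts <- floor(spec$fractions * n)
  counts["flat"] <- counts["flat"] + (n - sum(counts))
  classes <- sample(rep(names(counts), counts))
  genes <- sprintf("g%05d", seq_len(n))
  baseline <- runif(n, spec$baseline_range[1], spec$baseline_range[2])

  dev_slope <- matrix(0, n, nt, dimnames = list(genes, tiss))
  age_slope <- matrix(0, n, nt, dimnames = list(genes, tiss))
  # offset of each tissue at the boundary relative to baseline
  offset <- matrix(0, n, nt, dimnames = list(genes, tiss))

  outlier <- rep(NA_character_, n)
  trend_sign <- rep(NA_real_, n)

  idx_out <- classes %in% c("DiCo", "DiDi")
  outlier[idx_out] <- sample(tiss, sum(idx_out), replace = TRUE)
  trend_sign[idx_out] <- sample(c(-1, 1), sum(idx_out), replace = TRUE)
  for (g in which(idx_out)) {
    o <- outlier[g]
    s <- trend_sign[g] * e
    dev_slope[g, o] <- s
    offset[g, o] <- s * L1
    age_slope[g, o] <- if (classes[g] == "DiCo") {
      -0.9 * s * L1 / (l_max - l_bnd)  # return 90% of the way back
    } else {
      0.25 * s                          # keep departing, quarter rate
    }
  }

  idx_rev <- classes %in% c("UD", "DU")
  trend_sign[idx_rev] <- ifelse(classes[idx_rev] == "UD", 1, -1)
  n_rev <- sum(idx_rev)
  if (n_rev > 0) {
    het_dev <- matrix(runif(n_rev * nt, -0.3, 0.3), n_rev, nt)
    het_age <- matrix(runif(n_rev * nt, -0.15, 0.15), n_rev, nt)
    s <- trend_sign[idx_rev] * e
    dev_slope[idx_rev, ] <- s * (1 + het_dev)
    age_slope[idx_rev, ] <- -s * (1 + het_age)
    # boundary pivot: profiles meet at the boundary, no offset
  }

  # tissue-specific flags: weighted draw, optional coupling with DiCo
  n_spec <- round(spec$tissue_specific_fraction * n)
  native <- rep(NA_character_, n)
  loss_config <- rep(NA_character_, n)
  if (n_spec > 0) {
    w <- ifelse(classes == "DiCo", spec$dico_specific_odds, 1)
    spec_idx <- sample.int(n, n_spec, prob = w)
    native[spec_idx] <- sample(tiss, n_spec, replace = TRUE)
    e_loss <- 2.5 * e
    p_loss <- spec$identity_loss_odds / (1 + spec$identity_loss_odds)
    for (g in spec_idx) {
      nat <- native[g]
      offset[g, nat] <- offset[g, nat] + 3 * e
      is_loss <- runif(1) < p_loss
      in_native <- runif(1) < 0.5
      target <- if (in_native) nat else sample(setdiff(tiss, nat), 1)
      sign_l <- if (is_loss) (if (in_native) -1 else 1) else
        (if (in_native) 1 else -1)
      age_slope[g, target] <- age_slope[g, target] + sign_l * e_loss
      loss_config[g] <- paste0(if (in_native) "native_" else "foreign_",
                               if (sign_l > 0) "up" else "down")
    }
    # the elevation must hold throughout life, so specific genes keep a
    # constant native offset in development too (their class slopes are
    # unchanged)
  }

  is_dev <- meta$age_days < spec$period_boundary
  ti <- match(meta$tissue, tiss)
  mu <- matrix(0, n, nrow(meta), dimnames = list(genes, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    t_j <- ti[j]
    dl <- l[j] - l_bnd
    mu[, j] <- baseline + offset[, t_j] +
      if (is_dev[j]) dev_slope[, t_j] * dl else age_slope[, t_j] * dl
  }

  if (spec$noise_sd > 0) {
    sd_j <- spec$noise_sd *
      (1 + spec$hetero_strength * (l - l_min) / (l_max - l_min))
    noise <- matrix(rnorm(n * nrow(meta)), n, nrow(meta))
    noise <- sweep(noise, 2L, sd_j, `*`)
    mu <- mu + noise
  }
  mu <- pmax(mu, 0)

  truth <- tibble::tibble(
    gene = genes, class = classes, native_tissue = native,
    loss_config = loss_config, outlier_tissue = outlier,
    trend_sign = trend_sign,
    dev_slopes = lapply(seq_len(n), function(g) dev_slope[g, ]),
    ageing_slopes = lapply(seq_len(n), function(g) age_slope[g, ])
  )
  list(dataset = expr_dataset(mu, meta, spec$period_boundary), truth = truth)
}

#' Generate a null dataset with no age effect
#'
#' Gene values are baseline plus noise only; every expression-age
#' association is null by construction. Used to calibrate the permutation
#' tests.
#'
#' @inheritParams generate_dataset
#' @return an [expr_dataset()].
#' @export
generate_null_dataset <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  meta <- synthetic_meta(spec)
  n <- spec$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  baseline <- runif(n, spec$baseline_range[1], spec$baseline_range[2])
  mu <- matrix(baseline, n, nrow(meta)) +
    matrix(rnorm(n * nrow(meta), sd = max(spec$noise_sd, 1e-12)),
           n, nrow(meta))
  dimnames(mu) <- list(genes, meta$sample_id)
  expr_dataset(pmax(mu, 0), meta, spec$period_boundary)
}

#' Cell-type signature matrix
#'
#' Genes x cell-types matrix of mean expression per cell type, with a
#' companion cell-type table carrying the tissue and reference age-group
#' label of each cell type.
#'
#' @param values non-negative numeric matrix, genes x cell types, with
#'   dimnames.
#' @param celltypes optional tibble with columns `cell_type`, `tissue`,
#'   `age_group`; defaults to one tissue `"bulk"`, age group `"ref"`.
#' @return an object of class `signature_matrix`.
#' @export
signature_matrix <- function(values, celltypes = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) abort("signature needs cell-type colnames")
  if (anyDuplicated(colnames(values))) abort("duplicate cell-type ids")
  if (any(values < 0)) abort("signature values must be non-negative")
  if (is.null(celltypes)) {
    celltypes <- tibble::tibble(cell_type = colnames(values),
                                tissue = "bulk", age_group = "ref")
  }
  structure(list(values = values, celltypes = tibble::as_tibble(celltypes)),
            class = "signature_matrix")
}

#' Simulate a random cell-type signature matrix
#'
#' Independent non-negative profiles per cell type; full column rank with
#' probability one, so deconvolution is identifiable.
#'
#' @param n_genes number of genes.
#' @param cell_types character vector of cell-type names.
#' @param tissue tissue label recorded for all cell types.
#' @param seed integer seed.
#' @return a [signature_matrix()].
#' @export
simulate_signature <- function(n_genes = 500,
                               cell_types = paste0("ct", 1:6),
                               tissue = "bulk", seed = 1L) {
  set.seed(seed)
  v <- matrix(runif(n_genes * length(cell_types), 0, 10),
              n_genes, length(cell_types),
              dimnames = list(sprintf("g%05d", seq_len(n_genes)), cell_types))
  signature_matrix(v, tibble::tibble(cell_type = cell_types, tissue = tissue,
                                     age_group = "ref"))
}

#' Simulate bulk mixtures of known cell-type proportions
#'
#' Each bulk profile is `signature %*% proportions + noise`; the known
#' proportions are the ground truth for deconvolution tests.
#'
#' @param signature a [signature_matrix()] or plain matrix.
#' @param proportions individuals x cell-types matrix of non-negative
#'   proportions, each row summing to 1 (tolerance 1e-8).
#' @param noise_sd Gaussian noise sd added to the mixtures.
#' @param ages optional ages (days) for the mixture individuals; defaults
#'   to `seq_len(nrow(proportions))`.
#' @param seed integer seed.
#' @return an [expr_dataset()] of bulk profiles (tissue label `"bulk"`).
#' @export
generate_mixtures <- function(signature, proportions, noise_sd = 0,
                              ages = NULL, seed = 1L) {
  sig <- if (inherits(signature, "signature_matrix")) signature$values else
    as.matrix(signature)
  proportions <- as.matrix(proportions)
  if (ncol(proportions) != ncol(sig)) {
    abort("proportions must have one column per signature cell type")
  }
  if (any(abs(rowSums(proportions) - 1) > 1e-8)) {
    abort("each proportions row must sum to 1")
  }
  set.seed(seed)
  bulk <- sig %*% t(proportions)
  if (noise_sd > 0) {
    bulk <- bulk + matrix(rnorm(length(bulk), sd = noise_sd), nrow(bulk))
  }
  n_ind <- nrow(proportions)
  ind <- sprintf("mix%03d", seq_len(n_ind))
  colnames(bulk) <- paste0(ind, "_bulk")
  if (is.null(ages)) ages <- seq_len(n_ind)
  meta <- tibble::tibble(sample_id = colnames(bulk), individual_id = ind,
                         tissue = "bulk", age_days = as.numeric(ages))
  expr_dataset(pmax(bulk, 0), meta)
}

#' Simulate per-age-group signature matrices with optional convergence
#'
#' Builds one signature per age group from a common reference; at later
#' ages every cell-type profile is pulled a fraction `convergence * w`
#' toward the cross-cell-type mean profile (w growing linearly with age
#' rank), so minimally correlated cell-type pairs become more similar with
#' age when `convergence > 0`.
#'
#' @param n_genes number of genes.
#' @param tissues tissue labels; each gets `types_per_tissue` cell types.
#' @param types_per_tissue cell types per tissue.
#' @param age_groups numeric ages (days) of the signature snapshots.
#' @param convergence in \[0, 1\]: 0 = profiles constant across ages.
#' @param seed integer seed.
#' @return a named list of [signature_matrix()] objects, one per age group.
#' @export
simulate_signatures_by_age <- function(n_genes = 300,
                                       tissues = c("cortex", "liver",
                                                   "lung", "muscle"),
                                       types_per_tissue = 3,
                                       age_groups = c(90, 540, 720),
                                       convergence = 0, seed = 1L) {
  set.seed(seed)
  cts <- unlist(lapply(tissues, function(t)
    paste(t, seq_len(types_per_tissue), sep = "_ct")))
  ct_meta <- tibble::tibble(
    cell_type = cts,
    tissue = rep(tissues, each = types_per_tissue)
  )
  ref <- matrix(runif(n_genes * length(cts), 0, 10), n_genes, length(cts),
                dimnames = list(sprintf("g%05d", seq_len(n_genes)), cts))
  centre <- rowMeans(ref)
  out <- lapply(seq_along(age_groups), function(k) {
    w <- convergence * (k - 1) / max(1, length(age_groups) - 1)
    v <- (1 - w) * ref + w * centre
    signature_matrix(v, dplyr::mutate(ct_meta,
                                      age_group = as.character(age_groups[k])))
  })
  names(out) <- as.character(age_groups)
  out
}
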