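#' Expression dataset: gene x sample matrix with aligned sample metadata
#'
#' The universal carrier of the package. `values` is a numeric matrix with
#' genes as rows and samples as columns; `meta` is a tibble with one row per
#' sample column, in matching order, holding `sample_id`, `individual_id`,
#' `tissue`, `age_days` and the derived `period` (development vs ageing,
#' split at `period_boundary` days of age).
#'
#' @param values numeric matrix, genes x samples, with rownames (gene ids)
#'   and colnames (sample ids).
#' @param meta data frame with columns `sample_id`, `individual_id`,
#'   `tissue`, `age_days` (positive, in days). A `period` column, if absent,
#'   is derived from `age_days` and `period_boundary`.
#' @param period_boundary age in days separating development from ageing
#'   (default 90; in mouse, sexual maturity). Samples with
#'   `age_days < period_boundary` are labelled `"development"`, the rest
#'   `"ageing"`.
#'
#' @return an object of class `expr_dataset`: a list with elements `values`,
#'   `meta` and `period_boundary`.
#' @export
expr_dataset <- function(values, meta, period_boundary = 90) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  meta <- tibble::as_tibble(meta)
  required <- c("sample_id", "individual_id", "tissue", "age_days")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("metadata is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (is.null(rownames(values))) {
    abort("expression matrix must have gene ids as rownames")
  }
  if (anyDuplicated(rownames(values))) {
    abort("duplicate gene ids in expression matrix; sum duplicates upstream")
  }
  if (is.null(colnames(values))) colnames(values) <- meta$sample_id
  if (ncol(values) != nrow(meta)) {
    abort("number of matrix columns does not match number of metadata rows")
  }
  if (!setequal(colnames(values), meta$sample_id)) {
    abort("sample ids in matrix and metadata do not match")
  }
  if (anyDuplicated(meta$sample_id)) abort("duplicate sample ids in metadata")
  if (any(!is.finite(meta$age_days)) || any(meta$age_days <= 0)) {
    abort("age_days must be positive and finite")
  }
  dup <- duplicated(meta[, c("individual_id", "tissue")])
  if (any(dup)) {
    abort("each (individual_id, tissue) pair may appear at most once")
  }
  # align matrix columns to metadata order
  values <- values[, meta$sample_id, drop = FALSE]
  meta$tissue <- as.character(meta$tissue)
  meta$period <- assign_period(meta$age_days, period_boundary)
  structure(
    list(values = values, meta = meta, period_boundary = period_boundary),
    class = "expr_dataset"
  )
}

#' Assign lifespan period from age
#'
#' Pure function of age and boundary: `"development"` below the boundary,
#' `"ageing"` at or above it.
#'
#' @param age_days numeric vector of ages in days.
#' @param period_boundary boundary in days (default 90).
#' @return character vector of `"development"` / `"ageing"`.
#' @export
assign_period <- function(age_days, period_boundary = 90) {
  ifelse(age_days < period_boundary, "development", "ageing")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat("<expr_dataset> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  cat("  tissues: ", paste(sort(unique(x$meta$tissue)), collapse = ", "),
      "\n", sep = "")
  cat("  individuals: ", length(unique(x$meta$individual_id)),
      "; ages ", min(x$meta$age_days), "-", max(x$meta$age_days),
      " days (boundary ", x$period_boundary, " d)\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

#' Long-format view of an expression dataset
#'
#' @param x an `expr_dataset`.
#' @param ... unused.
#' @return a tibble with columns gene, sample_id, individual_id, tissue,
#'   age_days, period, value.
#' @method as_tibble expr_dataset
#' @export
as_tibble.expr_dataset <- function(x, ...) {
  long <- tibble::tibble(
    gene = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
  dplyr::left_join(long, x$meta, by = "sample_id")
}

#' Subset an expression dataset
#'
#' @param ds an `expr_dataset`.
#' @param genes optional character vector of gene ids to keep.
#' @param samples optional character vector of sample ids to keep.
#' @return an `expr_dataset`.
#' @export
subset_dataset <- function(ds, genes = NULL, samples = NULL) {
  stopifnot(inherits(ds, "expr_dataset"))
  v <- ds$values
  m <- ds$meta
  if (!is.null(genes)) v <- v[intersect(rownames(v), genes), , drop = FALSE]
  if (!is.null(samples)) {
    m <- m[m$sample_id %in% samples, , drop = FALSE]
    v <- v[, m$sample_id, drop = FALSE]
  }
  expr_dataset(v, m[, setdiff(names(m), "period")], ds$period_boundary)
}

#' Read an expression matrix and its sample metadata from delimited text
#'
#' The matrix file has gene ids in the first column and one column per
#' sample; the metadata file has one row per sample with columns
#' `sample_id`, `individual_id`, `tissue`, `age_days`. The delimiter is
#' auto-detected (tab or comma). Duplicate gene ids are summed with a
#' warning, mirroring the convention of summing FPKM values of duplicated
#' annotation entries. Negative expression values are rejected.
#'
#' @param table_path path to the expression matrix.
#' @param meta_path path to the sample metadata table.
#' @inheritParams expr_dataset
#' @return an `expr_dataset`.
#' @export
read_expression <- function(table_path, meta_path, period_boundary = 90) {
  mat_df <- read_delim_auto(table_path)
  meta <- read_delim_auto(meta_path)
  gene_ids <- as.character(mat_df[[1]])
  values <- as.matrix(mat_df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  if (any(values < 0, na.rm = TRUE)) {
    abort("expression values must be non-negative")
  }
  if (anyDuplicated(gene_ids)) {
    warn("duplicate gene ids found; summing their values")
    values <- rowsum(values, group = gene_ids, reorder = FALSE)
    gene_ids <- rownames(values)
  }
  rownames(values) <- gene_ids
  absent <- setdiff(meta$sample_id, colnames(values))
  if (length(absent) > 0) {
    abort(paste0("metadata samples absent from matrix: ",
                 paste(absent, collapse = ", ")))
  }
  extra <- setdiff(colnames(values), meta$sample_id)
  if (length(extra) > 0) {
    abort(paste0("matrix samples absent from metadata: ",
                 paste(extra, collapse = ", ")))
  }
  expr_dataset(values, meta, period_boundary)
}

read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  delim <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
               lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Write a tabular result to tab-separated text
#'
#' Values survive a write-read round trip at full double precision.
#'
#' @param result a data frame / tibble (any of the pipeline's tabular
#'   results) or a matrix (written with rownames as a leading `gene`
#'   column).
#' @param path output path.
#' @return `invisible(path)`.
#' @export
write_table <- function(result, path) {
  if (is.matrix(result)) {
    result <- tibble::as_tibble(result, rownames = "gene")
  }
  readr::write_tsv(tibble::as_tibble(result), path)
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path path to a TSV written by [write_table()].
#' @return a tibble.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

# internal helpers shared across modules -----------------------------------

# samples of a given period (and optionally tissue), in metadata order
meta_subset <- function(ds, period = NULL, tissue = NULL) {
  m <- ds$meta
  if (!is.null(period)) m <- m[m$period == period, , drop = FALSE]
  if (!is.null(tissue)) m <- m[m$tissue == tissue, , drop = FALSE]
  m
}

tissues_of <- function(ds) sort(unique(ds$meta$tissue))
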