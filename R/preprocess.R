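#' Filter genes by detection rate
#'
#' Drops genes not detected (value 0) in `max_zero_fraction` or more of all
#' samples, i.e. keeps a gene only when its zero fraction is strictly below
#' the threshold. With the default 0.25 this removes genes with zeros in
#' 25% or more of samples.
#'
#' @param ds an [expr_dataset()] of raw non-negative values.
#' @param max_zero_fraction proportion in \[0, 1\] (default 0.25).
#' @return the filtered `expr_dataset`.
#' @export
filter_low_expression <- function(ds, max_zero_fraction = 0.25) {
  stopifnot(inherits(ds, "expr_dataset"))
  zero_frac <- rowMeans(ds$values == 0)
  keep <- zero_frac < max_zero_fraction
  if (!any(keep)) warn("filtering removed every gene")
  subset_dataset(ds, genes = rownames(ds$values)[keep])
}

#' Log2 transform and quantile normalise an expression matrix
#'
#' Values are log2(x + 1) transformed and quantile normalised across all
#' samples jointly: each column's sorted values are replaced by the
#' cross-column mean at each rank, and ties within a column receive the
#' mean of the reference values over their tied rank positions (the
#' "average" tie convention; quantile-normalisation dialects differ here,
#' so the convention is part of the contract).
#'
#' @param ds an [expr_dataset()].
#' @param log_transform set `FALSE` if the values are already on a log
#'   scale and only the quantile step is wanted.
#' @return an `expr_dataset` on the normalised scale. After normalisation
#'   every column holds the identical multiset of values.
#' @export
log2_quantile_normalise <- function(ds, log_transform = TRUE) {
  stopifnot(inherits(ds, "expr_dataset"))
  v <- ds$values
  if (log_transform) {
    if (any(v < 0)) abort("negative values: already log-scale? see log_transform")
    v <- log2(v + 1)
  }
  if (ncol(v) < 2) {
    warn("single-sample dataset: returning log2 values unchanged")
  } else {
    v <- quantile_normalise_matrix(v)
  }
  out <- ds
  out$values <- v
  out
}

# reference distribution = cross-column mean at each rank; tied entries get
# the mean of the reference values over their tied positions
quantile_normalise_matrix <- function(v) {
  ref <- rowMeans(apply(v, 2L, sort))
  csum <- c(0, cumsum(ref))
  out <- v
  for (j in seq_len(ncol(v))) {
    rmn <- rank(v[, j], ties.method = "min")
    rmx <- rank(v[, j], ties.method = "max")
    out[, j] <- (csum[rmx + 1] - csum[rmn]) / (rmx - rmn + 1)
  }
  out
}
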