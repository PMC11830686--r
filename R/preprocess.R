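#' Nearest-rank empirical quantile
#'
#' The quantile convention used throughout the pipeline: the smallest
#' observed value whose cumulative fraction reaches `q` (type-1 quantile).
#' Cutoffs derived this way are always attained data values, which makes
#' the cutoff-escalation scan over observed values well defined.
#'
#' @param x numeric values.
#' @param q quantile level in (0, 1).
#' @return A single observed value of `x`.
#' @export
quantile_nearest_rank <- function(x, q) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("quantile level must lie in (0, 1)")
  if (!length(x)) stop("empty input")
  unname(quantile(x, probs = q, type = 1, names = FALSE))
}

#' Log2-transform a linear-scale MFI matrix
#'
#' @param m an [mfi_matrix()] on the linear scale.
#' @return The matrix with element-wise log2 values, `scale = "log2"`.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "mfi_matrix"))
  if (m$scale != "linear")
    stop("log2_transform expects a linear-scale matrix, got scale '", m$scale, "'")
  m$values <- log2(m$values)
  m$scale <- "log2"
  m
}

#' Sample-wise median centering
#'
#' Subtracts each sample's median log2 MFI across its marker panel,
#' removing per-sample scaling and plate/batch offsets. Every output row
#' has median exactly zero, so the operation is idempotent.
#'
#' @param m an [mfi_matrix()] on the `log2` (or already centered) scale.
#' @return The matrix with `scale = "log2_centered"`.
#' @export
median_center <- function(m) {
  stopifnot(inherits(m, "mfi_matrix"))
  if (!m$scale %in% c("log2", "log2_centered"))
    stop("median_center expects a log2-scale matrix, got scale '", m$scale, "'")
  if (ncol(m$values) < 2L)
    stop("median centering is degenerate with fewer than 2 markers per sample")
  m$values <- m$values - apply(m$values, 1L, median)
  m$scale <- "log2_centered"
  m
}

#' Low-reactivity marker pre-filter
#'
#' Drops markers whose `q`-quantile of log2 MFI across all samples does
#' not exceed `threshold`. Runs on the uncentered log2 scale: the absolute
#' threshold is meaningless after per-sample centering. The decision is
#' invariant to sample and marker order.
#'
#' @param m an [mfi_matrix()] with `scale = "log2"`.
#' @param q quantile level (default 0.75).
#' @param threshold log2 MFI threshold (default 10).
#' @return A list with the `retained` matrix, character vectors `kept`
#'   and `dropped` (marker keys), and the per-marker `quantile_values`.
#' @export
prefilter_low_reactivity <- function(m, q = 0.75, threshold = 10) {
  stopifnot(inherits(m, "mfi_matrix"))
  if (m$scale != "log2")
    stop("pre-filter runs on the uncentered log2 scale, got '", m$scale, "'")
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("quantile level must lie in (0, 1)")
  qv <- apply(m$values, 2L, quantile_nearest_rank, q = q)
  keep <- qv > threshold
  list(retained = subset_markers(m, colnames(m$values)[keep]),
       kept = colnames(m$values)[keep],
       dropped = colnames(m$values)[!keep],
       quantile_values = qv)
}
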