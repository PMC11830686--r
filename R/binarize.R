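#' Calibrate a binarization cutoff on healthy controls
#'
#' The base cutoff is the nearest-rank `q`-quantile of the healthy-control
#' (HC) intensity values; positivity is defined as a value strictly
#' greater than the cutoff, so the base cutoff itself is negative and at
#' most a fraction `1 - q` of the calibration controls can be positive.
#'
#' Cutoff escalation then scans the sorted distinct observed values
#' (HC and case pooled) above the base cutoff and accepts the largest
#' candidate that leaves the number of positive case samples unchanged
#' while strictly reducing the number of positive controls — i.e. the
#' specificity in HC is increased without changing the sensitivity in
#' cases. If no candidate qualifies the base cutoff is kept.
#'
#' @param hc HC intensity values on the analysis scale (n >= 10).
#' @param case case-group intensity values on the same scale.
#' @param q base quantile level (default 0.98).
#' @return A list: `cutoff`, `base_cutoff`, `escalated`, `n_hc`,
#'   `n_hc_pos` and `n_case_pos` (counts at the final cutoff).
#' @export
calibrate_cutoff <- function(hc, case, q = 0.98) {
  if (length(hc) < 10L)
    stop("cutoff calibration needs at least 10 HC values; pool controls if necessary")
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("quantile level must lie in (0, 1)")
  c0 <- quantile_nearest_rank(hc, q)
  n_case0 <- sum(case > c0)
  n_hc0 <- sum(hc > c0)
  cutoff <- c0; escalated <- FALSE
  cand <- sort(unique(c(hc, case)))
  cand <- cand[cand > c0]
  for (cc in rev(cand)) {
    if (sum(case > cc) == n_case0 && sum(hc > cc) < n_hc0) {
      cutoff <- cc; escalated <- TRUE
      break
    }
  }
  list(cutoff = cutoff, base_cutoff = c0, escalated = escalated,
       n_hc = length(hc), n_hc_pos = sum(hc > cutoff),
       n_case_pos = sum(case > cutoff))
}

#' Calibrate cutoffs for every marker of a matrix
#'
#' Applies [calibrate_cutoff()] marker-wise, using only HC samples for the
#' quantile and the case group for the escalation sensitivity constraint.
#' Disease and sicca controls never enter calibration; specificity against
#' them is evaluation-only.
#'
#' @param m an [mfi_matrix()] on the analysis scale.
#' @param meta aligned metadata.
#' @param case_group case group label used by the escalation rule.
#' @param q base quantile level.
#' @return A `cutoff_table` data frame with one row per marker: both the
#'   base and the (possibly escalated) final cutoff are recorded.
#' @export
build_cutoff_table <- function(m, meta, case_group = "SjD", q = 0.98) {
  stopifnot(inherits(m, "mfi_matrix"), nrow(meta) == nrow(m$values))
  hc_idx <- which(meta$group == "HC")
  case_idx <- which(meta$group == case_group)
  keys <- colnames(m$values)
  rows <- lapply(seq_along(keys), function(j) {
    cal <- calibrate_cutoff(m$values[hc_idx, j], m$values[case_idx, j], q)
    data.frame(marker_key = keys[j],
               marker_id = m$markers$marker_id[j],
               isotype = m$markers$isotype[j],
               cutoff = cal$cutoff,
               base_cutoff = cal$base_cutoff,
               base_quantile_level = q,
               escalated = cal$escalated,
               n_hc_used = cal$n_hc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cutoff_table", "data.frame")
  out
}

#' Binarize an MFI matrix against a cutoff table
#'
#' A call is positive when the value is strictly greater than the marker's
#' cutoff. The rule is applied uniformly to all samples and groups, so
#' cross-disease prevalences come from the same calls.
#'
#' @param m an [mfi_matrix()] on the scale the cutoffs were calibrated on.
#' @param cutoffs a `cutoff_table` covering every marker of `m`.
#' @param use one of `"cutoff"` (default: escalated where available) or
#'   `"base_cutoff"`.
#' @return A `binary_matrix`: logical calls plus marker annotations.
#' @export
binarize <- function(m, cutoffs, use = c("cutoff", "base_cutoff")) {
  stopifnot(inherits(m, "mfi_matrix"), inherits(cutoffs, "cutoff_table"))
  use <- match.arg(use)
  keys <- colnames(m$values)
  missing <- setdiff(keys, cutoffs$marker_key)
  if (length(missing))
    stop("no cutoff for marker(s): ", paste(missing, collapse = ", "))
  cut <- cutoffs[[use]][match(keys, cutoffs$marker_key)]
  calls <- sweep(m$values, 2L, cut, `>`)
  structure(list(calls = calls, markers = m$markers),
            class = "binary_matrix")
}

#' Fisher's exact test on binarized calls
#'
#' Two-sided p-value obtained by summing the hypergeometric probabilities
#' of all 2x2 tables (with the observed margins) that are no more probable
#' than the observed table. A degenerate margin (no positives anywhere,
#' or an empty group) yields p = 1 with a warning.
#'
#' @param case_calls,control_calls logical call vectors.
#' @return The two-sided p-value.
#' @seealso [fisher_exact_table()] for a count interface.
#' @export
fisher_exact <- function(case_calls, control_calls) {
  fisher_exact_table(matrix(c(sum(case_calls), sum(!case_calls),
                              sum(control_calls), sum(!control_calls)),
                            nrow = 2L, byrow = TRUE))
}

#' @param tab a 2x2 integer matrix: rows = groups, columns = positive /
#'   negative counts.
#' @rdname fisher_exact
#' @export
fisher_exact_table <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0))
  a <- tab[1L, 1L]
  k <- sum(tab[1L, ])          # case group size
  m <- sum(tab[, 1L])          # total positives
  n <- sum(tab[, 2L])          # total negatives
  if (k == 0L || sum(tab[2L, ]) == 0L || m == 0L || n == 0L) {
    warning("degenerate margin in 2x2 table; p = 1")
    return(1)
  }
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Per-marker, per-group seroprevalence
#'
#' Fraction of positive calls per marker within each study group. Groups
#' without samples are excluded with a warning.
#'
#' @param b a [binarize()] result.
#' @param meta aligned metadata.
#' @return A `prevalence_table` data frame: `marker_key`, `group`, `n`,
#'   `n_pos`, `prevalence` (fraction) and `percent`.
#' @export
prevalence_table <- function(b, meta) {
  stopifnot(inherits(b, "binary_matrix"), nrow(meta) == nrow(b$calls))
  groups <- intersect(.GROUPS, unique(meta$group))
  empty <- setdiff(unique(meta$group), groups)
  if (length(empty)) warning("empty group(s) excluded: ", paste(empty, collapse = ", "))
  keys <- colnames(b$calls)
  out <- do.call(rbind, lapply(groups, function(g) {
    idx <- meta$group == g
    npos <- colSums(b$calls[idx, , drop = FALSE])
    data.frame(marker_key = keys, group = g, n = sum(idx),
               n_pos = as.integer(npos),
               prevalence = npos / sum(idx),
               percent = 100 * npos / sum(idx),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("prevalence_table", "data.frame")
  out
}

#' Co-prevalence matrix of binarized markers
#'
#' For a sample subset, the diagonal holds each marker's prevalence and
#' the off-diagonal cells the fraction of samples positive for both
#' markers of the pair. Low co-prevalence between two markers means their
#' positive patients barely overlap, i.e. complementary coverage.
#'
#' @param b a [binarize()] result.
#' @param subset logical vector over samples, or character sample ids;
#'   `NULL` uses all samples.
#' @return A symmetric `coprevalence_matrix` of fractions, with attribute
#'   `n` (subset size).
#' @export
coprevalence_matrix <- function(b, subset = NULL) {
  stopifnot(inherits(b, "binary_matrix"))
  calls <- b$calls
  if (!is.null(subset)) {
    if (is.character(subset)) subset <- rownames(calls) %in% subset
    stopifnot(is.logical(subset), length(subset) == nrow(calls))
    calls <- calls[subset, , drop = FALSE]
  }
  if (!nrow(calls)) stop("empty sample subset")
  cp <- crossprod(calls) / nrow(calls)
  structure(cp, class = c("coprevalence_matrix", class(cp)), n = nrow(calls))
}
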