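#' Mann-Whitney U test for one marker
#'
#' Two-sided comparison of case versus control intensity values. The
#' p-value is exact (full null enumeration of rank assignments) when the
#' combined sample size is at most 12 and there are no ties; otherwise the
#' normal approximation with tie and continuity correction is used.
#'
#' @param case,control numeric vectors (each of length >= 2).
#' @return A list with `statistic` (U, counted from the case side) and
#'   `p_value`.
#' @export
mann_whitney <- function(case, control) {
  if (length(case) < 2L || length(control) < 2L)
    stop("mann_whitney needs at least 2 values per group")
  n1 <- length(case)
  r <- rank(c(case, control))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(case, control)) > 0L
  exact <- !ties && (n1 + length(control)) <= 12L
  p <- suppressWarnings(
    wilcox.test(case, control, exact = exact, correct = TRUE)$p.value
  )
  list(statistic = unname(U), p_value = unname(p))
}

#' SAM d-statistic
#'
#' Moderated mean-difference statistic of significance analysis of
#' microarrays: `d = (mean(case) - mean(control)) / (s + s0)`, where `s`
#' is the pooled standard error of the mean difference and `s0` a fudge
#' factor stabilising markers with small scatter.
#'
#' @param case,control numeric vectors (each of length >= 2).
#' @param s0 non-negative fudge factor.
#' @return The signed d-statistic.
#' @seealso [sam_permutation_p()] for its significance.
#' @export
sam_d <- function(case, control, s0 = 0) {
  if (length(case) < 2L || length(control) < 2L)
    stop("sam_d needs at least 2 values per group")
  if (s0 < 0) stop("s0 must be non-negative")
  s <- pooled_se(case, control)
  if (s + s0 == 0) stop("zero denominator: pooled scatter and s0 are both 0")
  (mean(case) - mean(control)) / (s + s0)
}

pooled_se <- function(case, control) {
  n1 <- length(case); n2 <- length(control)
  ssw <- sum((case - mean(case))^2) + sum((control - mean(control))^2)
  sqrt((1 / n1 + 1 / n2) * ssw / (n1 + n2 - 2))
}

#' Permutation significance of the SAM d-statistic
#'
#' Two-sided permutation p-value of [sam_d()] over random relabelings of
#' the group labels. When the number of distinct labelings is at most
#' `exact_limit` all labelings are enumerated and the p-value is exact;
#' otherwise `n_perm` Monte-Carlo permutations are drawn (the observed
#' labeling is counted once, giving the usual (1 + b) / (1 + B) estimate).
#'
#' @inheritParams sam_d
#' @param n_perm Monte-Carlo permutation count.
#' @param exact_limit enumeration threshold on `choose(n, n_case)`.
#' @return A list with `d` and `p_value`.
#' @export
sam_permutation_p <- function(case, control, s0 = 0, n_perm = 1000,
                              exact_limit = 5000) {
  d_obs <- sam_d(case, control, s0)
  x <- c(case, control)
  n1 <- length(case); n <- length(x)
  stat <- function(idx) {
    a <- x[idx]; b <- x[-idx]
    s <- pooled_se(a, b)
    (mean(a) - mean(b)) / (s + s0)
  }
  tol <- 1e-12
  if (choose(n, n1) <= exact_limit) {
    idxs <- combn(n, n1)
    d_all <- apply(idxs, 2L, stat)
    p <- mean(abs(d_all) >= abs(d_obs) - tol)
  } else {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (abs(stat(sample.int(n, n1))) >= abs(d_obs) - tol) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  list(d = d_obs, p_value = p)
}

#' Median fold change between groups
#'
#' Case/control ratio on the linear scale, computed from values on the
#' log2 analysis scale as `2^(median(case) - median(control))`.
#'
#' @param case,control numeric vectors of log2-scale values.
#' @return The linear-scale ratio (> 0).
#' @export
fold_change <- function(case, control) {
  if (!length(case) || !length(control)) stop("empty group")
  2^(median(case) - median(control))
}

#' Absolute quantile span between groups
#'
#' The maximum, over the 25/50/75% quantiles, of the absolute difference
#' between case and control quantiles (log2 units). This operationalises
#' the "absolute span of at least one quantile" criterion of the
#' discovery-screen Wilcoxon filter.
#'
#' @param case,control numeric vectors of log2-scale values.
#' @param probs quantile levels checked.
#' @return The maximal absolute quantile difference.
#' @export
quantile_span <- function(case, control, probs = c(0.25, 0.5, 0.75)) {
  if (!length(case) || !length(control)) stop("empty group")
  qc <- vapply(probs, function(p) quantile_nearest_rank(case, p), 0)
  qt <- vapply(probs, function(p) quantile_nearest_rank(control, p), 0)
  max(abs(qc - qt))
}

# vectorised SAM permutation p across the markers of a matrix.
# V: n x p matrix of values, case_idx: indices of case rows.
# Shares one permutation set across markers; exact enumeration for tiny n.
sam_screen_p <- function(V, case_idx, s0, n_perm = 1000, exact_limit = 5000) {
  n <- nrow(V); n1 <- length(case_idx); n2 <- n - n1
  col_d <- function(idx) {
    a <- V[idx, , drop = FALSE]; b <- V[-idx, , drop = FALSE]
    m1 <- colMeans(a); m2 <- colMeans(b)
    ssw <- colSums(a^2) - n1 * m1^2 + colSums(b^2) - n2 * m2^2
    s <- sqrt((1 / n1 + 1 / n2) * ssw / (n - 2))
    (m1 - m2) / (s + s0)
  }
  d_obs <- col_d(case_idx)
  tol <- 1e-12
  if (choose(n, n1) <= exact_limit) {
    idxs <- combn(n, n1)
    hits <- rep(0L, ncol(V))
    for (j in seq_len(ncol(idxs)))
      hits <- hits + (abs(col_d(idxs[, j])) >= abs(d_obs) - tol)
    p <- hits / ncol(idxs)
  } else {
    hits <- rep(0L, ncol(V))
    for (b in seq_len(n_perm))
      hits <- hits + (abs(col_d(sample.int(n, n1))) >= abs(d_obs) - tol)
    p <- (hits + 1) / (n_perm + 1)
  }
  list(d = d_obs, p = p)
}

#' Univariate candidate marker screen
#'
#' Runs the full per-marker screening battery on a centered log2 matrix:
#' Mann-Whitney test, median fold change, SAM d with shared-permutation
#' significance, quantile span, control-anchored binarization with
#' Fisher's exact test, and per-group prevalence. Flags record which
#' criteria sets each marker passes: the SAM discovery criteria
#' (p <= alpha, FC >= 1.5, d >= 2), the Wilcoxon discovery criteria
#' (p <= alpha, span >= 1, FC >= 1.5), and the validation Fisher
#' criterion (p <= alpha on binarized calls). Screen p-values are
#' reported raw (unadjusted), as in the analysis this implements;
#' multiple-testing adjustment belongs to the clinical-association stage.
#'
#' @param m an [mfi_matrix()] with `scale = "log2_centered"`.
#' @param meta aligned metadata (same sample order as `m`).
#' @param case_group,control_group group labels compared.
#' @param config a [pipeline_config()].
#' @return A list of class `screen_output` with elements `results` (a
#'   `screen_result` data frame), `cutoffs` (a `cutoff_table`), `binary`
#'   (a `binary_matrix` over all samples) and `prevalence`.
#' @export
screen_markers <- function(m, meta, case_group = "SjD", control_group = "HC",
                           config = pipeline_config()) {
  stopifnot(inherits(m, "mfi_matrix"))
  if (m$scale != "log2_centered")
    stop("screen_markers expects a sample-wise median-centered log2 matrix")
  stopifnot(nrow(meta) == nrow(m$values))
  case_idx <- which(meta$group == case_group)
  ctrl_idx <- which(meta$group == control_group)
  if (length(case_idx) < 2L || length(ctrl_idx) < 2L)
    stop("need at least 2 samples in each of the compared groups")
  V <- m$values
  keys <- colnames(V)

  # per-marker pooled SE; median across markers is the default SAM s0
  s_pool <- vapply(keys, function(k) pooled_se(V[case_idx, k], V[ctrl_idx, k]), 0)
  s0 <- config$sam_s0 %||% median(s_pool)

  sam <- sam_screen_p(V[c(case_idx, ctrl_idx), , drop = FALSE],
                      seq_along(case_idx), s0 = s0, n_perm = config$n_perm)

  mw_p <- numeric(length(keys)); fc <- numeric(length(keys))
  span <- numeric(length(keys))
  for (j in seq_along(keys)) {
    cs <- V[case_idx, j]; ct <- V[ctrl_idx, j]
    mw_p[j] <- mann_whitney(cs, ct)$p_value
    fc[j] <- fold_change(cs, ct)
    span[j] <- quantile_span(cs, ct)
  }

  cutoffs <- build_cutoff_table(m, meta, case_group = case_group,
                                q = config$cutoff_quantile)
  binary <- binarize(m, cutoffs)
  # markers with no positives at all yield a degenerate margin (p = 1);
  # routine in a screen, so the per-marker warning is silenced here
  fisher_p <- vapply(seq_along(keys), function(j) suppressWarnings(
    fisher_exact(binary$calls[case_idx, j], binary$calls[ctrl_idx, j])), 0)
  prevalence <- prevalence_table(binary, meta)

  prev_case <- prevalence$prevalence[prevalence$group == case_group]
  prev_ctrl <- prevalence$prevalence[prevalence$group == control_group]

  res <- data.frame(
    marker_key = keys,
    marker_id = m$markers$marker_id,
    isotype = m$markers$isotype,
    mw_p = mw_p,
    fold_change = fc,
    sam_d = unname(sam$d),
    sam_p = unname(sam$p),
    span = span,
    fisher_p = fisher_p,
    prev_case = prev_case,
    prev_control = prev_ctrl,
    pass_sam = unname(sam$p) <= config$screen_alpha &
      fc >= config$fold_change_min & unname(sam$d) >= config$d_score_min,
    pass_wilcoxon = mw_p <= config$screen_alpha &
      span >= config$span_min & fc >= config$fold_change_min,
    pass_fisher = fisher_p <= config$screen_alpha,
    stringsAsFactors = FALSE
  )
  class(res) <- c("screen_result", "data.frame")
  structure(list(results = res, cutoffs = cutoffs, binary = binary,
                 prevalence = prevalence, s0 = s0),
            class = "screen_output")
}
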