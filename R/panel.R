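#' Construct an OR-rule diagnostic panel
#'
#' A panel is an ordered set of binarized markers combined by a logical
#' OR: a sample is predicted positive if any panel marker's call is
#' positive. The selection order, per-marker marginal gains and the
#' cutoffs used are retained for the run manifest.
#'
#' @param markers ordered character vector of marker keys.
#' @param cutoffs optional `cutoff_table` slice covering the markers.
#' @param metrics optional metrics list (from [evaluate_panel()]).
#' @param gains optional numeric vector of marginal coverage gains
#'   (target-sample counts) recorded at selection time.
#' @return A `panel_model` object.
#' @export
panel_model <- function(markers, cutoffs = NULL, metrics = NULL, gains = NULL) {
  stopifnot(is.character(markers), length(markers) >= 1L)
  if (anyDuplicated(markers)) stop("duplicated markers in panel")
  if (!is.null(cutoffs)) {
    stopifnot(inherits(cutoffs, "cutoff_table"))
    missing <- setdiff(markers, cutoffs$marker_key)
    if (length(missing))
      stop("cutoff table does not cover: ", paste(missing, collapse = ", "))
    cutoffs <- cutoffs[match(markers, cutoffs$marker_key), , drop = FALSE]
    class(cutoffs) <- c("cutoff_table", "data.frame")
  }
  structure(list(markers = markers, cutoffs = cutoffs,
                 rule = "or", metrics = metrics, gains = gains),
            class = "panel_model")
}

#' Predict case status with an OR-rule panel
#'
#' @param panel a [panel_model()].
#' @param b a [binarize()] result containing every panel marker.
#' @return Named logical vector: `TRUE` where any panel marker is positive.
#' @export
predict_panel <- function(panel, b) {
  stopifnot(inherits(panel, "panel_model"), inherits(b, "binary_matrix"))
  missing <- setdiff(panel$markers, colnames(b$calls))
  if (length(missing))
    stop("panel marker(s) absent from calls: ", paste(missing, collapse = ", "))
  rowSums(b$calls[, panel$markers, drop = FALSE]) > 0
}

#' Evaluate panel sensitivity and specificity
#'
#' Sensitivity is the positive fraction in the target subgroup (for the
#' seronegative use case: Ro/SSA-negative SjD patients); specificity is
#' the negative fraction among healthy controls, and among non-Sjogren's
#' sicca (NSS) samples when present. Exact (Clopper-Pearson) binomial 95%
#' confidence intervals are attached to every estimate.
#'
#' @param panel a [panel_model()].
#' @param b a [binarize()] result.
#' @param meta aligned metadata.
#' @param target target subgroup: `"ro_ssa_negative"`, a group label, or a
#'   logical vector (see [join_metadata()] for metadata layout).
#' @return A metrics list of class `panel_metrics`.
#' @export
evaluate_panel <- function(panel, b, meta, target = "ro_ssa_negative") {
  stopifnot(nrow(meta) == nrow(b$calls))
  pred <- predict_panel(panel, b)
  tgt <- target_selector(meta, target)
  if (!any(tgt)) stop("empty target subgroup")
  hc <- meta$group == "HC"
  if (!any(hc)) stop("no HC samples to evaluate specificity against")
  prop_ci <- function(k, n) {
    ci <- binom.test(k, n)$conf.int
    c(lower = ci[1L], upper = ci[2L])
  }
  sens_k <- sum(pred[tgt]); sens_n <- sum(tgt)
  spec_k <- sum(!pred[hc]); spec_n <- sum(hc)
  out <- list(
    sensitivity = sens_k / sens_n,
    sensitivity_ci = prop_ci(sens_k, sens_n),
    n_target = sens_n,
    specificity_hc = spec_k / spec_n,
    specificity_hc_ci = prop_ci(spec_k, spec_n),
    n_hc = spec_n
  )
  nss <- meta$group == "NSS"
  if (any(nss)) {
    out$specificity_nss <- sum(!pred[nss]) / sum(nss)
    out$specificity_nss_ci <- prop_ci(sum(!pred[nss]), sum(nss))
    out$n_nss <- sum(nss)
  }
  class(out) <- "panel_metrics"
  out
}

#' Greedy forward selection of an OR-rule panel
#'
#' Builds a diagnostic panel for a target subgroup by forward feature
#' selection over binarized markers: the seed is the most prevalent
#' marker in the target subgroup; each further step adds, among markers
#' that keep the panel's HC specificity at or above `min_spec_hc`, the
#' marker with the largest incremental union coverage — the marker most
#' prevalent among target samples not yet covered. Maximising marginal
#' coverage is the operational form of preferring markers with low
#' co-prevalence to the panel so far. Selection stops at `max_k` markers
#' or when no marker adds coverage. Ties break by higher panel HC
#' specificity, then lexicographic marker key, so selection is
#' deterministic.
#'
#' By default only IgG channels are candidates (IgA reactivity tracks
#' disease activity and may vary over time, so it is kept out of the
#' diagnostic panel).
#'
#' @param b a [binarize()] result.
#' @param meta aligned metadata.
#' @param target target subgroup selector (default Ro/SSA-negative SjD).
#' @param max_k maximum panel size (>= 1).
#' @param min_spec_hc HC specificity floor enforced at every step.
#' @param candidates optional character vector of candidate marker keys
#'   (e.g. the pre-screened significant markers); default: all IgG
#'   markers in `b`.
#' @param cutoffs optional `cutoff_table` stored in the returned model.
#' @return A [panel_model()] with metrics, selection-order marginal gains
#'   and the target-subset co-prevalence submatrix of the selected
#'   markers (`attr(panel, "coprevalence")`).
#' @export
forward_select_panel <- function(b, meta, target = "ro_ssa_negative",
                                 max_k = 5, min_spec_hc = 0.95,
                                 candidates = NULL, cutoffs = NULL) {
  stopifnot(inherits(b, "binary_matrix"), nrow(meta) == nrow(b$calls))
  if (max_k < 1L) stop("max_k must be >= 1")
  tgt <- target_selector(meta, target)
  if (!any(tgt)) stop("empty target subgroup")
  hc <- meta$group == "HC"
  if (!any(hc)) stop("no HC samples: specificity floor cannot be enforced")
  if (is.null(candidates))
    candidates <- colnames(b$calls)[b$markers$isotype == "IgG"]
  missing <- setdiff(candidates, colnames(b$calls))
  if (length(missing))
    stop("candidate marker(s) absent from calls: ", paste(missing, collapse = ", "))
  if (!length(candidates)) stop("no candidate markers")

  Tm <- b$calls[tgt, candidates, drop = FALSE]
  H <- b$calls[hc, candidates, drop = FALSE]
  n_hc <- nrow(H)

  sel <- character(0)
  gains <- numeric(0)
  covered <- rep(FALSE, nrow(Tm))
  hc_pos <- rep(FALSE, n_hc)

  repeat {
    remaining <- setdiff(candidates, sel)
    if (!length(remaining) || length(sel) >= max_k) break
    gain <- spec <- rep(NA_real_, length(remaining))
    for (i in seq_along(remaining)) {
      mk <- remaining[i]
      sp <- sum(!(hc_pos | H[, mk])) / n_hc
      if (sp < min_spec_hc) next
      spec[i] <- sp
      gain[i] <- sum(Tm[!covered, mk])
    }
    eligible <- !is.na(gain)
    if (!any(eligible)) {
      if (!length(sel))
        stop(sprintf("no marker satisfies the HC specificity floor (min_spec_hc = %g)",
                     min_spec_hc))
      break
    }
    if (max(gain[eligible]) <= 0 && length(sel)) break
    ord <- order(-gain, -spec, remaining, na.last = TRUE)
    best <- ord[1L]
    sel <- c(sel, remaining[best])
    gains <- c(gains, gain[best])
    covered <- covered | Tm[, remaining[best]]
    hc_pos <- hc_pos | H[, remaining[best]]
  }

  panel <- panel_model(sel, cutoffs = cutoffs, gains = gains)
  panel$metrics <- evaluate_panel(panel, b, meta, target)
  attr(panel, "coprevalence") <-
    coprevalence_matrix(list_to_binary(b, sel), subset = tgt)
  panel
}

# binary_matrix restricted to a marker subset
list_to_binary <- function(b, keys) {
  idx <- match(keys, colnames(b$calls))
  structure(list(calls = b$calls[, idx, drop = FALSE],
                 markers = b$markers[idx, , drop = FALSE]),
            class = "binary_matrix")
}

#' Principal-component cohort-comparability check
#'
#' Singular value decomposition of the column-centered, sample-wise
#' median-centered log2 matrix, reporting the first two component
#' coordinates, the explained-variance fractions, and per-cohort
#' centroids with pairwise centroid distances as a quick diagnostic of
#' whether the global reactivity distribution is comparable between
#' recruiting centers.
#'
#' @param m an [mfi_matrix()] with `scale = "log2_centered"`; at least 3
#'   samples and 2 markers of rank >= 2.
#' @param meta optional aligned metadata with a `cohort` column.
#' @return A list of class `pca_qc`: `scores` (n x 2), `explained`
#'   (variance fractions, all components), `centroids` and
#'   `centroid_distances` (when metadata is supplied).
#' @export
pca_qc <- function(m, meta = NULL) {
  stopifnot(inherits(m, "mfi_matrix"))
  if (m$scale != "log2_centered")
    stop("pca_qc expects the centered log2 analysis scale")
  if (nrow(m$values) < 3L || ncol(m$values) < 2L)
    stop("pca_qc needs at least 3 samples and 2 markers")
  pr <- prcomp(m$values, center = TRUE, scale. = FALSE)
  if (pr$sdev[1L] <= 0 || length(pr$sdev) < 2L)
    stop("matrix rank < 2: no 2-D component plane")
  ev <- pr$sdev^2 / sum(pr$sdev^2)
  scores <- pr$x[, 1:2, drop = FALSE]
  out <- list(scores = scores, explained = ev)
  if (!is.null(meta) && "cohort" %in% names(meta)) {
    stopifnot(nrow(meta) == nrow(scores))
    cent <- do.call(rbind, lapply(split(as.data.frame(scores), meta$cohort),
                                  colMeans))
    out$centroids <- cent
    out$centroid_distances <- as.matrix(dist(cent))
  }
  class(out) <- "pca_qc"
  out
}

#' @importFrom stats dist
NULL

#' @export
print.panel_model <- function(x, ...) {
  cat("OR-rule panel:", paste(x$markers, collapse = " + "), "\n")
  if (!is.null(x$metrics)) {
    m <- x$metrics
    cat(sprintf("  sensitivity (target):   %.1f%% (n = %d)\n",
                100 * m$sensitivity, m$n_target))
    cat(sprintf("  specificity vs HC:      %.1f%% (n = %d)\n",
                100 * m$specificity_hc, m$n_hc))
    if (!is.null(m$specificity_nss))
      cat(sprintf("  specificity vs NSS:     %.1f%% (n = %d)\n",
                  100 * m$specificity_nss, m$n_nss))
  }
  invisible(x)
}
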