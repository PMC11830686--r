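#' Ground truth for a synthetic serology cohort
#'
#' Describes the generative model of a multiplex bead-array cohort on the
#' log2 scale: for sample j and marker i,
#' \deqn{log2 MFI_{ij} = \mu_i + \delta_{ij} e_i + c_j + b_{batch(j)} + \epsilon_{ij}}
#' with responder indicators \eqn{\delta_{ij} \sim Bernoulli(\pi_{i,g(j)})},
#' noise \eqn{\epsilon_{ij} \sim N(0, \sigma_i)}, per-sample scaling
#' offsets \eqn{c_j \sim N(0, sd)} and one additive batch offset per
#' recruiting center. The emitted matrix is `2^` of that value (linear
#' MFI). A responder is a location shift, not a variance change, matching
#' the threshold-based binarization downstream.
#'
#' @param markers `data.frame` with columns `marker_id`, `isotype`, `mu`
#'   (log2 background mean), `sigma` (log2 background sd, > 0), `effect`
#'   (log2 responder shift, >= 0); optional `source`.
#' @param prevalence numeric matrix, markers x groups, of responder
#'   prevalences in \[0, 1\]; column names are group labels.
#' @param sample_offset_sd sd of the per-sample scaling offset (log2).
#' @param centers `data.frame(cohort, offset, sjd_prob)`: batch offsets
#'   per recruiting center and the center mix of SjD patients (controls
#'   are recruited at the first center).
#' @param associations optional ledger `data.frame(marker_key, outcome,
#'   beta, beta0)` for [attach_clinical_outcomes()]; one marker per
#'   outcome.
#' @param missing_frac fraction of generated clinical flags blanked to
#'   `NA` to exercise complete-case handling.
#' @param rng_seed integer seed; identical (truth, seed) pairs generate
#'   bit-identical cohorts.
#' @return A `sim_truth` object.
#' @export
sim_truth <- function(markers, prevalence,
                      sample_offset_sd = 0.4,
                      centers = data.frame(
                        cohort = c("center1", "center2", "center3"),
                        offset = c(0, 0.2, -0.2),
                        sjd_prob = c(0.625, 0.207, 0.168)),
                      associations = NULL,
                      missing_frac = 0,
                      rng_seed = 1L) {
  check_markers(markers)
  need <- c("mu", "sigma", "effect")
  if (!all(need %in% names(markers)))
    stop("truth markers need columns: ", paste(need, collapse = ", "))
  if (any(markers$sigma <= 0)) stop("sigma must be > 0")
  if (any(markers$effect < 0)) stop("effect must be >= 0")
  prevalence <- as.matrix(prevalence)
  if (nrow(prevalence) != nrow(markers))
    stop("prevalence must have one row per marker")
  if (is.null(colnames(prevalence)) || !all(colnames(prevalence) %in% .GROUPS))
    stop("prevalence columns must be group labels (",
         paste(.GROUPS, collapse = ", "), ")")
  if (any(prevalence < 0 | prevalence > 1)) stop("prevalences must lie in [0, 1]")
  rownames(prevalence) <- marker_key(markers)
  if (!is.null(associations)) {
    need_a <- c("marker_key", "outcome", "beta", "beta0")
    if (!all(need_a %in% names(associations)))
      stop("associations need columns: ", paste(need_a, collapse = ", "))
    if (anyDuplicated(associations$outcome))
      stop("one marker per outcome in the association ledger")
    bad <- setdiff(associations$marker_key, marker_key(markers))
    if (length(bad))
      stop("association ledger references unknown marker(s): ",
           paste(bad, collapse = ", "))
  }
  stopifnot(sample_offset_sd >= 0, missing_frac >= 0, missing_frac < 1)
  structure(list(markers = markers, prevalence = prevalence,
                 sample_offset_sd = sample_offset_sd, centers = centers,
                 associations = associations, missing_frac = missing_frac,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_truth")
}

#' Default synthetic study truth
#'
#' A ready-made truth emulating a validation-study marker panel: one
#' anti-Ro60 IgG channel (responder prevalence 0.60 in SjD, echoing the
#' ~62% Ro/SSA positivity of such cohorts, with the cross-disease rates
#' of lupus and rheumatoid arthritis), `n_signal` SjD-enriched markers
#' with responder prevalences drawn between 0.05 and 0.19 (the range
#' reported for novel autoantibodies) and effect 5 sigma, a 10% share of
#' low-reactivity markers that the 75%-quantile pre-filter should drop,
#' and background seropositivity of 0.01 in every group for the
#' remaining null markers. Background means are drawn in 10.5-12.5 log2
#' MFI (low-reactivity: 8.5-9.8) and sigmas in 0.3-0.7 log2 units.
#'
#' @param n_markers total marker count.
#' @param n_signal number of SjD-enriched (signal) markers.
#' @param seed integer seed used both to draw the truth and as its
#'   `rng_seed`.
#' @param associations,missing_frac passed to [sim_truth()].
#' @return A `sim_truth`.
#' @export
default_sim_truth <- function(n_markers = 100, n_signal = 12, seed = 1L,
                              associations = NULL, missing_frac = 0) {
  stopifnot(n_markers >= n_signal + 2L)
  set.seed(as.integer(seed))
  n_low <- max(0L, round(0.1 * n_markers))
  n_null <- n_markers - 1L - n_signal - n_low
  ids <- sprintf("AG%03d", seq_len(n_markers - 1L))
  iso <- rep(c("IgG", "IgA"), length.out = n_markers - 1L)
  markers <- data.frame(
    marker_id = c("RO60", ids),
    isotype = c("IgG", iso),
    source = "discovery",
    mu = c(11.5, runif(n_signal, 10.8, 12.3),
           runif(n_null, 10.5, 12.5), runif(n_low, 8.5, 9.8)),
    sigma = runif(n_markers, 0.3, 0.7),
    effect = 0,
    stringsAsFactors = FALSE
  )
  sig_idx <- 1L + seq_len(n_signal)
  markers$effect[1L] <- 3
  markers$effect[sig_idx] <- 5 * markers$sigma[sig_idx]
  # make all signal markers IgG except every third (panel selection is
  # IgG-only; keep some IgA signal for the association stage)
  markers$isotype[sig_idx] <- ifelse(seq_len(n_signal) %% 3L == 0L, "IgA", "IgG")
  prev <- matrix(0.01, n_markers, length(.GROUPS),
                 dimnames = list(NULL, .GROUPS))
  prev[1L, ] <- c(SjD = 0.60, HC = 0.02, NSS = 0, RA = 0.02,
                  SLE = 0.35, SSc = 0.08)
  prev[sig_idx, "SjD"] <- runif(n_signal, 0.05, 0.19)
  sim_truth(markers, prev, associations = associations,
            missing_frac = missing_frac, rng_seed = as.integer(seed))
}

#' Simulate a multiplex serology cohort
#'
#' Draws a cohort from a [sim_truth()] generative model and returns the
#' linear-scale MFI matrix, the sample metadata, and the truth augmented
#' with the realised responder indicators, sample offsets and center
#' assignments (the ground-truth ledger for recovery tests). Ro/SSA
#' status is the responder indicator of the designated `"RO60|IgG"`
#' channel when present, `NA` otherwise. Deterministic given
#' `truth$rng_seed`.
#'
#' @param truth a [sim_truth()].
#' @param n_per_group named integer vector of group sizes, e.g.
#'   `c(SjD = 347, HC = 118, NSS = 44)`; every group must appear in the
#'   truth's prevalence map.
#' @return A list of class `sim_cohort`: `mfi`, `meta`, `truth` (with
#'   `$delta`, `$sample_offsets`, `$batch` filled in).
#' @export
simulate_cohort <- function(truth, n_per_group) {
  stopifnot(inherits(truth, "sim_truth"))
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group))))
    stop("n_per_group must be a named vector of group sizes")
  if (any(n_per_group < 1L)) stop("group counts must be >= 1")
  absent <- setdiff(names(n_per_group), colnames(truth$prevalence))
  if (length(absent))
    stop("group(s) absent from the prevalence map: ",
         paste(absent, collapse = ", "))
  set.seed(truth$rng_seed)
  groups <- rep(names(n_per_group), times = n_per_group)
  n <- length(groups)
  keys <- marker_key(truth$markers)
  p <- length(keys)
  sample_id <- sprintf("%s_%04d", groups, unlist(lapply(n_per_group, seq_len)))

  ctr <- truth$centers
  cohort <- rep(ctr$cohort[1L], n)
  is_sjd <- groups == "SjD"
  if (any(is_sjd))
    cohort[is_sjd] <- sample(ctr$cohort, sum(is_sjd), replace = TRUE,
                             prob = ctr$sjd_prob)
  b_off <- ctr$offset[match(cohort, ctr$cohort)]
  c_off <- rnorm(n, 0, truth$sample_offset_sd)

  delta <- matrix(0L, n, p, dimnames = list(sample_id, keys))
  for (i in seq_len(p)) {
    pr <- truth$prevalence[i, groups]
    delta[, i] <- rbinom(n, 1L, pr)
  }
  eps <- matrix(rnorm(n * p), n, p) *
    rep(truth$markers$sigma, each = n)
  log2v <- rep(truth$markers$mu, each = n) +
    delta * rep(truth$markers$effect, each = n) +
    c_off + b_off + eps
  dimnames(log2v) <- list(sample_id, keys)

  ro <- if ("RO60|IgG" %in% keys) delta[, "RO60|IgG"] == 1L else NA
  meta <- data.frame(sample_id = sample_id, group = groups, cohort = cohort,
                     ro_ssa_positive = ro, stringsAsFactors = FALSE)

  truth$delta <- delta
  truth$sample_offsets <- setNames(c_off, sample_id)
  truth$batch <- setNames(cohort, sample_id)
  structure(list(mfi = mfi_matrix(2^log2v,
                                  markers = truth$markers[, c("marker_id", "isotype", "source")],
                                  scale = "linear"),
                 meta = meta, truth = truth),
            class = "sim_cohort")
}

#' Attach marker-linked clinical outcomes to a simulated cohort
#'
#' For each association-ledger entry, draws the binary outcome as
#' `Bernoulli(plogis(beta0 + beta * x))` where `x` is the sample's
#' centered log2 level of the linked marker, for samples of the given
#' groups (clinical flags of other samples stay `NA`). A fraction
#' `missing_frac` of the generated flags is blanked to `NA`. Uses
#' `truth$rng_seed + 1` so it is deterministic and independent of the
#' cohort draw.
#'
#' @param sim a [simulate_cohort()] result.
#' @param associations association ledger; default the truth's.
#' @param missing_frac default the truth's.
#' @param groups groups receiving outcomes (default `"SjD"`).
#' @return The `sim_cohort` with outcome columns added to `$meta`.
#' @export
attach_clinical_outcomes <- function(sim, associations = NULL,
                                     missing_frac = NULL, groups = "SjD") {
  stopifnot(inherits(sim, "sim_cohort"))
  associations <- associations %||% sim$truth$associations
  if (is.null(associations)) stop("no association ledger")
  missing_frac <- missing_frac %||% sim$truth$missing_frac
  keys <- colnames(sim$mfi$values)
  bad <- setdiff(associations$marker_key, keys)
  if (length(bad))
    stop("association ledger references marker(s) absent from the matrix: ",
         paste(bad, collapse = ", "))
  centered <- median_center(log2_transform(sim$mfi))
  set.seed(offset_seed(sim$truth$rng_seed, 1))
  in_grp <- sim$meta$group %in% groups
  for (r in seq_len(nrow(associations))) {
    a <- associations[r, ]
    x <- centered$values[, a$marker_key]
    pr <- plogis(a$beta0 + a$beta * x)
    y <- rep(NA, length(x))
    y[in_grp] <- rbinom(sum(in_grp), 1L, pr[in_grp]) == 1L
    if (missing_frac > 0) {
      idx <- which(in_grp)
      drop <- idx[runif(length(idx)) < missing_frac]
      y[drop] <- NA
    }
    sim$meta[[a$outcome]] <- y
  }
  sim
}
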