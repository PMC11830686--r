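#' Canonical validation-study truths
#'
#' Two ready-made [sim_truth()] constructors encoding the planted-signal
#' scenarios used by the package's recovery and calibration studies.
#'
#' `planted_panel_truth()` describes a seronegative-panel scenario: three
#' complementary diagnostic markers with responder prevalences
#' `prevalences` in the (all Ro/SSA-negative) SjD group and 0.01
#' background seropositivity in HC, whose responder sets are made
#' pairwise disjoint at simulation time by [simulate_disjoint_cohort()],
#' among `n_null` markers with no responders anywhere. Background means
#' are 11 log2 MFI, sigma 0.5, responder effect 5 sigma.
#'
#' `planted_assoc_truth()` describes an association scenario: one marker
#' (`"AG001|IgA"`, responder prevalence 0.15 in SjD, effect 5 sigma)
#' carries a logistic association of strength `beta` with the outcome
#' `"pulmonary"`; `n_null` further markers are null.
#'
#' @param n_null number of null markers.
#' @param prevalences target-group responder prevalences of the three
#'   planted panel markers.
#' @param seed integer `rng_seed` of the truth.
#' @return A `sim_truth`.
#' @export
planted_panel_truth <- function(n_null = 50, prevalences = c(0.12, 0.10, 0.08),
                                seed = 1L) {
  stopifnot(length(prevalences) == 3L)
  p <- 3L + n_null
  markers <- data.frame(
    marker_id = sprintf("AG%03d", seq_len(p)),
    isotype = "IgG",
    source = "discovery",
    mu = 11, sigma = 0.5,
    effect = c(rep(2.5, 3L), rep(0, n_null)),
    stringsAsFactors = FALSE
  )
  prev <- matrix(0, p, 2L, dimnames = list(NULL, c("SjD", "HC")))
  prev[1:3, "SjD"] <- prevalences
  prev[1:3, "HC"] <- 0.01
  sim_truth(markers, prev, rng_seed = as.integer(seed))
}

#' @param beta logistic coefficient of the planted association (log-odds
#'   per centered log2 unit).
#' @param beta0 its intercept.
#' @param missing_frac fraction of flags blanked to `NA`.
#' @rdname planted_panel_truth
#' @export
planted_assoc_truth <- function(n_null = 50, beta = 1.0, beta0 = -1.0,
                                missing_frac = 0, seed = 1L) {
  p <- 1L + n_null
  markers <- data.frame(
    marker_id = sprintf("AG%03d", seq_len(p)),
    isotype = c("IgA", rep("IgG", n_null)),
    source = "discovery",
    mu = 11, sigma = 0.5,
    effect = c(2.5, rep(0, n_null)),
    stringsAsFactors = FALSE
  )
  prev <- matrix(0, p, 2L, dimnames = list(NULL, c("SjD", "HC")))
  prev[1L, "SjD"] <- 0.15
  assoc <- data.frame(marker_key = "AG001|IgA", outcome = "pulmonary",
                      beta = beta, beta0 = beta0, stringsAsFactors = FALSE)
  sim_truth(markers, prev, associations = assoc,
            missing_frac = missing_frac, rng_seed = as.integer(seed))
}

#' Simulate a cohort with pairwise-disjoint planted responder sets
#'
#' Like [simulate_cohort()], but re-assigns the responder indicators of
#' the first three markers within the SjD group so their responder sets
#' are pairwise disjoint (each sample responds to at most one of the
#' planted markers), keeping the marginal responder counts drawn from the
#' planted prevalences. This is the generative structure of a
#' complementary marker panel: low co-prevalence between its members.
#'
#' @param truth a [planted_panel_truth()].
#' @param n_per_group named group sizes (must include `SjD`).
#' @return A `sim_cohort` (see [simulate_cohort()]).
#' @export
simulate_disjoint_cohort <- function(truth, n_per_group) {
  sim <- simulate_cohort(truth, n_per_group)
  keys <- marker_key(truth$markers)[1:3]
  sjd <- which(sim$meta$group == "SjD")
  set.seed(offset_seed(truth$rng_seed, 2))
  counts <- rbinom(3L, length(sjd), truth$prevalence[1:3, "SjD"])
  if (sum(counts) > length(sjd))
    stop("planted responder counts exceed the SjD group size")
  pool <- sample(sjd)        # random disjoint allocation
  start <- cumsum(c(1L, counts[-3L]))
  for (k in 1:3) {
    idx <- pool[seq.int(start[k], length.out = counts[k])]
    delta <- integer(nrow(sim$meta))
    delta[idx] <- 1L
    old <- sim$truth$delta[sjd, keys[k]]
    new <- delta[sjd]
    # rebuild the signal component of the affected cells
    eff <- truth$markers$effect[k]
    col <- match(keys[k], colnames(sim$mfi$values))
    log2v <- log2(sim$mfi$values[sjd, col]) + (new - old) * eff
    sim$mfi$values[sjd, col] <- 2^log2v
    sim$truth$delta[sjd, keys[k]] <- new
  }
  sim
}
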