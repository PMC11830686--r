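#' Pipeline configuration
#'
#' Collects every scalar threshold used across the pipeline in one
#' validated object. The defaults are the operating points of the analysis
#' the package implements: a 75%-quantile low-reactivity pre-filter at
#' log2 MFI 10, screening at alpha = 0.05 with fold change >= 1.5,
#' SAM D-score >= 2 and quantile span >= 1 (log2 units), binarization
#' cutoffs at the 98% quantile of healthy controls (at most 2% positive
#' controls), panel selection with a 0.95 HC-specificity floor, and an
#' association effect-size filter at |coefficient| >= 0.45.
#'
#' @param prefilter_quantile fraction; quantile across all samples used by
#'   the low-reactivity pre-filter.
#' @param prefilter_threshold log2 MFI value a marker's pre-filter quantile
#'   must exceed to be retained.
#' @param prefilter logical; whether the pre-filter stage runs at all.
#' @param screen_alpha significance level for the univariate screens.
#' @param fold_change_min minimum case/control fold change (linear scale).
#' @param d_score_min minimum SAM d-statistic.
#' @param span_min minimum absolute quantile span (log2 units).
#' @param cutoff_quantile HC quantile defining the base binarization cutoff.
#' @param max_hc_positivity maximum tolerated fraction of positive healthy
#'   controls implied by `cutoff_quantile` (reporting/diagnostic use).
#' @param coef_min minimum absolute logistic coefficient for an association
#'   to pass the effect-size filter.
#' @param min_spec_hc HC specificity floor enforced during panel selection.
#' @param max_k maximum panel size for forward selection.
#' @param sam_s0 SAM fudge factor; `NULL` selects the median pooled
#'   standard error across screened markers.
#' @param n_perm number of label permutations for SAM significance when
#'   exhaustive enumeration is infeasible.
#' @param rng_seed integer seed driving every stochastic stage.
#'
#' @return An object of class `pipeline_config` (a validated named list).
#' @export
#' @examples
#' cfg <- pipeline_config(rng_seed = 42)
#' cfg$cutoff_quantile
pipeline_config <- function(prefilter_quantile = 0.75,
                            prefilter_threshold = 10,
                            prefilter = TRUE,
                            screen_alpha = 0.05,
                            fold_change_min = 1.5,
                            d_score_min = 2,
                            span_min = 1,
                            cutoff_quantile = 0.98,
                            max_hc_positivity = 0.02,
                            coef_min = 0.45,
                            min_spec_hc = 0.95,
                            max_k = 5,
                            sam_s0 = NULL,
                            n_perm = 1000,
                            rng_seed = 1L) {
  cfg <- list(
    prefilter_quantile = prefilter_quantile,
    prefilter_threshold = prefilter_threshold,
    prefilter = isTRUE(prefilter),
    screen_alpha = screen_alpha,
    fold_change_min = fold_change_min,
    d_score_min = d_score_min,
    span_min = span_min,
    cutoff_quantile = cutoff_quantile,
    max_hc_positivity = max_hc_positivity,
    coef_min = coef_min,
    min_spec_hc = min_spec_hc,
    max_k = as.integer(max_k),
    sam_s0 = sam_s0,
    n_perm = as.integer(n_perm),
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  fracs <- c("prefilter_quantile", "screen_alpha", "cutoff_quantile",
             "max_hc_positivity", "min_spec_hc")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
      stop(sprintf("config field '%s' must be a fraction in (0, 1)", f))
  }
  nonneg <- c("prefilter_threshold", "fold_change_min", "d_score_min",
              "span_min", "coef_min")
  for (f in nonneg) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0)
      stop(sprintf("config field '%s' must be a non-negative number", f))
  }
  if (!is.null(cfg$sam_s0) && (!is.numeric(cfg$sam_s0) || cfg$sam_s0 < 0))
    stop("config field 'sam_s0' must be NULL or a non-negative number")
  if (cfg$max_k < 1L) stop("config field 'max_k' must be >= 1")
  if (cfg$n_perm < 1L) stop("config field 'n_perm' must be >= 1")
  invisible(cfg)
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config()` returns a `pipeline_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' @param cfg a `pipeline_config` object.
#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("seropanel pipeline configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(x[[nm]])) "<auto>" else format(x[[nm]])))
  }
  invisible(x)
}
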