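#' Logistic regression of a binary outcome on one marker level
#'
#' Maximum-likelihood fit of `outcome ~ intercept + level` by iteratively
#' reweighted least squares (log-likelihood tolerance 1e-8, at most 100
#' iterations), with the Wald p-value for the level coefficient. Rows
#' with a missing outcome or level are dropped first (complete-case
#' analysis). Completely separated data are flagged non-estimable instead
#' of returning a silently diverging coefficient.
#'
#' @param outcome logical (or 0/1) outcome vector.
#' @param level numeric predictor, the centered log2 marker level.
#' @return A list: `coefficient` (log-odds per log2 unit), `se`,
#'   `p_value`, `intercept`, `n_complete`, `estimable`.
#' @export
fit_logistic <- function(outcome, level) {
  stopifnot(length(outcome) == length(level))
  if (is.numeric(outcome)) {
    if (!all(outcome %in% c(0, 1) | is.na(outcome)))
      stop("outcome must be binary")
    outcome <- outcome == 1
  }
  keep <- !is.na(outcome) & !is.na(level)
  y <- outcome[keep]; x <- level[keep]
  n <- length(y)
  if (n < 10L) stop("fewer than 10 complete cases")
  if (length(unique(y)) < 2L) stop("outcome has a single class after complete-case filtering")

  res <- list(coefficient = NA_real_, se = NA_real_, p_value = NA_real_,
              intercept = NA_real_, n_complete = n, estimable = FALSE)
  # complete separation is detectable directly for a single predictor
  if (min(x[y]) > max(x[!y]) || max(x[y]) < min(x[!y])) return(res)

  fit <- suppressWarnings(
    glm(y ~ x, family = binomial(),
        control = glm.control(epsilon = 1e-8, maxit = 100))
  )
  sm <- summary(fit)$coefficients
  if (!fit$converged || !all(is.finite(sm[, "Std. Error"])) ||
      sm["x", "Std. Error"] > 1e3)
    return(res)
  res$coefficient <- unname(sm["x", "Estimate"])
  res$se <- unname(sm["x", "Std. Error"])
  res$p_value <- unname(sm["x", "Pr(>|z|)"])
  res$intercept <- unname(sm["(Intercept)", "Estimate"])
  res$estimable <- TRUE
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment producing q-values:
#' `q_(i) = min over j >= i of m * p_(j) / j`, capped at 1, returned in
#' the original input order.
#'
#' @param p p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numbers in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Screen markers against binary clinical characteristics
#'
#' Per (marker, outcome) pair: complete-case logistic regression of the
#' outcome on the centered log2 marker level, Benjamini-Hochberg
#' adjustment across all markers within each outcome, and the combined
#' filter `p <= alpha` and `|coefficient| >= coef_min` that marks
#' associations as both statistically significant and of meaningful
#' effect size. Outcomes with fewer than 10 complete cases, or a single
#' observed class, are skipped with a warning.
#'
#' The predictor is the continuous centered level; set
#' `predictor = "binary"` to regress on binarized calls instead.
#'
#' @param m an [mfi_matrix()] with `scale = "log2_centered"`.
#' @param meta aligned metadata whose flag columns contain the outcomes.
#' @param outcomes character vector of flag column names to screen.
#' @param groups group label(s) whose samples enter the regression
#'   (clinical manifestations are patient properties; default `"SjD"`).
#' @param alpha significance level of the filter.
#' @param coef_min minimum absolute coefficient of the filter.
#' @param predictor `"level"` (default) or `"binary"`.
#' @param binary a [binarize()] result, required when
#'   `predictor = "binary"`.
#' @return An `association_result` data frame: one row per (marker,
#'   outcome) with `n_complete`, `coefficient`, `se`, `p`, `q`,
#'   `ci_lower`, `ci_upper` (Wald 95%), `estimable`, `passes_filter` —
#'   forest-plot-ready.
#' @export
association_screen <- function(m, meta, outcomes, groups = "SjD",
                               alpha = 0.05, coef_min = 0.45,
                               predictor = c("level", "binary"),
                               binary = NULL) {
  stopifnot(inherits(m, "mfi_matrix"), nrow(meta) == nrow(m$values))
  if (m$scale != "log2_centered")
    stop("association_screen expects the centered log2 analysis scale")
  predictor <- match.arg(predictor)
  missing <- setdiff(outcomes, names(meta))
  if (length(missing))
    stop("outcome(s) absent from metadata: ", paste(missing, collapse = ", "))
  X <- if (predictor == "level") m$values else {
    if (is.null(binary)) stop("predictor = 'binary' needs a binary matrix")
    b <- binary$calls[, colnames(m$values), drop = FALSE]
    storage.mode(b) <- "double"
    b
  }
  in_grp <- meta$group %in% groups
  keys <- colnames(X)
  out <- list()
  for (oc in outcomes) {
    y <- meta[[oc]][in_grp]
    ycc <- y[!is.na(y)]
    if (length(ycc) < 10L || length(unique(ycc)) < 2L) {
      warning("outcome '", oc, "' skipped: ",
              if (length(ycc) < 10L) "fewer than 10 complete cases"
              else "single observed class")
      next
    }
    fits <- lapply(keys, function(k) fit_logistic(y, X[in_grp, k]))
    df <- data.frame(
      marker_key = keys,
      outcome = oc,
      n_complete = vapply(fits, `[[`, 0L, "n_complete"),
      coefficient = vapply(fits, `[[`, 0, "coefficient"),
      se = vapply(fits, `[[`, 0, "se"),
      p = vapply(fits, `[[`, 0, "p_value"),
      estimable = vapply(fits, `[[`, TRUE, "estimable"),
      stringsAsFactors = FALSE
    )
    df$q <- NA_real_
    est <- df$estimable
    if (any(est)) df$q[est] <- bh_adjust(df$p[est])
    df$ci_lower <- df$coefficient - 1.96 * df$se
    df$ci_upper <- df$coefficient + 1.96 * df$se
    df$passes_filter <- est & df$p <= alpha & abs(df$coefficient) >= coef_min
    out[[oc]] <- df
  }
  if (!length(out)) stop("no usable outcome")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("association_result", "data.frame")
  res
}
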