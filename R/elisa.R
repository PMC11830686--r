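#' ELISA standard curve
#'
#' A ladder of exactly five calibration standards spanning 2.5 to 40 U/ml
#' (the kit convention for the muscarinic receptor M3/M5 assays), with
#' strictly increasing concentrations and strictly monotone optical
#' densities.
#'
#' @param concentration standard concentrations in U/ml, increasing.
#' @param response measured OD values of the standards; strictly monotone
#'   (either direction, depending on assay format).
#' @return An object of class `standard_curve`.
#' @export
standard_curve <- function(concentration = c(2.5, 5, 10, 20, 40), response) {
  if (length(concentration) != 5L || length(response) != 5L)
    stop("a standard curve has exactly 5 ladder points")
  if (any(diff(concentration) <= 0))
    stop("standard concentrations must be strictly increasing")
  d <- diff(response)
  if (!(all(d > 0) || all(d < 0)))
    stop("standard responses must be strictly monotone")
  structure(list(concentration = concentration, response = response,
                 increasing = all(d > 0),
                 range = range(concentration)),
            class = "standard_curve")
}

#' Quantify ELISA titers from a standard curve
#'
#' Interpolates OD readings to concentrations by piecewise linear
#' interpolation on the (log2 concentration, response) plane, i.e.
#' log-linear interpolation between neighbouring standards. Readings
#' outside the ladder are censored rather than extrapolated: below the
#' lowest standard the titer is flagged `"<2.5"`, above the highest
#' `">40"` (bounds taken from the curve). Censored titers are `NA` so
#' they cannot silently enter cutoff calibration.
#'
#' @param od numeric vector of sample OD readings.
#' @param curve a [standard_curve()].
#' @return A `data.frame` with columns `od`, `titer` (U/ml, `NA` when
#'   censored) and `flag` (`"ok"`, `"<lo"`-style or `">hi"`-style).
#' @export
elisa_quantify <- function(od, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  resp <- curve$response
  conc <- curve$concentration
  if (!curve$increasing) {          # align so response increases with conc
    resp <- rev(resp)
    conc <- rev(conc)
  }
  lo_flag <- sprintf("<%g", curve$range[1L])
  hi_flag <- sprintf(">%g", curve$range[2L])
  titer <- 2^approx(x = resp, y = log2(conc), xout = od, rule = 1)$y
  flag <- rep("ok", length(od))
  below <- od < min(resp)
  above <- od > max(resp)
  # censoring flags follow the concentration axis: on a decreasing
  # (competitive) curve a low response means a high concentration
  if (conc[1L] < conc[length(conc)]) {
    flag[below] <- lo_flag
    flag[above] <- hi_flag
  } else {
    flag[below] <- hi_flag
    flag[above] <- lo_flag
  }
  titer[below | above] <- NA_real_
  data.frame(od = od, titer = titer, flag = flag, stringsAsFactors = FALSE)
}

#' @importFrom stats approx
NULL
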