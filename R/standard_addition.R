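#' Fit a standard-addition line
#'
#' Ordinary least squares of the response ratio on the spiked amount
#' (ug of analyte per g of food). The series must contain the unspiked pool
#' (spike 0) and at least one spiked level; the slope is the matrix
#' sensitivity in response per ug/g and the x-axis intercept magnitude is the
#' native concentration.
#'
#' @param series data.frame with numeric columns `spike_level` (ug/g) and
#'   `response_ratio`.
#' @return a `calibration_fit` (slope in response per ug/g).
#' @export
fit_addition <- function(series) {
  assert_columns(series, c("spike_level", "response_ratio"),
                 "standard-addition series")
  if (any(series$spike_level < 0)) stop_domain("spike levels must be >= 0")
  if (!any(series$spike_level == 0))
    stop_domain("standard-addition series must include the unspiked pool (spike 0)")
  .fit_line(series$spike_level, series$response_ratio, xlab = "spike level")
}

#' Native concentration from a standard-addition fit
#'
#' The standard-addition estimate is the magnitude of the x-axis intercept,
#' `intercept / slope`. Because a multiplicative matrix effect scales slope
#' and intercept alike, the ratio is invariant to it. A negative fitted
#' intercept (native signal below the blank/baseline) is floored at zero with
#' a warning rather than reported as a negative concentration.
#'
#' @param fit a `calibration_fit` from [fit_addition()].
#' @return native concentration in ug/g.
#' @export
#' @examples
#' native_concentration(fit_addition(data.frame(
#'   spike_level = c(0, 1), response_ratio = c(1, 2))))  # 1
native_concentration <- function(fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (!is.finite(fit$slope) || fit$slope <= 0)
    stop_domain("non-quantifiable series: standard-addition slope must be > 0")
  if (fit$intercept < 0) {
    warning("fitted intercept is negative (response below baseline); ",
            "reporting concentration 0")
    return(0)
  }
  fit$intercept / fit$slope
}

#' Recovery from the slope ratio of matrix and solvent lines
#'
#' The extraction recovery (including any matrix effect on sensitivity) is
#' the standard-addition slope divided by the solvent calibration slope, in
#' percent, once both are expressed per ug/g of sample: a solvent slope in
#' response per ug/mL corresponds to `slope_solvent / extract_factor` per
#' ug/g.
#'
#' @param slope_matrix standard-addition slope, response per ug/g.
#' @param slope_solvent solvent calibration slope, response per ug/mL (> 0).
#' @param units a [units_config()].
#' @return recovery in percent.
#' @export
#' @examples
#' recovery_percent(1.0, 1.0)          # 100
#' recovery_percent(0.72, 1.0)         # 72
recovery_percent <- function(slope_matrix, slope_solvent,
                             units = units_config()) {
  stopifnot(inherits(units, "units_config"))
  if (!is.finite(slope_solvent) || slope_solvent <= 0)
    stop_domain("solvent calibration slope must be > 0")
  100 * slope_matrix / (slope_solvent / units$extract_factor)
}

#' Procedural-blank subtraction
#'
#' Background contamination (ubiquitous phthalates in particular) measured in
#' the procedural blank is subtracted from the measured food concentration,
#' floored at zero.
#'
#' @param c measured concentration, ug/g (>= 0).
#' @param c_blank procedural-blank concentration, ug/g (>= 0).
#' @return blank-corrected concentration, ug/g.
#' @export
blank_subtract <- function(c, c_blank) {
  if (any(c < 0) || any(c_blank < 0))
    stop_domain("concentrations must be >= 0")
  pmax(c - c_blank, 0)
}

#' Left-censoring of non-quantifiable results (GEMS/Food-EURO)
#'
#' Results at or above the LOQ are reported as measured. Non-quantifiable
#' results between LOD and LOQ are substituted with LOQ/2. Results below the
#' LOD are substituted with 0 under the default lower-bound policy, or with
#' LOD/2 under the middle-bound policy.
#'
#' @param c blank-corrected concentration, ug/g (>= 0); may be vectorised.
#' @param lod,loq limits in sample units (ug/g), `lod < loq`.
#' @param below_lod substitution policy for results below the LOD: `"zero"`
#'   (default, lower bound) or `"half_lod"` (middle bound).
#' @return list with `reported_value` and `censor_status` (one of
#'   `quantified`, `below_loq`, `below_lod`), vectorised over `c`.
#' @export
#' @examples
#' censor_value(0.015, lod = 0.01, loq = 0.025)  # LOQ/2 = 0.0125, below_loq
censor_value <- function(c, lod, loq, below_lod = c("zero", "half_lod")) {
  below_lod <- match.arg(below_lod)
  if (!is.finite(lod) || !is.finite(loq) || lod >= loq)
    stop_validation("censoring limits must satisfy lod < loq")
  if (any(c < 0)) stop_domain("concentrations must be >= 0")
  status <- ifelse(c >= loq, "quantified",
                   ifelse(c >= lod, "below_loq", "below_lod"))
  value <- ifelse(status == "quantified", c,
                  ifelse(status == "below_loq", loq / 2,
                         if (below_lod == "zero") 0 else lod / 2))
  list(reported_value = value, censor_status = status)
}

#' Quantify one analyte in one pool by standard addition
#'
#' Chains the stages in the order quantify -> blank-subtract -> censor: fits
#' the standard-addition line, takes the x-intercept magnitude as the raw
#' native concentration, quantifies the procedural blank the same way when a
#' blank series is given, subtracts it, and applies left-censoring against
#' the analyte's limits converted to sample units. Recovery is computed from
#' the slope ratio when a solvent slope is given.
#'
#' @param series standard-addition data.frame (`spike_level`,
#'   `response_ratio`) for the pool.
#' @param blank_series optional standard-addition data.frame for the
#'   procedural blank in the same batch.
#' @param lod_extract,loq_extract limits in extract units (ug/mL).
#' @param slope_solvent optional solvent calibration slope (response per
#'   ug/mL) for recovery.
#' @param units a [units_config()].
#' @param below_lod censoring policy, see [censor_value()].
#' @return one-row data.frame: `raw_estimate`, `blank_estimate`, `corrected`,
#'   `censor_status`, `reported_value` (ug/g), `recovery_percent`.
#' @export
quantify_pool <- function(series, blank_series = NULL,
                          lod_extract, loq_extract,
                          slope_solvent = NULL,
                          units = units_config(),
                          below_lod = c("zero", "half_lod")) {
  below_lod <- match.arg(below_lod)
  fit <- fit_addition(series)
  raw <- native_concentration(fit)
  blank <- if (!is.null(blank_series))
    native_concentration(fit_addition(blank_series)) else 0
  corrected <- blank_subtract(raw, blank)
  lod_s <- extract_to_sample_units(lod_extract, units)
  loq_s <- extract_to_sample_units(loq_extract, units)
  cen <- censor_value(corrected, lod_s, loq_s, below_lod = below_lod)
  rec <- if (!is.null(slope_solvent))
    recovery_percent(fit$slope, slope_solvent, units) else NA_real_
  data.frame(raw_estimate = raw,
             blank_estimate = blank,
             corrected = corrected,
             censor_status = cen$censor_status,
             reported_value = cen$reported_value,
             recovery_percent = rec,
             stringsAsFactors = FALSE)
}

#' Apply censoring substitution to a pooled-concentration table
#'
#' Adds a `reported_value` column to a concentration table: quantified rows
#' keep their corrected value; `below_loq` rows receive LOQ/2 and `below_lod`
#' rows the below-LOD substitute, using each analyte's limits converted to
#' sample units.
#'
#' @param concentrations data.frame as from [read_concentration_table()].
#' @param analytes analyte specification data.frame (for LOD/LOQ).
#' @param units a [units_config()].
#' @param below_lod censoring policy, see [censor_value()].
#' @return the concentration table with a `reported_value` column (ug/g).
#' @export
apply_censoring <- function(concentrations, analytes = default_analytes(),
                            units = units_config(),
                            below_lod = c("zero", "half_lod")) {
  below_lod <- match.arg(below_lod)
  assert_columns(concentrations, c("analyte", "corrected", "censor_status"),
                 "concentration table")
  idx <- match(concentrations$analyte, analytes$name)
  if (anyNA(idx))
    stop_validation("analyte(s) missing from specification table: ",
                    paste(unique(concentrations$analyte[is.na(idx)]),
                          collapse = ", "))
  lod_s <- extract_to_sample_units(analytes$lod_extract[idx], units)
  loq_s <- extract_to_sample_units(analytes$loq_extract[idx], units)
  out <- concentrations
  out$reported_value <- NA_real_
  q <- concentrations$censor_status == "quantified"
  out$reported_value[q] <- concentrations$corrected[q]
  bq <- concentrations$censor_status == "below_loq"
  out$reported_value[bq] <- loq_s[bq] / 2
  bd <- concentrations$censor_status == "below_lod"
  out$reported_value[bd] <- if (below_lod == "zero") 0 else lod_s[bd] / 2
  out
}
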