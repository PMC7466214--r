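#' Fit an external (solvent) calibration line
#'
#' Ordinary least squares of the internal-standard-normalised response ratio
#' on nominal concentration, through all replicate injections. Unweighted, as
#' is conventional for simple linear GC-MS calibration over a narrow range.
#'
#' @param series data.frame with numeric columns `concentration` (ug/mL) and
#'   `response_ratio`; replicate rows at a level are treated as independent
#'   points.
#' @return an object of class `calibration_fit`: list with `slope`
#'   (response per ug/mL), `intercept`, `r_squared`, `n_points`.
#' @export
#' @examples
#' s <- data.frame(concentration = c(0, 0.5, 1), response_ratio = c(0, 0.5, 1))
#' fit_calibration(s)$slope  # 1
fit_calibration <- function(series) {
  assert_columns(series, c("concentration", "response_ratio"),
                 "calibration series")
  x <- series$concentration
  y <- series$response_ratio
  if (any(x < 0)) stop_domain("calibration concentrations must be >= 0")
  .fit_line(x, y, xlab = "concentration")
}

# shared OLS core for calibration and standard-addition lines; stats::lm is
# the fitting engine, R^2 taken from the model summary
.fit_line <- function(x, y, xlab = "x") {
  if (length(x) != length(y) || length(x) < 2)
    stop_domain("need >= 2 (", xlab, ", response) points")
  if (length(unique(x)) < 2)
    stop_domain("degenerate design: all ", xlab, " values identical")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  # coefficient of determination; a flat response with zero residuals is a
  # perfect (if degenerate) fit
  r2 <- if (ss_tot == 0) as.numeric(ss_res == 0) else 1 - ss_res / ss_tot
  r2 <- min(max(r2, 0), 1)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n_points = length(x)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("calibration_fit: y = %.6gx %+.6g  (R2 = %.6g, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Estimate LOD and LOQ from a signal-to-noise dilution series
#'
#' The LOQ is the lowest tested concentration whose quantification-ion
#' signal-to-noise is strictly above `sn_quant_threshold` (default 10); the
#' LOD is the lowest concentration whose qualifier-ion signal-to-noise is
#' strictly above `sn_qual_threshold` (default 3). A limit whose threshold is
#' never exceeded is returned as `NA` with its `*_reached` flag `FALSE`.
#'
#' @param sn_series data.frame with columns `concentration` (ug/mL, sorted
#'   ascending), `sn_quant`, `sn_qual`.
#' @param sn_quant_threshold S/N threshold on the quantification ion (LOQ).
#' @param sn_qual_threshold S/N threshold on the qualifier ion (LOD).
#' @return list with `lod`, `loq` (ug/mL or NA), `lod_reached`,
#'   `loq_reached`, and the thresholds used.
#' @export
estimate_lod_loq <- function(sn_series, sn_quant_threshold = 10,
                             sn_qual_threshold = 3) {
  assert_columns(sn_series, c("concentration", "sn_quant", "sn_qual"),
                 "signal-to-noise series")
  if (nrow(sn_series) < 1) stop_domain("signal-to-noise series is empty")
  if (is.unsorted(sn_series$concentration, strictly = FALSE))
    stop_domain("signal-to-noise series must be sorted ascending by concentration")
  pick <- function(sn, thr) {
    i <- which(sn > thr)
    if (length(i)) sn_series$concentration[min(i)] else NA_real_
  }
  loq <- pick(sn_series$sn_quant, sn_quant_threshold)
  lod <- pick(sn_series$sn_qual, sn_qual_threshold)
  if (!is.na(lod) && !is.na(loq) && lod > loq)
    warning("estimated LOD exceeds LOQ; check the S/N series")
  list(lod = lod, loq = loq,
       lod_reached = !is.na(lod), loq_reached = !is.na(loq),
       sn_quant_threshold = sn_quant_threshold,
       sn_qual_threshold = sn_qual_threshold)
}

#' Repeatability precision as a relative standard deviation
#'
#' RSDr in percent from replicate determinations at a single level
#' (conventionally n = 8 independent solutions measured within one day):
#' `100 * sd(values) / mean(values)`.
#'
#' @param values numeric vector of replicate estimates (n >= 2).
#' @return list with `rsd_percent` and `n`.
#' @export
#' @examples
#' repeatability_rsd(c(0.09, 0.10, 0.11))$rsd_percent  # 10
repeatability_rsd <- function(values) {
  if (length(values) < 2) stop_domain("need >= 2 replicate values")
  if (any(!is.finite(values))) stop_domain("replicate values must be finite")
  m <- mean(values)
  if (m == 0) stop_domain("mean of replicates is zero; RSD undefined")
  list(rsd_percent = 100 * stats::sd(values) / abs(m), n = length(values))
}
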