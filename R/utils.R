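#' Round half-up to a number of significant figures
#'
#' Reported concentrations and exposures are displayed at three significant
#' figures with conventional half-up tie-breaking (0.0615 -> 0.0615, but a
#' value whose rounding digit is exactly 5 rounds away from zero, unlike
#' [base::signif()], which rounds half to even). Internal computation is never
#' rounded; this helper is applied at the reporting boundary only.
#'
#' @param x numeric vector.
#' @param digits number of significant figures (default 3).
#' @return numeric vector rounded half-up to `digits` significant figures.
#' @export
#' @examples
#' signif_half_up(0.061827)   # 0.0618
#' signif_half_up(1.012368)   # 1.01
signif_half_up <- function(x, digits = 3) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 1)
  out <- x
  nz <- is.finite(x) & x != 0
  if (any(nz)) {
    e <- floor(log10(abs(x[nz]))) + 1
    f <- 10^(digits - e)
    # nudge by a relative epsilon so values stored as 0.49999... ties still
    # round up; magnitudes here are far above double precision granularity
    out[nz] <- sign(x[nz]) * floor(abs(x[nz]) * f + 0.5 + 1e-9) / f
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) {
  stop(structure(class = c("fcm_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_schema <- function(...) {
  stop(structure(class = c("fcm_schema_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_validation <- function(...) {
  stop(structure(class = c("fcm_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_schema(what, ": missing required column(s): ",
                paste(missing, collapse = ", "))
  invisible(df)
}
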