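#' Configuration of a synthetic GC-MS measurement study
#'
#' Defines the generating model for a full measurement bundle: per-analyte
#' solvent sensitivities (slope/intercept of the internal-standard response
#' line), per-pool true native concentrations, multiplicative recovery
#' fractions, additive procedural-blank contamination, and a constant-CV
#' multiplicative repeatability noise on the response ratio.
#'
#' Defaults reproduce the bundled study conditions: the eight target
#' migrants with their fitted solvent calibration parameters, true pool
#' concentrations equal to the bundled pooled-concentration table (with a
#' non-quantifiable DNOP placed between LOD and LOQ at 0.015 ug/g), the
#' observed per-pool recoveries (0.72-1.18), no blank contamination, 5%
#' repeatability CV, triplicate calibration injections and duplicate
#' unspiked-pool analyses.
#'
#' @param calibration data.frame with `name`, `slope`, `intercept` (response
#'   ratio per ug/mL); defaults to [default_calibration_params()].
#' @param truth data.frame with `analyte`, `age_group`,
#'   `true_concentration` (ug/g), `recovery_fraction`,
#'   `blank_concentration` (ug/g); defaults built from
#'   [default_concentrations()].
#' @param cv_repeatability fractional CV of the multiplicative response
#'   noise (>= 0).
#' @param calibration_levels ug/mL levels for the solvent calibration.
#' @param calibration_replicates injections per calibration level.
#' @param spike_levels ug/g standard-addition design, including 0.
#' @param unspiked_replicates replicate analyses of the unspiked pool.
#' @param units a [units_config()].
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(calibration = default_calibration_params(),
                             truth = default_truth(),
                             cv_repeatability = 0.05,
                             calibration_levels = c(0.0025, 0.005, 0.01,
                                                    0.025, 0.05, 0.1, 0.25,
                                                    0.5, 1, 2),
                             calibration_replicates = 3L,
                             spike_levels = c(0, 0.05, 0.1, 0.25, 0.5),
                             unspiked_replicates = 2L,
                             units = units_config()) {
  assert_columns(calibration, c("name", "slope", "intercept"),
                 "calibration parameters")
  assert_columns(truth, c("analyte", "age_group", "true_concentration",
                          "recovery_fraction", "blank_concentration"),
                 "truth table")
  if (any(calibration$slope <= 0))
    stop_validation("sensitivity slopes must be > 0")
  if (any(truth$recovery_fraction <= 0))
    stop_validation("recovery fractions must be > 0")
  if (any(truth$true_concentration < 0) || any(truth$blank_concentration < 0))
    stop_validation("true and blank concentrations must be >= 0")
  if (cv_repeatability < 0) stop_validation("cv_repeatability must be >= 0")
  if (any(calibration_levels < 0)) stop_validation("levels must be >= 0")
  if (!0 %in% spike_levels)
    stop_validation("spike design must include the unspiked pool (0)")
  if (calibration_replicates < 1 || unspiked_replicates < 1)
    stop_validation("replicate counts must be >= 1")
  missing <- setdiff(truth$analyte, calibration$name)
  if (length(missing))
    stop_validation("no calibration parameters for analyte(s): ",
                    paste(missing, collapse = ", "))
  structure(list(calibration = calibration, truth = truth,
                 cv_repeatability = cv_repeatability,
                 calibration_levels = calibration_levels,
                 calibration_replicates = as.integer(calibration_replicates),
                 spike_levels = spike_levels,
                 unspiked_replicates = as.integer(unspiked_replicates),
                 units = units),
            class = "synthetic_config")
}

#' Default ground-truth table for the synthetic study
#'
#' True pool concentrations equal to the bundled pooled concentrations;
#' the censored DNOP pools are assigned a true concentration of 0.015 ug/g
#' (between its LOD of 0.01 and LOQ of 0.025 ug/g in sample units, so a
#' faithful pipeline reports them below the LOQ). Recovery fractions are the
#' observed per-pool slope-ratio recoveries; blank contamination defaults
#' to 0.
#'
#' @return data.frame with `analyte`, `age_group`, `true_concentration`,
#'   `recovery_fraction`, `blank_concentration`.
#' @export
default_truth <- function() {
  conc <- default_concentrations()
  truth <- data.frame(analyte = conc$analyte,
                      age_group = conc$age_group,
                      true_concentration = conc$corrected,
                      recovery_fraction = conc$recovery_percent / 100,
                      blank_concentration = 0,
                      stringsAsFactors = FALSE)
  truth$true_concentration[is.na(truth$true_concentration)] <- 0.015
  truth
}

# deterministic sub-stream seed for (study seed, analyte index, pool index),
# kept within the 32-bit integer range
.substream_seed <- function(seed, analyte_idx, pool_idx = 0L) {
  (as.numeric(seed) * 48271 + analyte_idx * 1009 + pool_idx * 97) %%
    2147483629
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  force(code)
}

.apply_noise <- function(y, cv, n) {
  if (cv == 0) return(y)
  y * (1 + stats::rnorm(n, mean = 0, sd = cv))
}

#' Simulate a solvent calibration series
#'
#' Response ratios follow the linear sensitivity model
#' `y = slope * x + intercept`, multiplied by `(1 + eps)` with `eps` a
#' mean-zero Gaussian of the stated CV (constant across levels, matching
#' RSD-style precision reporting).
#'
#' @param analyte analyte name carried through to the output.
#' @param slope,intercept solvent sensitivity (response per ug/mL).
#' @param levels ug/mL concentrations (non-empty, >= 0).
#' @param cv fractional repeatability CV.
#' @param replicates injections per level (default triplicate).
#' @param seed integer seed; identical seeds give identical series.
#' @return data.frame with `analyte`, `concentration`, `replicate`,
#'   `response_ratio`.
#' @export
generate_calibration_series <- function(analyte, slope, intercept, levels,
                                        cv = 0.05, replicates = 3L,
                                        seed = 1L) {
  if (length(levels) < 1) stop_domain("levels must be non-empty")
  if (any(levels < 0)) stop_domain("levels must be >= 0")
  if (slope <= 0) stop_validation("slope must be > 0")
  if (cv < 0 || replicates < 1)
    stop_validation("cv must be >= 0 and replicates >= 1")
  x <- rep(levels, each = replicates)
  mu <- slope * x + intercept
  y <- .with_seed(seed, .apply_noise(mu, cv, length(mu)))
  data.frame(analyte = analyte,
             concentration = x,
             replicate = rep(seq_len(replicates), times = length(levels)),
             response_ratio = y,
             stringsAsFactors = FALSE)
}

#' Simulate a standard-addition series for one pool
#'
#' The matrix response at spike level s is
#' `slope * recovery * (true + blank + s) / extract_factor`, times the same
#' multiplicative noise as the calibration model. The matrix line carries no
#' solvent-calibration intercept: the response of the extracted food is
#' proportional to the amount of analyte recovered, which is what makes the
#' x-intercept of the fitted line equal the native (plus blank)
#' concentration for any recovery fraction.
#'
#' @param analyte,pool_id labels carried through to the output.
#' @param slope solvent sensitivity, response per ug/mL (> 0).
#' @param recovery multiplicative recovery fraction (> 0).
#' @param true_concentration native pool concentration, ug/g.
#' @param blank_concentration additive batch contamination, ug/g.
#' @param spike_levels ug/g design including 0.
#' @param cv fractional repeatability CV.
#' @param unspiked_replicates replicates of the spike-0 analysis (spiked
#'   levels are analysed once, as in the standard protocol).
#' @param seed integer seed.
#' @param units a [units_config()].
#' @return data.frame with `analyte`, `pool_id`, `spike_level`, `replicate`,
#'   `response_ratio`.
#' @export
generate_addition_series <- function(analyte, pool_id, slope, recovery,
                                     true_concentration,
                                     blank_concentration = 0,
                                     spike_levels = c(0, 0.05, 0.1, 0.25, 0.5),
                                     cv = 0.05, unspiked_replicates = 2L,
                                     seed = 1L, units = units_config()) {
  if (!0 %in% spike_levels)
    stop_domain("spike design must include the unspiked pool (0)")
  if (any(spike_levels < 0)) stop_domain("spike levels must be >= 0")
  if (slope <= 0 || recovery <= 0)
    stop_validation("slope and recovery must be > 0")
  if (true_concentration < 0 || blank_concentration < 0)
    stop_validation("concentrations must be >= 0")
  reps <- ifelse(spike_levels == 0, unspiked_replicates, 1L)
  x <- rep(spike_levels, times = reps)
  mu <- slope * recovery *
    (true_concentration + blank_concentration + x) / units$extract_factor
  y <- .with_seed(seed, .apply_noise(mu, cv, length(mu)))
  data.frame(analyte = analyte,
             pool_id = pool_id,
             spike_level = x,
             replicate = unlist(lapply(reps, seq_len)),
             response_ratio = y,
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic measurement bundle
#'
#' One solvent calibration series per analyte and one standard-addition
#' series per analyte x pool, plus matching procedural-blank addition series
#' (sharing the batch's blank contamination, so blank subtraction removes it
#' in expectation), and the complete generating configuration as ground
#' truth. Sub-stream seeds are derived deterministically from
#' `(seed, analyte index, pool index)`, so any slice of the bundle is
#' reproducible on its own.
#'
#' @param config a [synthetic_config()].
#' @param seed integer study seed.
#' @param dir optional directory; when given, writes `calibration.csv`,
#'   `additions.csv`, `blanks.csv` and `truth.json` there.
#' @return (invisibly when writing) a list with elements `calibration`,
#'   `additions`, `blanks` (data.frames) and `truth` (the generating
#'   parameters, including the seed).
#' @export
generate_study <- function(config = synthetic_config(), seed = 1L,
                           dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  analytes <- config$calibration$name
  cal <- do.call(rbind, lapply(seq_along(analytes), function(i) {
    generate_calibration_series(
      analyte = analytes[i],
      slope = config$calibration$slope[i],
      intercept = config$calibration$intercept[i],
      levels = config$calibration_levels,
      cv = config$cv_repeatability,
      replicates = config$calibration_replicates,
      seed = .substream_seed(seed, i, 0L))
  }))
  pools <- unique(config$truth$age_group)
  series <- function(blank_only) {
    do.call(rbind, lapply(seq_len(nrow(config$truth)), function(k) {
      row <- config$truth[k, ]
      i <- match(row$analyte, analytes)
      j <- match(row$age_group, pools)
      generate_addition_series(
        analyte = row$analyte,
        pool_id = row$age_group,
        slope = config$calibration$slope[i],
        recovery = row$recovery_fraction,
        true_concentration = if (blank_only) 0 else row$true_concentration,
        blank_concentration = row$blank_concentration,
        spike_levels = config$spike_levels,
        cv = config$cv_repeatability,
        unspiked_replicates = config$unspiked_replicates,
        seed = .substream_seed(seed, i, j + if (blank_only) 1000L else 0L),
        units = config$units)
    }))
  }
  additions <- series(blank_only = FALSE)
  blanks <- series(blank_only = TRUE)
  truth <- list(seed = seed,
                cv_repeatability = config$cv_repeatability,
                spike_levels = config$spike_levels,
                calibration_levels = config$calibration_levels,
                extract_factor = config$units$extract_factor,
                calibration = config$calibration,
                truth = config$truth)
  out <- list(calibration = cal, additions = additions, blanks = blanks,
              truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(cal, file.path(dir, "calibration.csv"),
                     row.names = FALSE)
    utils::write.csv(additions, file.path(dir, "additions.csv"),
                     row.names = FALSE)
    utils::write.csv(blanks, file.path(dir, "blanks.csv"), row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    return(invisible(out))
  }
  out
}
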