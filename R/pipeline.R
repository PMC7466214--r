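#' Run configuration for the full pipeline
#'
#' Collects input tables and policy switches; every policy defaults to the
#' bundled study conditions (LOQ/2 substitution between LOD and LOQ, zero
#' below the LOD, body-weight-normalised intakes, 1 g -> 1 mL extraction).
#'
#' @param analytes analyte specification data.frame.
#' @param consumption consumption data.frame.
#' @param concentrations optional pooled-concentration data.frame; when NULL
#'   the pipeline expects measurement series via `additions`/`blanks`.
#' @param additions,blanks optional standard-addition (and procedural-blank)
#'   measurement data.frames.
#' @param calibration optional solvent calibration measurement data.frame
#'   (long format); when given, solvent slopes are fitted from it, otherwise
#'   `calibration_params` supplies them.
#' @param calibration_params data.frame with `name`, `slope` used for
#'   recovery when no raw calibration series is given.
#' @param inventory optional screening-inventory data.frame.
#' @param units a [units_config()].
#' @param below_lod censoring policy, see [censor_value()].
#' @param risk a [risk_config()].
#' @param ttc a [ttc_config()] or NULL to skip TTC screening.
#' @param seed integer seed recorded in outputs.
#' @return an object of class `run_config`.
#' @export
run_config <- function(analytes = default_analytes(),
                       consumption = default_consumption(),
                       concentrations = NULL,
                       additions = NULL, blanks = NULL,
                       calibration = NULL,
                       calibration_params = default_calibration_params(),
                       inventory = NULL,
                       units = units_config(),
                       below_lod = c("zero", "half_lod"),
                       risk = risk_config(),
                       ttc = NULL,
                       seed = 1L) {
  below_lod <- match.arg(below_lod)
  if (is.null(concentrations) && is.null(additions))
    stop_validation("provide either a concentration table or addition series")
  structure(list(analytes = analytes, consumption = consumption,
                 concentrations = concentrations, additions = additions,
                 blanks = blanks, calibration = calibration,
                 calibration_params = calibration_params,
                 inventory = inventory, units = units,
                 below_lod = below_lod, risk = risk, ttc = ttc,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Fit solvent calibrations for every analyte in a long series table
#'
#' @param calibration data.frame as from [read_calibration_table()].
#' @return data.frame with `name`, `slope`, `intercept`, `r_squared`,
#'   `n_points`.
#' @export
fit_all_calibrations <- function(calibration) {
  assert_columns(calibration, c("analyte", "concentration", "response_ratio"),
                 "calibration table")
  do.call(rbind, lapply(split(calibration, calibration$analyte), function(d) {
    f <- fit_calibration(d)
    data.frame(name = d$analyte[1], slope = f$slope,
               intercept = f$intercept, r_squared = f$r_squared,
               n_points = f$n_points, stringsAsFactors = FALSE)
  }))
}

#' Quantify every analyte x pool from standard-addition series
#'
#' Splits a long addition table by analyte and pool, pairs each series with
#' its procedural blank (same analyte and pool) when available, and runs
#' [quantify_pool()] with the analyte's limits and solvent slope.
#'
#' @param additions long addition data.frame (`analyte`, `pool_id`,
#'   `spike_level`, `replicate`, `response_ratio`).
#' @param blanks optional blank addition data.frame of the same shape.
#' @param analytes analyte specification data.frame.
#' @param calibration_params data.frame with `name`, `slope`.
#' @param units a [units_config()].
#' @param below_lod censoring policy.
#' @return data.frame with one row per analyte x pool, columns as in
#'   [quantify_pool()] plus `analyte` and `age_group`.
#' @export
quantify_study <- function(additions, blanks = NULL,
                           analytes = default_analytes(),
                           calibration_params = default_calibration_params(),
                           units = units_config(),
                           below_lod = c("zero", "half_lod")) {
  below_lod <- match.arg(below_lod)
  assert_columns(additions, c("analyte", "pool_id", "spike_level",
                              "response_ratio"), "addition table")
  groups <- split(additions,
                  list(additions$analyte, additions$pool_id), drop = TRUE)
  rows <- lapply(groups, function(d) {
    an <- d$analyte[1]; pool <- d$pool_id[1]
    spec <- analytes[analytes$name == an, , drop = FALSE]
    if (nrow(spec) != 1)
      stop_validation("no specification for analyte ", an)
    bl <- NULL
    if (!is.null(blanks)) {
      bl <- blanks[blanks$analyte == an & blanks$pool_id == pool, ,
                   drop = FALSE]
      if (nrow(bl) == 0) bl <- NULL
    }
    slope_solvent <- calibration_params$slope[
      match(an, calibration_params$name)]
    res <- quantify_pool(d, blank_series = bl,
                         lod_extract = spec$lod_extract,
                         loq_extract = spec$loq_extract,
                         slope_solvent = slope_solvent,
                         units = units, below_lod = below_lod)
    cbind(data.frame(analyte = an, age_group = pool,
                     stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full exposure and risk pipeline
#'
#' calibrate -> quantify -> censor -> expose -> characterise risk. When raw
#' measurement series are supplied they are fitted and quantified first;
#' when a pooled-concentration table is supplied the pipeline starts at the
#' censoring step. Warnings (below-baseline intercepts, missing TDIs) never
#' abort the run.
#'
#' @param config a [run_config()].
#' @return an object of class `study_results`: list with `concentrations`
#'   (censored, with `reported_value`), `exposures` (from
#'   [exposure_table()]), `hazard_quotients`, `group_tdi` (per age group x
#'   statistic), `ttc` (or NULL), `inventory_summary` (or NULL), and
#'   `provenance` (policies and seed).
#' @export
run_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  calibration_params <- config$calibration_params
  if (!is.null(config$calibration))
    calibration_params <- fit_all_calibrations(config$calibration)
  conc <- config$concentrations
  if (is.null(conc)) {
    conc <- quantify_study(config$additions, config$blanks,
                           analytes = config$analytes,
                           calibration_params = calibration_params,
                           units = config$units,
                           below_lod = config$below_lod)
  } else {
    conc <- apply_censoring(conc, analytes = config$analytes,
                            units = config$units,
                            below_lod = config$below_lod)
  }
  exposures <- exposure_table(conc, config$consumption)
  hq <- hazard_quotient(exposures$value, exposures$analyte, config$risk)
  hq <- cbind(exposures[c("analyte", "age_group", "statistic")],
              hq[c("tdi", "hq", "exceeds", "assessable")])
  by_slice <- split(exposures,
                    list(exposures$age_group, exposures$statistic),
                    drop = TRUE)
  group_tdi <- do.call(rbind, lapply(names(by_slice), function(nm) {
    sl <- by_slice[[nm]]
    g <- group_exposure_dehp_eq(sl, config$risk)
    data.frame(age_group = sl$age_group[1], statistic = sl$statistic[1],
               dehp_equivalents = g$dehp_equivalents,
               group_tdi = g$group_tdi, exceeds = g$exceeds,
               stringsAsFactors = FALSE)
  }))
  ttc <- NULL
  if (!is.null(config$ttc)) {
    cls <- config$analytes$cramer_class[
      match(exposures$analyte, config$analytes$name)]
    ttc <- cbind(exposures[c("analyte", "statistic")],
                 ttc_screen(exposures$value, cls, exposures$age_group,
                            config$ttc))
  }
  inventory_summary <- NULL
  if (!is.null(config$inventory)) {
    counts <- count_regulated(config$inventory)
    inventory_summary <- list(
      n_regulated = counts$n_regulated,
      n_total = counts$n_total,
      regulation = cbind(config$inventory[c("compound", "sml_token")],
                         flag_regulated(config$inventory$sml_token,
                                        config$inventory$compound)),
      detection = detection_frequency(config$inventory))
  }
  structure(list(concentrations = conc, exposures = exposures,
                 hazard_quotients = hq, group_tdi = group_tdi, ttc = ttc,
                 inventory_summary = inventory_summary,
                 provenance = list(below_lod = config$below_lod,
                                   extract_factor =
                                     config$units$extract_factor,
                                   seed = config$seed)),
            class = "study_results")
}

#' @export
print.study_results <- function(x, ...) {
  cat("study_results:", nrow(x$exposures), "exposure estimates for",
      length(unique(x$exposures$analyte)), "analytes x",
      length(unique(x$exposures$age_group)), "age groups\n")
  cat("  exposure range (ug/kg bw/day):",
      format(signif_half_up(min(x$exposures$value)), digits = 3), "-",
      format(signif_half_up(max(x$exposures$value)), digits = 3), "\n")
  if (any(x$hazard_quotients$exceeds, na.rm = TRUE))
    cat("  WARNING: hazard quotient above 1\n")
  else cat("  no exposure exceeds its tolerable daily intake\n")
  if (!is.null(x$inventory_summary))
    cat("  inventory:", x$inventory_summary$n_regulated, "of",
        x$inventory_summary$n_total, "screened compounds in the positive list\n")
  invisible(x)
}

#' Simulate a study bundle and write it to disk
#'
#' Thin wrapper over [generate_study()] for scripted use.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @param dir output directory.
#' @return invisibly, the generated bundle.
#' @export
simulate_study <- function(config = synthetic_config(), seed = 1L, dir) {
  generate_study(config, seed = seed, dir = dir)
}

#' Write the study outputs as CSV, JSON and a markdown report
#'
#' @param results a `study_results` from [run_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_study_report <- function(results, dir) {
  stopifnot(inherits(results, "study_results"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    concentrations = file.path(dir, "concentrations.csv"),
    exposures = file.path(dir, "exposures.csv"),
    risk_json = file.path(dir, "risk_report.json"),
    risk_md = file.path(dir, "risk_report.md"))
  utils::write.csv(results$concentrations, paths["concentrations"],
                   row.names = FALSE)
  utils::write.csv(results$exposures, paths["exposures"], row.names = FALSE)
  risk <- list(provenance = results$provenance,
               hazard_quotients = results$hazard_quotients,
               group_tdi = results$group_tdi)
  if (!is.null(results$ttc)) risk$ttc <- results$ttc
  if (!is.null(results$inventory_summary))
    risk$inventory <- results$inventory_summary[c("n_regulated", "n_total")]
  jsonlite::write_json(risk, paths["risk_json"], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  md <- c("# Dietary exposure and risk report", "",
          sprintf("Seed: %d; below-LOD policy: %s; extract factor: %g mL/g",
                  results$provenance$seed, results$provenance$below_lod,
                  results$provenance$extract_factor), "",
          "## Exposure range",
          sprintf("Mean exposures span %.3g-%.3g ug/kg bw/day.",
                  min(results$exposures$value[
                    results$exposures$statistic == "mean"]),
                  max(results$exposures$value[
                    results$exposures$statistic == "mean"])), "",
          "## Hazard quotients (exposure / TDI)")
  hq <- results$hazard_quotients[results$hazard_quotients$assessable, ]
  md <- c(md, sprintf("- %s (%s, %s): HQ = %.3g%s", hq$analyte, hq$age_group,
                      hq$statistic, hq$hq,
                      ifelse(hq$exceeds, " EXCEEDS TDI", "")))
  md <- c(md, "", "## Cumulative phthalates (DEHP equivalents)",
          sprintf("- %s %s: %.3g ug/kg bw/day vs group-TDI %g%s",
                  results$group_tdi$age_group, results$group_tdi$statistic,
                  results$group_tdi$dehp_equivalents,
                  results$group_tdi$group_tdi,
                  ifelse(results$group_tdi$exceeds, " EXCEEDED", "")))
  if (!is.null(results$inventory_summary)) {
    md <- c(md, "", "## Screening inventory",
            sprintf(paste0("%d of %d identified compounds are in the ",
                           "plastics-regulation positive list (numeric SML, ",
                           "group SML '+', or non-detectable 'ND' tokens)."),
                    results$inventory_summary$n_regulated,
                    results$inventory_summary$n_total))
  }
  writeLines(md, paths["risk_md"])
  invisible(paths)
}
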