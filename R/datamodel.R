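#' Units convention for extract vs. sample concentrations
#'
#' Food aliquots of one gram are extracted and reconstituted in one millilitre
#' of solvent, so an extract concentration in ug/mL maps to a sample
#' concentration in ug/g through `extract_factor` (mL of final extract per g
#' of sample): `c_sample = c_extract * extract_factor`. The default of 1
#' reflects the 1 g -> 1 mL protocol; other protocols can set a different
#' factor.
#'
#' @param extract_factor mL of final extract per g of sample; must be > 0.
#' @param round_sigfigs significant figures used when values are reported.
#' @return an object of class `units_config`.
#' @export
units_config <- function(extract_factor = 1.0, round_sigfigs = 3L) {
  if (!is.numeric(extract_factor) || length(extract_factor) != 1L ||
      !is.finite(extract_factor) || extract_factor <= 0)
    stop_validation("extract_factor must be a single positive number")
  if (round_sigfigs < 1) stop_validation("round_sigfigs must be >= 1")
  structure(list(extract_factor = extract_factor,
                 round_sigfigs = as.integer(round_sigfigs)),
            class = "units_config")
}

#' @export
print.units_config <- function(x, ...) {
  cat("units_config: ", x$extract_factor, " mL extract per g sample; ",
      x$round_sigfigs, " significant figures for reporting\n", sep = "")
  invisible(x)
}

#' Convert an extract concentration (ug/mL) to sample units (ug/g)
#'
#' @param c_extract concentration in the final extract, ug/mL (>= 0).
#' @param units a [units_config()].
#' @return concentration in the food sample, ug/g.
#' @export
#' @examples
#' extract_to_sample_units(0.01, units_config())  # 0.01 ug/g
extract_to_sample_units <- function(c_extract, units = units_config()) {
  stopifnot(inherits(units, "units_config"))
  if (any(!is.finite(c_extract)) || any(c_extract < 0))
    stop_domain("extract concentrations must be finite and >= 0")
  c_extract * units$extract_factor
}

#' Convert a sample concentration (ug/g) to extract units (ug/mL)
#'
#' Inverse of [extract_to_sample_units()].
#' @inheritParams extract_to_sample_units
#' @param c_sample concentration in the food sample, ug/g (>= 0).
#' @export
sample_to_extract_units <- function(c_sample, units = units_config()) {
  stopifnot(inherits(units, "units_config"))
  if (any(!is.finite(c_sample)) || any(c_sample < 0))
    stop_domain("sample concentrations must be finite and >= 0")
  c_sample / units$extract_factor
}

.cramer_levels <- c("I", "II", "III")
.age_groups <- c("1-2", "3-9", "10-17")

validate_analytes <- function(df) {
  assert_columns(df, c("name", "cas", "quant_ion", "qual_ion",
                       "lod_extract", "loq_extract", "tdi", "sml",
                       "cramer_class", "group_tdi_member", "potency_factor"),
                 "analyte table")
  if (anyDuplicated(df$name))
    stop_validation("duplicate analyte name(s): ",
                    paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  for (i in seq_len(nrow(df))) {
    nm <- df$name[i]
    if (!nzchar(nm)) stop_validation("analyte row ", i, ": empty name")
    if (!is.na(df$lod_extract[i]) && !is.na(df$loq_extract[i]) &&
        df$lod_extract[i] >= df$loq_extract[i])
      stop_validation("analyte ", nm, ": lod_extract must be < loq_extract")
    if (df$quant_ion[i] == df$qual_ion[i])
      stop_validation("analyte ", nm,
                      ": quantification and qualifier ions must differ")
    if (!is.na(df$tdi[i]) && df$tdi[i] <= 0)
      stop_validation("analyte ", nm, ": tdi must be > 0")
    if (is.na(df$potency_factor[i]) || df$potency_factor[i] <= 0)
      stop_validation("analyte ", nm, ": potency_factor must be > 0")
    if (!is.na(df$cramer_class[i]) &&
        !df$cramer_class[i] %in% .cramer_levels)
      stop_validation("analyte ", nm, ": cramer_class must be one of ",
                      paste(.cramer_levels, collapse = ", "))
  }
  df
}

#' Read the analyte specification table
#'
#' One row per target compound: identity (name, CAS), SIM quantification and
#' qualifier ions (m/z), detection and quantification limits in the extract
#' (ug/mL), and optional risk metadata (tolerable daily intake in
#' ug/kg bw/day, specific migration limit in mg/kg, Cramer class, membership
#' in the phthalate group-TDI with its potency factor in DEHP equivalents).
#'
#' @param path CSV file with a header row, UTF-8, "." decimal; empty cells are
#'   missing optional values.
#' @return a validated data.frame of analyte specifications.
#' @export
read_analyte_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("name", "cas", "quant_ion", "qual_ion",
                       "lod_extract", "loq_extract", "tdi", "sml",
                       "cramer_class", "group_tdi_member", "potency_factor"),
                 "analyte table")
  if (nrow(df)) {
    df$cas <- as.character(df$cas)
    df$cramer_class <- as.character(df$cramer_class)
    df$cramer_class[!is.na(df$cramer_class) & df$cramer_class == ""] <- NA
    df$group_tdi_member <- as.logical(df$group_tdi_member)
    df$potency_factor[is.na(df$potency_factor)] <- 1
  }
  validate_analytes(df)
}

#' Write an analyte specification table
#' @param analytes a validated analyte data.frame.
#' @param path output CSV path.
#' @export
write_analyte_table <- function(analytes, path) {
  validate_analytes(analytes)
  utils::write.csv(analytes, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Bundled analyte specifications for the eight target migrants
#'
#' Five phthalates (DEP, DIBP, DBP, DEHP, DNOP), the citrate plasticizer ATBC,
#' the antioxidant BHT and the UV filter octocrylene, with their SIM ions,
#' extract LOD/LOQ, TDIs where established (DEP 500, DBP 10, DEHP 50
#' ug/kg bw/day) and Cramer classes.
#'
#' @return a validated analyte data.frame.
#' @export
default_analytes <- function() {
  read_analyte_table(system.file("extdata", "analytes.csv",
                                 package = "fcmexposure", mustWork = TRUE))
}

#' Bundled solvent calibration parameters for the eight target migrants
#'
#' Slope and intercept of the internal-standard-normalised response line in
#' methanol (response ratio per ug/mL), the coefficient of determination, and
#' the working range, per analyte.
#'
#' @return a data.frame with columns name, slope, intercept, r_squared,
#'   range_low, range_high.
#' @export
default_calibration_params <- function() {
  df <- utils::read.csv(system.file("extdata", "calibration_params.csv",
                                    package = "fcmexposure", mustWork = TRUE),
                        stringsAsFactors = FALSE)
  if (any(df$slope <= 0)) stop_validation("calibration slopes must be > 0")
  df
}

#' Read per-age-group consumption statistics
#'
#' Mean and 95th-percentile consumption of the food group per age group. In
#' `per_kg_bw` mode the figures are already normalised to body weight
#' (g per kg bw per day); in `absolute_with_bw` mode they are absolute
#' (g/day) and `body_weight` (kg) is required.
#'
#' @param path CSV with columns age_group, intake_mean, intake_p95, mode,
#'   body_weight.
#' @return a validated data.frame.
#' @export
read_consumption_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("age_group", "intake_mean", "intake_p95", "mode"),
                 "consumption table")
  if (!"body_weight" %in% names(df)) df$body_weight <- NA_real_
  validate_consumption(df)
}

validate_consumption <- function(df) {
  if (anyDuplicated(df$age_group))
    stop_validation("duplicate age_group in consumption table")
  bad <- !df$mode %in% c("per_kg_bw", "absolute_with_bw")
  if (any(bad))
    stop_validation("unknown consumption mode: ",
                    paste(unique(df$mode[bad]), collapse = ", "))
  if (any(!is.finite(df$intake_mean)) || any(df$intake_mean < 0) ||
      any(!is.finite(df$intake_p95)))
    stop_validation("intakes must be finite and >= 0")
  if (any(df$intake_p95 < df$intake_mean))
    stop_validation("intake_p95 must be >= intake_mean for every age group")
  need_bw <- df$mode == "absolute_with_bw"
  if (any(need_bw & (is.na(df$body_weight) | df$body_weight <= 0)))
    stop_validation("absolute_with_bw mode requires a positive body_weight")
  df
}

#' Bundled consumption statistics for snacks and biscuits, ages 1-17
#'
#' National dietary-survey consumption of the studied food group for the
#' 1-2, 3-9 and 10-17 year age groups: mean (and P95) of 1.671 (8.508),
#' 0.9806 (4.265) and 0.3705 (1.932) g per kg body weight per day
#' respectively.
#'
#' @return a validated consumption data.frame.
#' @export
default_consumption <- function() {
  read_consumption_table(system.file("extdata", "consumption.csv",
                                     package = "fcmexposure", mustWork = TRUE))
}

#' Read a pooled-concentration table
#'
#' One row per analyte x age-group pool: the blank-corrected concentration in
#' ug/g (`corrected`, empty when the result is censored), the censor status
#' (`quantified`, `below_loq`, `below_lod`) and the slope-ratio recovery in
#' percent.
#'
#' @param path CSV path.
#' @return a data.frame.
#' @export
read_concentration_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("analyte", "age_group", "corrected", "censor_status"),
                 "concentration table")
  bad <- !df$censor_status %in% c("quantified", "below_loq", "below_lod")
  if (any(bad))
    stop_validation("unknown censor_status: ",
                    paste(unique(df$censor_status[bad]), collapse = ", "))
  if (any(df$censor_status == "quantified" & !is.finite(df$corrected)))
    stop_validation("quantified rows must carry a finite corrected value")
  if (any(is.finite(df$corrected) & df$corrected < 0))
    stop_validation("corrected concentrations must be >= 0")
  df
}

#' Bundled pooled concentrations of the eight migrants
#'
#' Blank-corrected concentrations (ug/g) of the eight target migrants in the
#' three consumption-weighted composite pools, with slope-ratio recoveries.
#' DNOP was below the LOQ in every pool and is carried as a censored result.
#'
#' @return a data.frame as from [read_concentration_table()].
#' @export
default_concentrations <- function() {
  read_concentration_table(system.file("extdata", "concentrations.csv",
                                       package = "fcmexposure",
                                       mustWork = TRUE))
}

#' Read a calibration or standard-addition measurement series
#'
#' Long format, one row per injection: `analyte`, the x variable
#' (`concentration` in ug/mL for solvent calibration; `spike_level` in ug/g
#' for standard addition, with `pool_id`), `replicate`, and `response_ratio`
#' (quantification-ion area / internal-standard ion-153 area).
#'
#' @param path CSV path.
#' @return a data.frame.
#' @name read_series
NULL

#' @rdname read_series
#' @export
read_calibration_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("analyte", "concentration", "replicate",
                       "response_ratio"), "calibration table")
  if (any(df$concentration < 0))
    stop_validation("calibration concentrations must be >= 0")
  df
}

#' @rdname read_series
#' @export
read_addition_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("analyte", "pool_id", "spike_level", "replicate",
                       "response_ratio"), "addition table")
  if (any(df$spike_level < 0))
    stop_validation("spike levels must be >= 0")
  df
}

#' Read the screening-inventory table
#'
#' One row per compound identified in the packaging screen: identity, GC
#' retention time, Cramer class, the migration-regulation token from the
#' positive list (a numeric SML in mg/kg, `+` for the 60 mg/kg group
#' restriction, `ND` for a non-detectable restriction, `NI`/`NL` for
#' not-in-positive-list) and one logical detection column per
#' sample x extraction solvent (e.g. `AS_01_ACN`).
#'
#' @param path CSV path.
#' @return a data.frame.
#' @export
read_inventory_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  assert_columns(df, c("compound", "cas", "rt_min", "cramer_class",
                       "sml_token"), "inventory table")
  det <- grep("_(ACN|HEX)$", names(df), value = TRUE)
  if (!length(det))
    stop_schema("inventory table: no detection columns (sample_SOLVENT)")
  for (d in det) df[[d]] <- as.logical(df[[d]])
  df
}

#' Bundled screening inventory of identified packaging migrants
#'
#' The 65 compounds identified in the packaging screen of the seven food
#' samples (acetonitrile and hexane extracts), with retention times, Cramer
#' classes, positive-list tokens and per-sample detection flags.
#'
#' @return a data.frame as from [read_inventory_table()].
#' @export
default_inventory <- function() {
  read_inventory_table(system.file("extdata", "inventory.csv",
                                   package = "fcmexposure", mustWork = TRUE))
}
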