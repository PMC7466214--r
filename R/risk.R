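#' Risk characterisation configuration
#'
#' Tolerable daily intakes (ug/kg bw/day) for the analytes with established
#' health-based guidance values (DEP 500, DBP 10, DEHP 50), and the
#' cumulative group-TDI of 50 ug/kg bw/day in DEHP equivalents proposed for
#' the structurally related phthalates DEHP, DBP, DiNP and BBP (unit potency
#' by default).
#'
#' @param tdi_table named numeric vector of TDIs, ug/kg bw/day.
#' @param group_tdi cumulative group-TDI in DEHP equivalents, ug/kg bw/day.
#' @param group_members analytes contributing to the group-TDI.
#' @param potency_factors named numeric vector of DEHP-equivalence potencies;
#'   members without an entry default to 1.
#' @return an object of class `risk_config`.
#' @export
risk_config <- function(tdi_table = c(DEP = 500, DBP = 10, DEHP = 50),
                        group_tdi = 50,
                        group_members = c("DEHP", "DBP", "DiNP", "BBP"),
                        potency_factors = NULL) {
  if (any(tdi_table <= 0) || group_tdi <= 0)
    stop_validation("TDIs and the group-TDI must be > 0")
  if (!is.null(potency_factors) && any(potency_factors <= 0))
    stop_validation("potency factors must be > 0")
  structure(list(tdi_table = tdi_table, group_tdi = group_tdi,
                 group_members = group_members,
                 potency_factors = potency_factors %||% numeric()),
            class = "risk_config")
}

#' Threshold-of-toxicological-concern configuration
#'
#' Per-person daily exposure thresholds by Cramer structural class
#' (I 1800, II 540, III 90 ug/person/day) and the body weights used to turn
#' per-kg exposures into per-person exposures. No body weights are bundled as
#' study values; the example weights shipped with the package
#' (`body_weights_example.csv`: 12/24/50 kg) are illustrative only and must
#' be reviewed for any real assessment.
#'
#' @param thresholds named numeric vector, ug/person/day, decreasing from
#'   class I to III.
#' @param body_weight named numeric vector of body weights (kg) by age group.
#' @return an object of class `ttc_config`.
#' @export
ttc_config <- function(thresholds = c(I = 1800, II = 540, III = 90),
                       body_weight = NULL) {
  if (!all(c("I", "II", "III") %in% names(thresholds)))
    stop_validation("thresholds must be named I, II, III")
  if (is.unsorted(rev(thresholds[c("I", "II", "III")]), strictly = TRUE))
    stop_validation("TTC thresholds must decrease from class I to III")
  if (!is.null(body_weight) && any(body_weight <= 0))
    stop_validation("body weights must be > 0")
  structure(list(thresholds = thresholds, body_weight = body_weight),
            class = "ttc_config")
}

#' Hazard quotient against the tolerable daily intake
#'
#' HQ = exposure / TDI; a quotient strictly above 1 flags a potential
#' concern. Analytes without an established TDI are returned as not
#' assessable rather than an error.
#'
#' @param exposure exposure in ug/kg bw/day (vectorised).
#' @param analyte analyte name(s), matched against the TDI table.
#' @param config a [risk_config()].
#' @return data.frame with `analyte`, `exposure`, `tdi`, `hq`, `exceeds`,
#'   `assessable`.
#' @export
#' @examples
#' hazard_quotient(0.545, "DEP")$hq  # 0.00109
hazard_quotient <- function(exposure, analyte, config = risk_config()) {
  stopifnot(inherits(config, "risk_config"))
  if (any(exposure < 0)) stop_domain("exposures must be >= 0")
  tdi <- unname(config$tdi_table[analyte])
  hq <- exposure / tdi
  data.frame(analyte = analyte, exposure = exposure, tdi = tdi, hq = hq,
             exceeds = !is.na(hq) & hq > 1,
             assessable = !is.na(tdi),
             stringsAsFactors = FALSE)
}

#' Cumulative phthalate exposure in DEHP equivalents
#'
#' Sums potency-weighted exposures over the group-TDI members present in the
#' input (missing members simply contribute nothing) and compares the total
#' with the cumulative group-TDI.
#'
#' @param estimates data.frame with columns `analyte` and `value`
#'   (ug/kg bw/day), e.g. one age group x statistic slice of
#'   [exposure_table()].
#' @param config a [risk_config()].
#' @return list with `dehp_equivalents` (ug/kg bw/day), `group_tdi`,
#'   `exceeds`, and the per-member contributions.
#' @export
group_exposure_dehp_eq <- function(estimates, config = risk_config()) {
  stopifnot(inherits(config, "risk_config"))
  assert_columns(estimates, c("analyte", "value"), "exposure estimates")
  members <- estimates[estimates$analyte %in% config$group_members, ,
                       drop = FALSE]
  pot <- config$potency_factors[members$analyte]
  pot[is.na(pot)] <- 1
  contrib <- members$value * as.numeric(pot)
  total <- sum(contrib)
  list(dehp_equivalents = total,
       group_tdi = config$group_tdi,
       exceeds = total > config$group_tdi,
       contributions = data.frame(analyte = members$analyte,
                                  exposure = members$value,
                                  potency = as.numeric(pot),
                                  dehp_eq = contrib,
                                  stringsAsFactors = FALSE))
}

#' Threshold-of-toxicological-concern screen
#'
#' Converts a body-weight-normalised exposure to a per-person daily exposure
#' (`exposure * body_weight`) and compares it, strictly, with the Cramer
#' class threshold. Missing class or body weight yields a not-assessable
#' verdict rather than an error.
#'
#' @param exposure exposure in ug/kg bw/day.
#' @param cramer_class `"I"`, `"II"` or `"III"` (NA allowed).
#' @param age_group age group label used to look up the body weight.
#' @param config a [ttc_config()] with body weights.
#' @return data.frame with `per_person_exposure` (ug/person/day),
#'   `threshold`, `exceeds`, `assessable`.
#' @export
ttc_screen <- function(exposure, cramer_class, age_group, config) {
  stopifnot(inherits(config, "ttc_config"))
  if (any(exposure < 0)) stop_domain("exposures must be >= 0")
  bw <- if (is.null(config$body_weight)) NA_real_
        else unname(config$body_weight[age_group])
  thr <- unname(config$thresholds[as.character(cramer_class)])
  per_person <- exposure * bw
  data.frame(age_group = age_group,
             cramer_class = as.character(cramer_class),
             per_person_exposure = per_person,
             threshold = thr,
             exceeds = !is.na(per_person) & !is.na(thr) & per_person > thr,
             assessable = !is.na(per_person) & !is.na(thr),
             stringsAsFactors = FALSE)
}

#' Regulation status of an inventory compound from its positive-list token
#'
#' A numeric token is a specific migration limit in mg/kg; `+` marks the
#' generic group restriction of 60 mg/kg; `ND` marks a substance listed with
#' a non-detectable-migration restriction (the four diisocyanates); `NI` and
#' `NL` mark substances not included in the plastics-regulation positive
#' list. Numeric, `+` and `ND` tokens all denote listed (regulated)
#' substances.
#'
#' @param sml_token character vector of tokens.
#' @param compound optional compound names for error messages.
#' @return data.frame with `status` (`regulated_sml`, `regulated_group_sml`,
#'   `regulated_non_detectable`, `not_listed`), `sml_mg_kg` (NA where no
#'   numeric limit applies) and `regulated`.
#' @export
#' @examples
#' flag_regulated(c("3", "+", "ND", "NI"))$regulated  # TRUE TRUE TRUE FALSE
flag_regulated <- function(sml_token, compound = NULL) {
  tok <- trimws(as.character(sml_token))
  compound <- compound %||% tok
  numeric_tok <- suppressWarnings(as.numeric(tok))
  status <- character(length(tok))
  sml <- rep(NA_real_, length(tok))
  for (i in seq_along(tok)) {
    if (!is.na(numeric_tok[i])) {
      status[i] <- "regulated_sml"; sml[i] <- numeric_tok[i]
    } else if (tok[i] == "+") {
      status[i] <- "regulated_group_sml"; sml[i] <- 60
    } else if (tok[i] == "ND") {
      status[i] <- "regulated_non_detectable"
    } else if (tok[i] %in% c("NI", "NL")) {
      status[i] <- "not_listed"
    } else {
      stop_validation("unknown positive-list token \"", tok[i],
                      "\" for compound ", compound[i])
    }
  }
  data.frame(status = status, sml_mg_kg = sml,
             regulated = status != "not_listed",
             stringsAsFactors = FALSE)
}

#' Count positive-list compounds in a screening inventory
#'
#' @param inventory data.frame as from [read_inventory_table()].
#' @return list with `n_regulated` and `n_total`.
#' @export
count_regulated <- function(inventory) {
  if (nrow(inventory) == 0) return(list(n_regulated = 0L, n_total = 0L))
  flags <- flag_regulated(inventory$sml_token, inventory$compound)
  list(n_regulated = sum(flags$regulated), n_total = nrow(inventory))
}

#' Per-compound detection frequency across samples
#'
#' A compound counts as detected in a sample when it was found in at least
#' one extraction solvent; the frequency is the number of samples with a
#' detection over the total number of samples screened.
#'
#' @param inventory data.frame with logical detection columns named
#'   `<sample>_<SOLVENT>` (e.g. `AS_01_ACN`, `AS_01_HEX`).
#' @return data.frame with `compound`, `n_detected`, `n_samples`,
#'   `frequency`.
#' @export
detection_frequency <- function(inventory) {
  det_cols <- grep("_(ACN|HEX)$", names(inventory), value = TRUE)
  if (!length(det_cols))
    stop_schema("inventory has no detection columns (sample_SOLVENT)")
  samples <- unique(sub("_(ACN|HEX)$", "", det_cols))
  detected <- vapply(seq_len(nrow(inventory)), function(i) {
    sum(vapply(samples, function(s) {
      cols <- det_cols[startsWith(det_cols, paste0(s, "_"))]
      any(unlist(inventory[i, cols]), na.rm = TRUE)
    }, logical(1)))
  }, integer(1))
  data.frame(compound = inventory$compound,
             n_detected = detected,
             n_samples = length(samples),
             frequency = detected / length(samples),
             stringsAsFactors = FALSE)
}
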