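#' Consumption-weighted pool composition
#'
#' Composite pools mirror the share of each food in the age group's
#' consumption: the pool weight of food i is its consumption amount divided
#' by the total.
#'
#' @param consumptions data.frame with columns `food_id` and `amount`
#'   (>= 0, not all zero; any consistent unit).
#' @return data.frame with columns `food_id`, `weight` summing to 1.
#' @export
#' @examples
#' pool_weights(data.frame(food_id = c("A", "B", "C"), amount = c(2, 1, 1)))
pool_weights <- function(consumptions) {
  assert_columns(consumptions, c("food_id", "amount"), "consumption amounts")
  if (nrow(consumptions) < 1) stop_domain("need at least one food")
  if (any(consumptions$amount < 0)) stop_domain("amounts must be >= 0")
  total <- sum(consumptions$amount)
  if (total == 0) stop_domain("all consumption amounts are zero")
  data.frame(food_id = consumptions$food_id,
             weight = consumptions$amount / total,
             stringsAsFactors = FALSE)
}

#' Concentration of a modelled composite pool
#'
#' The physically pooled sample has concentration equal to the
#' consumption-weighted mean of the per-food concentrations.
#'
#' @param recipe data.frame with `food_id`, `weight` (weights >= 0, summing
#'   to 1 within 1e-9).
#' @param per_food_conc named numeric vector, ug/g per food_id.
#' @return pooled concentration, ug/g.
#' @export
pooled_concentration <- function(recipe, per_food_conc) {
  assert_columns(recipe, c("food_id", "weight"), "pool recipe")
  if (any(recipe$weight < 0) || abs(sum(recipe$weight) - 1) > 1e-9)
    stop_validation("pool weights must be >= 0 and sum to 1")
  missing <- setdiff(recipe$food_id, names(per_food_conc))
  if (length(missing))
    stop_domain("no concentration for food(s): ",
                paste(missing, collapse = ", "))
  sum(recipe$weight * per_food_conc[recipe$food_id])
}

#' Deterministic point exposure
#'
#' Dietary exposure is the pool concentration (ug/g) times the consumption
#' figure. In `per_kg_bw` mode the intake is already g per kg body weight per
#' day and the product is the exposure in ug/kg bw/day; in
#' `absolute_with_bw` mode an absolute intake in g/day is divided by the body
#' weight first.
#'
#' @param c_pool pool concentration, ug/g (>= 0).
#' @param intake consumption figure (g/kg bw/day, or g/day in absolute mode).
#' @param mode `"per_kg_bw"` (default) or `"absolute_with_bw"`.
#' @param body_weight body weight in kg, required in absolute mode.
#' @return exposure in ug/kg bw/day (unrounded).
#' @export
#' @examples
#' exposure_point(0.0370, 1.671)  # 0.061827 -> reported 0.0618
exposure_point <- function(c_pool, intake,
                           mode = c("per_kg_bw", "absolute_with_bw"),
                           body_weight = NULL) {
  mode <- match.arg(mode)
  if (any(c_pool < 0) || any(intake < 0))
    stop_domain("concentration and intake must be >= 0")
  if (mode == "absolute_with_bw") {
    if (is.null(body_weight) || any(!is.finite(body_weight)) ||
        any(body_weight <= 0))
      stop_validation("absolute_with_bw mode requires a positive body_weight")
    intake <- intake / body_weight
  }
  c_pool * intake
}

#' Mean and P95 exposure for every analyte x age-group pair
#'
#' Combines the censored reported concentrations of each pool with the age
#' group's mean and 95th-percentile consumption. The pool concentration is
#' treated as fixed, so the P95 exposure is concentration times P95 intake;
#' censored substitutions (LOQ/2) feed the exposure directly.
#'
#' @param concentrations concentration table carrying `analyte`, `age_group`
#'   and `reported_value` (apply [apply_censoring()] first if needed).
#' @param consumption consumption table as from [read_consumption_table()].
#' @param round_sigfigs significant figures for the `reported` column.
#' @return data.frame with one row per analyte x age_group x statistic
#'   (mean, p95): `value` (unrounded, ug/kg bw/day) and `reported` (rounded
#'   half-up).
#' @export
exposure_table <- function(concentrations, consumption = default_consumption(),
                           round_sigfigs = 3) {
  assert_columns(concentrations, c("analyte", "age_group", "reported_value"),
                 "concentration table")
  validate_consumption(consumption)
  key <- paste(concentrations$analyte, concentrations$age_group)
  if (anyDuplicated(key))
    stop_validation("duplicate analyte x age_group pair(s): ",
                    paste(unique(key[duplicated(key)]), collapse = "; "))
  idx <- match(concentrations$age_group, consumption$age_group)
  if (anyNA(idx))
    stop_validation("no consumption data for age group(s): ",
                    paste(unique(concentrations$age_group[is.na(idx)]),
                          collapse = ", "))
  rows <- lapply(c("mean", "p95"), function(stat) {
    intake <- if (stat == "mean") consumption$intake_mean[idx]
              else consumption$intake_p95[idx]
    value <- mapply(function(c_pool, amt, mode, bw) {
      exposure_point(c_pool, amt, mode = mode,
                     body_weight = if (is.na(bw)) NULL else bw)
    }, concentrations$reported_value, intake,
       consumption$mode[idx], consumption$body_weight[idx])
    data.frame(analyte = concentrations$analyte,
               age_group = concentrations$age_group,
               statistic = stat,
               value = value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$analyte, unique(concentrations$analyte)),
                   out$age_group, out$statistic), ]
  rownames(out) <- NULL
  out$reported <- signif_half_up(out$value, round_sigfigs)
  out
}
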