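#' Population exposed beyond the MMT threshold
#'
#' Heat exposure is the total population in cells strictly warmer than the
#' minimum mortality temperature; cold exposure the total in cells strictly
#' colder. Cells exactly at the MMT (a measure-zero event for real
#' temperatures) count in neither side, so
#' `heat + cold + at-MMT population = total land population`.
#'
#' @param pop_field Population raster, persons per cell (`NA` off land).
#' @param T_field Temperature raster, degC, aligned with `pop_field`.
#' @param mmt Threshold temperature, degC.
#' @param side `"heat"` or `"cold"`.
#' @return Persons (scalar).
#' @export
exposure_count <- function(pop_field, T_field, mmt, side = c("heat", "cold")) {
  side <- match.arg(side)
  if (!identical(dim(pop_field), dim(T_field)))
    stop("invalid input: fields are misaligned", call. = FALSE)
  sel <- if (side == "heat") T_field > mmt else T_field < mmt
  sum(pop_field[which(sel)], na.rm = TRUE)
}

# population sitting exactly at the threshold
population_at_mmt <- function(pop_field, T_field, mmt) {
  sum(pop_field[which(T_field == mmt)], na.rm = TRUE)
}

#' Mobility-induced change in MMT-threshold exposure
#'
#' Compares a static and a mobility-adjusted exposure count under one
#' temperature scenario. On the daily timescale the static count uses the
#' scenario month's nighttime frame and the dynamic count its daytime frame
#' (commuting). On the seasonal timescale both counts are nighttime frames —
#' January (static) vs July (dynamic) — evaluated against the same scenario
#' temperatures, isolating the effect of the seasonal population swing. The
#' percentage change is referenced to the July nighttime total for heat and
#' the January nighttime total for cold.
#'
#' @param stack A [city_stack()].
#' @param curve An [erf()] providing the MMT.
#' @param timescale `"daily"` or `"seasonal"`.
#' @param scenario A `temperature_scenario` (see [monthly_mean_scenario()],
#'   [extreme_day_composite()]).
#' @param side `"heat"` or `"cold"`.
#' @param month_summer,month_winter Months used for the seasonal pair and the
#'   percentage denominators, defaults 7 and 1.
#' @return Object of class `exposure_delta`: list with `side`, `timescale`,
#'   `scenario` (descriptor string), `exposure_static`, `exposure_dynamic`,
#'   `delta` (persons), `delta_pct` (% of the reference nighttime total),
#'   `pop_at_mmt`.
#' @export
mobility_exposure_delta <- function(stack, curve,
                                    timescale = c("daily", "seasonal"),
                                    scenario, side = c("heat", "cold"),
                                    month_summer = 7L, month_winter = 1L) {
  timescale <- match.arg(timescale)
  side <- match.arg(side)
  stopifnot(inherits(scenario, "temperature_scenario"))
  mmt <- extract_mmt(curve)
  land <- stack$land_mask
  if (timescale == "daily") {
    m <- scenario$month
    static_pop <- mask_field(stack$pop_night[[m]], land)
    dynamic_pop <- mask_field(stack$pop_day[[m]], land)
  } else {
    static_pop <- mask_field(stack$pop_night[[as.integer(month_winter)]], land)
    dynamic_pop <- mask_field(stack$pop_night[[as.integer(month_summer)]], land)
  }
  e_static <- exposure_count(static_pop, scenario$field, mmt, side)
  e_dynamic <- exposure_count(dynamic_pop, scenario$field, mmt, side)
  ref_month <- if (side == "heat") as.integer(month_summer)
  else as.integer(month_winter)
  ref_total <- land_total(stack$pop_night[[ref_month]], land)
  structure(list(side = side, timescale = timescale,
                 scenario = scenario_label(scenario),
                 exposure_static = e_static, exposure_dynamic = e_dynamic,
                 delta = e_dynamic - e_static,
                 delta_pct = 100 * (e_dynamic - e_static) / ref_total,
                 pop_at_mmt = population_at_mmt(dynamic_pop, scenario$field,
                                                mmt)),
            class = "exposure_delta")
}

scenario_label <- function(scenario) {
  if (scenario$mode == "monthly_mean")
    sprintf("monthly_mean(month=%d)", scenario$month)
  else sprintf("extreme(month=%d, side=%s, fraction=%g)",
               scenario$month, scenario$side, scenario$fraction)
}

#' Incoming-population-weighted temperature
#'
#' `<T> = sum(T_i * P_i) / sum(P_i)` over the grid cells with positive
#' population change only — the average temperature experienced by the net
#' incoming population. Cells losing population are excluded.
#'
#' @param dP_field Population-change raster, persons per cell.
#' @param T_field Temperature raster, degC, aligned.
#' @return Degrees Celsius (scalar).
#' @export
population_weighted_temperature <- function(dP_field, T_field) {
  if (!identical(dim(dP_field), dim(T_field)))
    stop("invalid input: fields are misaligned", call. = FALSE)
  pos <- which(dP_field > 0 & !is.na(T_field))
  if (!length(pos))
    stop("no incoming population: no cell with positive population change",
         call. = FALSE)
  sum(T_field[pos] * dP_field[pos]) / sum(dP_field[pos])
}

#' Cumulative incoming-population fraction from cold to warm locations
#'
#' Sorts the cells with positive population change by their temperature
#' deviation from the city mean and accumulates their share of the total
#' influx, yielding the curve "what fraction of the incoming population ends
#' up at or below a given temperature". `fraction_above_mean` is the share
#' landing in cells strictly warmer than the mean; values well above 50%
#' indicate that mobility funnels people into the warm urban core.
#'
#' @param dP_field Population-change raster, persons per cell.
#' @param T_field Temperature raster, degC, aligned.
#' @param t_bar City mean temperature, degC.
#' @return Object of class `cumulative_curve`: list with `dT` (sorted
#'   `T - t_bar`), `cum_fraction` (nondecreasing, ends at 1),
#'   `fraction_above_mean` (%).
#' @export
cumulative_incoming_fraction <- function(dP_field, T_field, t_bar) {
  if (!identical(dim(dP_field), dim(T_field)))
    stop("invalid input: fields are misaligned", call. = FALSE)
  pos <- which(dP_field > 0 & !is.na(T_field))
  if (!length(pos))
    stop("no incoming population: no cell with positive population change",
         call. = FALSE)
  dT <- T_field[pos] - t_bar
  w <- dP_field[pos]
  ord <- order(dT)
  structure(list(dT = dT[ord],
                 cum_fraction = cumsum(w[ord]) / sum(w),
                 fraction_above_mean = 100 * sum(w[dT > 0]) / sum(w)),
            class = "cumulative_curve")
}
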