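#' Full per-city analysis
#'
#' Runs every stage for one city: mobility deltas and quadrant, seasonal
#' cosine fits and population-temperature coupling, rescaled radial profiles
#' with exponential fits, MMT-threshold exposure deltas (daily heat in July,
#' daily cold in January, seasonal heat in July), the incoming-population
#' cumulative curve and weighted temperature, and — when an ERF is supplied —
#' the mobility-induced relative-risk changes. Deterministic given the stack.
#'
#' @param stack A [city_stack()].
#' @param curve Optional [erf()]. When `NULL`, risk fields are omitted with a
#'   warning and all exposure thresholds fall back to `mmt_fallback`.
#' @param scenario_mode `"mean"` (monthly-mean composite, default) or
#'   `"extreme"` (hottest/coldest `extreme_fraction` of days).
#' @param extreme_fraction Fraction of days for extreme composites.
#' @param p_ref Reference population for rescaling (largest city's April
#'   daytime total); default this city's own, giving `k = 1`.
#' @param month_summer,month_winter Scenario months, defaults 7 and 1.
#' @param mmt_fallback Threshold used when no ERF is given, degC.
#' @return Object of class `city_report`: list with `city_id`, `mobility`,
#'   `seasonal`, `coupling`, `profiles`, `exponential_fits`, `exposure`,
#'   `temperatures`, `curve_summary`, `risk`.
#' @export
run_city <- function(stack, curve = NULL,
                     scenario_mode = c("mean", "extreme"),
                     extreme_fraction = 0.03, p_ref = NULL,
                     month_summer = 7L, month_winter = 1L,
                     mmt_fallback = 18) {
  scenario_mode <- match.arg(scenario_mode)
  make_scen <- function(month, side) {
    if (scenario_mode == "mean") monthly_mean_scenario(stack, month)
    else extreme_day_composite(stack, month, side, extreme_fraction)
  }
  scen_summer <- make_scen(month_summer, "hot")
  scen_winter <- make_scen(month_winter, "cold")

  mob <- mobility_summary(stack, month = month_summer)
  # stacks covering only part of the year cannot support the seasonal fits
  seas <- tryCatch(seasonal_fit_table(stack), error = function(e) NULL)

  if (is.null(p_ref))
    p_ref <- land_total(stack$pop_day[[4L]], stack$land_mask)
  params <- rescale_params(land_total(stack$pop_day[[4L]], stack$land_mask),
                           p_ref)
  dd <- delta_p_daily(stack, month_summer)
  night_summer <- mask_field(stack$pop_night[[month_summer]],
                             stack$land_mask)
  prof_night <- build_radial_profile(night_summer, scen_summer$field, stack,
                                     params)
  prof_dP <- build_radial_profile(dd$field, scen_summer$field, stack, params)
  exp_fit_night <- tryCatch(fit_exponential(prof_night),
                            error = function(e) NULL)

  t_bar <- domain_mean_temperature(stack, scen_summer)
  # nighttime-dominant cities have no net incoming cells; report NA there
  curves <- tryCatch(
    cumulative_incoming_fraction(dd$field, scen_summer$field, t_bar),
    error = function(e) NULL)
  t_weighted <- tryCatch(
    population_weighted_temperature(dd$field, scen_summer$field),
    error = function(e) NA_real_)

  if (is.null(curve)) {
    warning("no ERF supplied: risk fields omitted, MMT threshold uses the ",
            "fallback value", call. = FALSE)
    mmt_curve <- make_synthetic_erf(mmt = mmt_fallback,
                                    t_range = mmt_fallback + c(-30, 30))
    risk <- NULL
  } else {
    mmt_curve <- curve
    risk <- if (is.finite(t_weighted))
      delta_rr_percent(curve, t_weighted, t_bar) else NULL
  }
  exposure <- rbind(
    as_exposure_row(mobility_exposure_delta(stack, mmt_curve, "daily",
                                            scen_summer, "heat",
                                            month_summer, month_winter)),
    as_exposure_row(mobility_exposure_delta(stack, mmt_curve, "daily",
                                            scen_winter, "cold",
                                            month_summer, month_winter)),
    as_exposure_row(mobility_exposure_delta(stack, mmt_curve, "seasonal",
                                            scen_summer, "heat",
                                            month_summer, month_winter)))

  structure(list(
    city_id = stack$city_id,
    mobility = mob,
    seasonal = if (is.null(seas)) NULL else seas$fits,
    coupling = data.frame(
      slope_permille_per_C = if (is.null(seas)) NA_real_
      else seas$coupling$slope,
      intercept_permille = if (is.null(seas)) NA_real_
      else seas$coupling$intercept,
      r_squared = if (is.null(seas)) NA_real_
      else seas$coupling$r_squared),
    profiles = list(night_pop = prof_night, dP_daily = prof_dP),
    exponential_fits = list(night_pop = exp_fit_night),
    exposure = exposure,
    temperatures = data.frame(t_bar = t_bar, t_weighted = t_weighted,
                              t_elevation = t_weighted - t_bar),
    curve_summary = data.frame(
      fraction_above_mean = if (is.null(curves)) NA_real_
      else curves$fraction_above_mean,
      curve_final = if (is.null(curves)) NA_real_
      else curves$cum_fraction[length(curves$cum_fraction)]),
    risk = if (is.null(risk)) NULL else
      data.frame(T_weighted = risk$T_weighted, T_mean = risk$T_mean,
                 rr_weighted = risk$rr_weighted, rr_mean = risk$rr_mean,
                 delta_rr_pct = risk$delta_rr_pct, clamped = risk$clamped)),
    class = "city_report")
}

as_exposure_row <- function(x) {
  data.frame(side = x$side, timescale = x$timescale, scenario = x$scenario,
             exposure_static = x$exposure_static,
             exposure_dynamic = x$exposure_dynamic,
             delta = x$delta, delta_pct = x$delta_pct,
             pop_at_mmt = x$pop_at_mmt, stringsAsFactors = FALSE)
}

#' Ensemble analysis across cities
#'
#' Runs [run_city()] for every stack, assembles the per-city table, counts
#' quadrants, summarises the key percentages (median and IQR, linear-
#' interpolation quantiles), and fits the daily-mobility scaling law on each
#' branch with enough cities. The rescaling reference is the ensemble's
#' largest April daytime total.
#'
#' @param stacks List of [city_stack()] objects (>= 3).
#' @param curves Optional list of [erf()] objects, recycled or named by
#'   city id.
#' @param ... Passed to [run_city()].
#' @return Object of class `ensemble_report`: list with `cities`
#'   (data.frame), `quadrant_counts`, `summary` (data.frame of median/IQR
#'   rows), `scaling` (list of `scaling_fit` per branch), `reports`.
#' @export
run_ensemble <- function(stacks, curves = NULL, ...) {
  if (length(stacks) < 3L)
    stop("insufficient data: need >= 3 cities", call. = FALSE)
  p_ref <- max(vapply(stacks, function(s)
    land_total(s$pop_day[[4L]], s$land_mask), numeric(1L)))
  get_curve <- function(i, id) {
    if (is.null(curves)) NULL
    else if (!is.null(names(curves)) && id %in% names(curves)) curves[[id]]
    else curves[[(i - 1L) %% length(curves) + 1L]]
  }
  reports <- lapply(seq_along(stacks), function(i)
    run_city(stacks[[i]], curve = get_curve(i, stacks[[i]]$city_id),
             p_ref = p_ref, ...))

  cities <- do.call(rbind, lapply(reports, function(r) {
    heat <- r$exposure[r$exposure$side == "heat" &
                         r$exposure$timescale == "daily", ]
    cold <- r$exposure[r$exposure$side == "cold" &
                         r$exposure$timescale == "daily", ]
    seas <- r$exposure[r$exposure$timescale == "seasonal", ]
    cbind(r$mobility,
          data.frame(
            heat_delta = heat$delta, heat_delta_pct = heat$delta_pct,
            cold_delta = cold$delta, cold_delta_pct = cold$delta_pct,
            seasonal_heat_delta = seas$delta,
            seasonal_heat_delta_pct = seas$delta_pct,
            t_bar = r$temperatures$t_bar,
            t_weighted = r$temperatures$t_weighted,
            t_elevation = r$temperatures$t_elevation,
            fraction_above_mean = r$curve_summary$fraction_above_mean,
            coupling_slope = r$coupling$slope_permille_per_C,
            delta_rr_pct = if (is.null(r$risk)) NA_real_
            else r$risk$delta_rr_pct))
  }))

  quad <- table(factor(cities$quadrant, levels = c("I", "II", "III", "IV")))
  summ <- do.call(rbind, lapply(
    c("pct_daily", "pct_seasonal", "heat_delta_pct", "cold_delta_pct",
      "seasonal_heat_delta_pct", "t_elevation", "fraction_above_mean",
      "delta_rr_pct"),
    function(v) summarise_stat(cities[[v]], v)))

  scaling <- list()
  for (br in c("positive", "negative")) {
    fit <- tryCatch(fit_scaling(p_night_july(stacks), cities$dP_daily, br),
                    error = function(e) NULL)
    if (!is.null(fit)) scaling[[br]] <- fit
  }
  structure(list(cities = cities, quadrant_counts = quad, summary = summ,
                 scaling = scaling, reports = reports),
            class = "ensemble_report")
}

p_night_july <- function(stacks) {
  vapply(stacks, function(s) land_total(s$pop_night[[7L]], s$land_mask),
         numeric(1L))
}

# median and IQR (Q3 - Q1, type-7 linear interpolation quantiles)
summarise_stat <- function(x, name) {
  x <- x[is.finite(x)]
  if (!length(x))
    return(data.frame(stat = name, n = 0L, median = NA_real_, q1 = NA_real_,
                      q3 = NA_real_, iqr = NA_real_))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(stat = name, n = length(x), median = q[2L], q1 = q[1L],
             q3 = q[3L], iqr = q[3L] - q[1L])
}

#' Write a city report to CSV tables
#'
#' One file per table (`mobility.csv`, `seasonal.csv`, `coupling.csv`,
#' `exposure.csv`, `temperatures.csv`, `curve.csv`, `risk.csv` when present,
#' and the two radial profiles). Byte-stable for identical reports.
#'
#' @param report A [run_city()] result.
#' @param dir Output directory (created if needed).
#' @export
write_city_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(d, name)
    utils::write.csv(d, file.path(dir, name), row.names = FALSE)
  wr(report$mobility, "mobility.csv")
  if (!is.null(report$seasonal)) wr(report$seasonal, "seasonal.csv")
  wr(report$coupling, "coupling.csv")
  wr(report$exposure, "exposure.csv")
  wr(report$temperatures, "temperatures.csv")
  wr(report$curve_summary, "curve.csv")
  wr(as.data.frame(report$profiles$night_pop), "profile_night_pop.csv")
  wr(as.data.frame(report$profiles$dP_daily), "profile_dP_daily.csv")
  if (!is.null(report$risk)) wr(report$risk, "risk.csv")
  invisible(dir)
}

#' Write an ensemble report (CSV + JSON)
#'
#' `cities.csv`, `summary.csv`, and `ensemble.json` (quadrant counts, summary
#' statistics, scaling fits).
#'
#' @param report A [run_ensemble()] result.
#' @param dir Output directory (created if needed).
#' @export
write_ensemble_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$cities, file.path(dir, "cities.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(quadrant_counts = as.list(report$quadrant_counts),
         summary = report$summary,
         scaling = lapply(report$scaling, unclass)),
    file.path(dir, "ensemble.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
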