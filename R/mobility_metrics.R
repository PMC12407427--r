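#' Daily population change (day minus night)
#'
#' City-total and per-cell difference between the daytime and nighttime
#' population frames of a month (July by convention): the net commuter inflow
#' a static residential census misses. The percentage is relative to the same
#' month's nighttime total.
#'
#' @param stack A [city_stack()].
#' @param month Calendar month, default 7 (July).
#' @return List with `total` (persons), `field` (per-cell, `NA` off land),
#'   `pct` (% of the month's nighttime total), `month`.
#' @export
delta_p_daily <- function(stack, month = 7L) {
  month <- as.integer(month)
  day <- stack$pop_day[[month]]; night <- stack$pop_night[[month]]
  if (is.null(day) || is.null(night))
    stop("invalid input: missing day or night frame for month ", month,
         call. = FALSE)
  field <- mask_field(day - night, stack$land_mask)
  total <- sum(field, na.rm = TRUE)
  night_total <- land_total(night, stack$land_mask)
  list(total = total, field = field,
       pct = 100 * total / night_total, month = month)
}

#' Seasonal population change (summer minus winter nighttime)
#'
#' City-total and per-cell difference between the July and January nighttime
#' frames: positive for touristic cities that gain residents in summer,
#' negative for the majority pattern of a summer exodus. The percentage is
#' relative to the January nighttime total.
#'
#' @param stack A [city_stack()].
#' @param month_summer,month_winter Months compared, defaults 7 and 1.
#' @return List with `total` (persons), `field`, `pct` (% of the winter
#'   nighttime total).
#' @export
delta_p_seasonal <- function(stack, month_summer = 7L, month_winter = 1L) {
  hi <- stack$pop_night[[as.integer(month_summer)]]
  lo <- stack$pop_night[[as.integer(month_winter)]]
  if (is.null(hi) || is.null(lo))
    stop("invalid input: missing nighttime frame", call. = FALSE)
  field <- mask_field(hi - lo, stack$land_mask)
  total <- sum(field, na.rm = TRUE)
  list(total = total, field = field,
       pct = 100 * total / land_total(lo, stack$land_mask))
}

#' Classify a city's mobility quadrant
#'
#' Four regimes from the signs of the daily and seasonal population changes:
#' quadrant I = daytime- and winter-peaked (positive daily change, negative
#' July-minus-January seasonal change, the majority of European cities),
#' II = nighttime- and winter-peaked, III = nighttime- and summer-peaked,
#' IV = daytime- and summer-peaked (touristic destinations). A delta of
#' exactly zero is unclassifiable and returns `NA` with a warning rather than
#' being silently assigned.
#'
#' `summer_positive_is_winter = TRUE` flips the seasonal sign convention
#' (i.e. treats a positive seasonal delta as winter-peaked), for inputs whose
#' seasonal delta is defined January-minus-July.
#'
#' @param dP_daily Daily population change, persons.
#' @param dP_seasonal Seasonal (July minus January nighttime) change, persons.
#' @param summer_positive_is_winter Flip switch for the seasonal sign
#'   convention; default `FALSE`.
#' @return `"I"`, `"II"`, `"III"`, `"IV"`, or `NA_character_`.
#' @export
classify_quadrant <- function(dP_daily, dP_seasonal,
                              summer_positive_is_winter = FALSE) {
  if (!is.finite(dP_daily) || !is.finite(dP_seasonal))
    stop("invalid input: deltas must be finite", call. = FALSE)
  if (dP_daily == 0 || dP_seasonal == 0) {
    warning("zero delta: city is unclassifiable", call. = FALSE)
    return(NA_character_)
  }
  seas <- if (summer_positive_is_winter) -dP_seasonal else dP_seasonal
  winter_peaked <- seas < 0
  if (dP_daily > 0) {
    if (winter_peaked) "I" else "IV"
  } else {
    if (winter_peaked) "II" else "III"
  }
}

#' Per-city mobility summary row
#'
#' @param stack A [city_stack()].
#' @param month Month for the daily delta (default 7).
#' @return One-row data.frame: `city_id`, `dP_daily`, `dP_seasonal`,
#'   `pct_daily`, `pct_seasonal`, `quadrant`.
#' @export
mobility_summary <- function(stack, month = 7L) {
  dd <- delta_p_daily(stack, month)
  ds <- delta_p_seasonal(stack)
  quad <- tryCatch(classify_quadrant(dd$total, ds$total),
                   warning = function(w) NA_character_)
  data.frame(city_id = stack$city_id, dP_daily = dd$total,
             dP_seasonal = ds$total, pct_daily = dd$pct,
             pct_seasonal = ds$pct, quadrant = quad,
             stringsAsFactors = FALSE)
}

#' Scaling of daily population change with city size
#'
#' Ordinary least squares of `log10(|dP_daily|)` on `log10(P_night)` across
#' cities. The positive branch uses cities gaining population by day; the
#' negative branch negates the daily change of nighttime-dominant cities so
#' its magnitude can be log-transformed. An exponent near 1 is the gravity-law
#' expectation: total inflow proportional to destination population.
#'
#' @param p_night Nighttime population totals, persons (one per city).
#' @param dp_daily Daily population changes, persons (one per city).
#' @param branch `"positive"` or `"negative"`.
#' @return Object of class `scaling_fit`: list with `beta`, `intercept`
#'   (log10 persons), `r_squared`, `n_cities`, `branch`.
#' @export
fit_scaling <- function(p_night, dp_daily, branch = c("positive", "negative")) {
  branch <- match.arg(branch)
  stopifnot(length(p_night) == length(dp_daily))
  keep <- if (branch == "positive") dp_daily > 0 else dp_daily < 0
  keep <- keep & is.finite(p_night) & is.finite(dp_daily) & p_night > 0
  x <- log10(p_night[keep])
  yv <- if (branch == "positive") dp_daily[keep] else -dp_daily[keep]
  y <- log10(yv)
  if (sum(keep) < 3L)
    stop("insufficient data: need >= 3 cities on the ", branch, " branch",
         call. = FALSE)
  if (stats::var(x) == 0)
    stop("insufficient data: zero variance in city size", call. = FALSE)
  fit <- stats::lm(y ~ x)
  structure(list(beta = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n_cities = sum(keep), branch = branch),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit %s> beta = %.4g (R2 = %.4g, n = %d)\n",
              x$branch, x$beta, x$r_squared, x$n_cities))
  invisible(x)
}
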