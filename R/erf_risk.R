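#' Exposure-response function (temperature vs relative mortality risk)
#'
#' A tabulated, typically J- or U-shaped curve mapping daily mean temperature
#' to the relative risk (RR) of mortality for one city and age group. The
#' minimum mortality temperature (MMT) is the knot temperature at which RR is
#' lowest — the population's optimum — and the curve is normalised so that
#' `RR(MMT) = 1`. Ties in the minimum are broken toward the lower
#' temperature; a curve whose minimum sits on the boundary of the tabulated
#' range (e.g. monotone) is degenerate and triggers a warning.
#'
#' @param knots Data.frame with columns `temperature_C` (strictly increasing)
#'   and `rr` (positive).
#' @param mmp Optional minimum mortality percentile (metadata only).
#' @param age_group Age-group label, default `"45-65"` (the working-age
#'   group most likely to commute).
#' @return Object of class `erf`: list with `knots`, `mmt`, `mmp`,
#'   `age_group`, `clamp = "boundary"`.
#' @export
erf <- function(knots, mmp = NA_real_, age_group = "45-65") {
  stopifnot(is.data.frame(knots),
            all(c("temperature_C", "rr") %in% names(knots)))
  if (nrow(knots) < 3L)
    stop("invalid curve: need at least 3 knots", call. = FALSE)
  if (!all(is.finite(knots$temperature_C)) || !all(is.finite(knots$rr)))
    stop("invalid curve: non-finite knot values", call. = FALSE)
  if (any(diff(knots$temperature_C) <= 0))
    stop("invalid curve: knot temperatures must be strictly increasing",
         call. = FALSE)
  if (any(knots$rr <= 0))
    stop("invalid curve: RR must be positive", call. = FALSE)
  i_min <- which(knots$rr == min(knots$rr))[1L]   # tie -> lower temperature
  if (i_min == 1L || i_min == nrow(knots))
    warning("ERF minimum lies on the boundary of the tabulated range",
            call. = FALSE)
  knots$rr <- knots$rr / knots$rr[i_min]
  structure(list(knots = knots[, c("temperature_C", "rr")],
                 mmt = knots$temperature_C[i_min], mmp = mmp,
                 age_group = age_group, clamp = "boundary"),
            class = "erf")
}

#' @export
print.erf <- function(x, ...) {
  cat(sprintf("<erf %s> %d knots over [%g, %g] degC, MMT = %g degC\n",
              x$age_group, nrow(x$knots), min(x$knots$temperature_C),
              max(x$knots$temperature_C), x$mmt))
  invisible(x)
}

#' Minimum mortality temperature of an ERF
#'
#' @param curve An [erf()].
#' @return Degrees Celsius.
#' @export
extract_mmt <- function(curve) {
  stopifnot(inherits(curve, "erf"))
  curve$mmt
}

#' Relative risk at given temperatures
#'
#' Piecewise-linear interpolation between the tabulated knots. Temperatures
#' beyond the knot range are clamped to the boundary knot's RR (so an
#' out-of-range hot temperature takes the maximum RR on the warm side); the
#' returned vector carries a `clamped` attribute flagging where this
#' happened, since clamped values are lower bounds on the true risk.
#'
#' @param curve An [erf()].
#' @param T Temperature(s), degC.
#' @return Numeric RR vector with logical attribute `clamped`.
#' @export
rr_at <- function(curve, T) {
  stopifnot(inherits(curve, "erf"))
  kn <- curve$knots
  out <- stats::approx(kn$temperature_C, kn$rr, xout = T, rule = 2)$y
  attr(out, "clamped") <- T < kn$temperature_C[1L] |
    T > kn$temperature_C[nrow(kn)]
  out
}

#' Mobility-induced change in relative risk
#'
#' Compares the RR at the incoming-population-weighted temperature with the
#' RR at the city's mean temperature, as a relative percent change:
#' `100 * (RR(<T>) - RR(Tbar)) / RR(Tbar)`. Positive when the population
#' influx concentrates where the ERF says risk is higher; below the MMT a
#' warmer weighted temperature gives a negative (protective) change.
#'
#' @param curve An [erf()].
#' @param T_weighted Incoming-population-weighted temperature, degC.
#' @param T_mean City mean temperature, degC.
#' @return Object of class `risk_delta`: list with `T_weighted`, `T_mean`,
#'   `rr_weighted`, `rr_mean`, `delta_rr_pct`, `clamped` (logical, either
#'   evaluation clamped).
#' @export
delta_rr_percent <- function(curve, T_weighted, T_mean) {
  if (!is.finite(T_weighted) || !is.finite(T_mean))
    stop("invalid input: temperatures must be finite", call. = FALSE)
  rr_w <- rr_at(curve, T_weighted)
  rr_m <- rr_at(curve, T_mean)
  structure(list(T_weighted = T_weighted, T_mean = T_mean,
                 rr_weighted = as.numeric(rr_w), rr_mean = as.numeric(rr_m),
                 delta_rr_pct =
                   100 * (as.numeric(rr_w) - as.numeric(rr_m)) /
                   as.numeric(rr_m),
                 clamped = any(attr(rr_w, "clamped"), attr(rr_m, "clamped"))),
            class = "risk_delta")
}

#' Read an ERF from CSV
#'
#' Expects columns `temperature_C` and `rr`; leading comment lines of the
#' form `# key: value` may carry `mmt`, `mmp`, and `age_group` metadata
#' (`mmt` in the header is informational — the curve's MMT is always
#' recomputed from the knots).
#'
#' @param path CSV file path.
#' @return An [erf()].
#' @export
read_erf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), ":")[[1L]]
    if (length(kv) == 2L) meta[[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  d <- utils::read.csv(text = lines[!grepl("^#", lines)])
  erf(d,
      mmp = if (!is.null(meta$mmp)) as.numeric(meta$mmp) else NA_real_,
      age_group = if (!is.null(meta$age_group)) meta$age_group else "45-65")
}

#' Write an ERF to CSV
#'
#' @param curve An [erf()].
#' @param path Output path.
#' @export
write_erf <- function(curve, path) {
  stopifnot(inherits(curve, "erf"))
  hdr <- c(sprintf("# mmt: %.10g", curve$mmt),
           if (is.finite(curve$mmp)) sprintf("# mmp: %.10g", curve$mmp),
           sprintf("# age_group: %s", curve$age_group))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(curve$knots, con, row.names = FALSE)
  invisible(path)
}
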