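#' Fit the 12-month cosine model to a monthly series
#'
#' Least-squares fit of `P_t = A * cos(2*pi*(t + b)/12) + c` to twelve monthly
#' values (`t = 1` is January). For population series the phase shift `b` is
#' bounded to `[-2, 0]`, the convention under which the seasonal extremum
#' falls in June-August (`b = 0` or `-2` put it in June or August); the
#' amplitude `A` keeps a free sign, so winter-peaked series come out with
#' `A < 0` at the corresponding phase. Temperature series are fitted without
#' phase bounds.
#'
#' The optimisation uses variable projection: for any fixed `b` the model is
#' linear in `(A, c)`, so the profiled residual sum of squares is minimised
#' over `b` alone (closed-form trigonometric regression when unbounded; a
#' grid-plus-polish line search over `[-2, 0]` when bounded). This minimises
#' the same nonlinear least-squares objective as an iterative fitter but
#' cannot fail to converge, and is exact on noiseless generative series.
#'
#' @param series Numeric vector of 12 finite values (persons or degC),
#'   January first.
#' @param bound_phase Bound `b` to `[-2, 0]`? Default `TRUE` (population
#'   convention).
#' @return Object of class `seasonal_fit`: list with `A`, `b`, `c`,
#'   `r_squared`, `fitted`.
#' @export
fit_cosine <- function(series, bound_phase = TRUE) {
  if (length(series) != 12L || !all(is.finite(series)))
    stop("invalid input: `series` must be 12 finite values", call. = FALSE)
  t <- 1:12
  y <- as.numeric(series)

  # (A, c) and RSS for a fixed phase, linear least squares
  solve_at <- function(b) {
    x <- cos(2 * pi * (t + b) / 12)
    vx <- sum((x - mean(x))^2)
    if (vx < 1e-12) {                     # degenerate regressor
      A <- 0; cc <- mean(y)
    } else {
      A <- sum((x - mean(x)) * (y - mean(y))) / vx
      cc <- mean(y) - A * mean(x)
    }
    res <- y - (A * x + cc)
    list(A = A, c = cc, b = b, rss = sum(res^2))
  }

  if (!bound_phase) {
    # closed form: regress on cos and sin components, then recover (A, b)
    th <- 2 * pi * t / 12
    X <- cbind(1, cos(th), sin(th))
    beta <- qr.solve(X, y)
    A <- sqrt(beta[2L]^2 + beta[3L]^2)
    if (A < .Machine$double.eps * max(1, abs(beta[1L]))) {
      best <- list(A = 0, c = beta[1L], b = NA_real_,
                   rss = sum((y - beta[1L])^2))
    } else {
      phi <- atan2(-beta[3L], beta[2L])   # A cos(theta + phi) expansion
      b <- phi * 12 / (2 * pi)
      if (b > 6) b <- b - 12
      if (b <= -6) b <- b + 12
      best <- solve_at(b)
    }
  } else {
    grid <- seq(-2, 0, length.out = 81L)
    rss_g <- vapply(grid, function(b) solve_at(b)$rss, numeric(1L))
    i <- which.min(rss_g)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(function(b) solve_at(b)$rss, c(lo, hi),
                           tol = .Machine$double.eps^0.5)
    cand <- list(solve_at(opt$minimum), solve_at(-2), solve_at(0))
    best <- cand[[which.min(vapply(cand, `[[`, numeric(1L), "rss"))]]
  }
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot > 0) 1 - best$rss / sstot else NA_real_
  structure(list(A = unname(best$A), b = unname(best$b),
                 c = unname(best$c), r_squared = r2,
                 fitted = eq1_cosine_safe(t, best$A, best$b, best$c)),
            class = "seasonal_fit")
}

eq1_cosine_safe <- function(t, A, b, c) {
  if (is.na(b)) rep(c, length(t)) else A * cos(2 * pi * (t + b) / 12) + c
}

#' @export
print.seasonal_fit <- function(x, ...) {
  cat(sprintf("<seasonal_fit> A = %.4g, b = %.4g months, c = %.4g, R2 = %.4g\n",
              x$A, x$b, x$c, x$r_squared))
  invisible(x)
}

#' Linear coupling of monthly population to monthly temperature
#'
#' Ordinary least squares of the relative monthly population deviation,
#' `1000 * (P_t - Pbar) / Pbar` (per mille of the annual mean), on monthly
#' mean temperature. A positive slope means population is in phase with the
#' temperature cycle (summer influx, e.g. touristic coastal cities); a
#' negative slope means out of phase (summer exodus).
#'
#' @param pop Numeric vector of 12 monthly population totals, persons.
#' @param temp Numeric vector of 12 monthly mean temperatures, degC.
#' @return Object of class `linear_coupling`: list with `slope` (permille per
#'   degC), `intercept` (permille), `r_squared`.
#' @export
fit_linear_coupling <- function(pop, temp) {
  if (length(pop) != 12L || length(temp) != 12L ||
      !all(is.finite(pop)) || !all(is.finite(temp)))
    stop("invalid input: need 12 finite values in both series", call. = FALSE)
  pbar <- mean(pop)
  if (pbar <= 0) stop("invalid input: mean population must be positive",
                      call. = FALSE)
  if (stats::var(temp) == 0)
    stop("insufficient variation: constant temperature series",
         call. = FALSE)
  dev <- 1000 * (pop - pbar) / pbar
  fit <- stats::lm(dev ~ temp)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = suppressWarnings(summary(fit)$r.squared)),
            class = "linear_coupling")
}

#' Seasonal fit table for one city
#'
#' Fits the cosine model to the monthly nighttime and daytime population
#' totals (phase bounded) and to monthly mean temperature (unbounded), plus
#' the linear population-temperature coupling for the nighttime series.
#' The `good_fit` flag marks fits with R-squared above 0.5.
#'
#' @param stack A [city_stack()].
#' @return List with `fits` (data.frame: series, A, b, c, r_squared,
#'   good_fit) and `coupling` (a [fit_linear_coupling()] result).
#' @export
seasonal_fit_table <- function(stack) {
  pn <- monthly_population_totals(stack, "night")
  pd <- monthly_population_totals(stack, "day")
  tm <- monthly_mean_temperature(stack)
  fits <- list(night_pop = fit_cosine(pn, bound_phase = TRUE),
               day_pop = fit_cosine(pd, bound_phase = TRUE),
               temperature = fit_cosine(tm, bound_phase = FALSE))
  tab <- data.frame(
    series = names(fits),
    A = vapply(fits, `[[`, numeric(1L), "A"),
    b = vapply(fits, `[[`, numeric(1L), "b"),
    c = vapply(fits, `[[`, numeric(1L), "c"),
    r_squared = vapply(fits, `[[`, numeric(1L), "r_squared"),
    row.names = NULL)
  tab$good_fit <- !is.na(tab$r_squared) & tab$r_squared > 0.5
  list(fits = tab, coupling = fit_linear_coupling(pn, tm))
}
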