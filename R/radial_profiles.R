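#' Cross-city rescaling parameters
#'
#' Cities of different sizes are made comparable by dividing both radial
#' distance and population density by `k = (P_city / P_ref)^(1/3)`, with
#' `P_ref` the reference (largest) city's total — under this transform the
#' radial profiles of scaled-copy cities collapse onto a common curve. In the
#' reference city itself `k = 1`.
#'
#' @param P_city This city's total population, persons (conventionally the
#'   April daytime total).
#' @param P_ref The reference city's total, persons.
#' @return Object of class `rescale_params`: list with `k`, `P_city`, `P_ref`.
#' @export
rescale_params <- function(P_city, P_ref) {
  if (!is.finite(P_city) || !is.finite(P_ref) || P_city <= 0 || P_ref <= 0)
    stop("invalid params: populations must be positive", call. = FALSE)
  structure(list(k = (P_city / P_ref)^(1 / 3),
                 P_city = P_city, P_ref = P_ref),
            class = "rescale_params")
}

#' Rescale distance and population
#'
#' `r' = r / k`, `P' = P / k`.
#'
#' @param r Distance(s), km.
#' @param P Population value(s).
#' @param params A [rescale_params()].
#' @return List with `r` and `P` rescaled.
#' @export
rescale <- function(r, P, params) {
  stopifnot(inherits(params, "rescale_params"))
  if (!is.finite(params$k) || params$k <= 0)
    stop("invalid params: k must be positive", call. = FALSE)
  list(r = r / params$k, P = P / params$k)
}

#' Rescaled annular radial profile of population and temperature deviation
#'
#' Assigns every land cell its rescaled distance `r' = r/k` from the city
#' centre and averages, per 0.5-km annulus from 1 to 30 rescaled km
#' (half-open bins `[lo, hi)`), the rescaled population density `P/k`
#' (persons per km^2, so profiles of scaled-copy cities are identical) and
#' the temperature deviation from the domain mean, `T - Tbar`. Cells closer
#' than 1 rescaled km are outside the first bin and ignored; empty annuli are
#' reported with `n_cells = 0` and `NA` means, not zeros.
#'
#' @param field_pop Population raster on the stack grid (persons per cell).
#' @param field_T Temperature raster on the stack grid, degC.
#' @param stack A [city_stack()] (provides grid geometry, mask, centre).
#' @param params A [rescale_params()].
#' @param bin_edges Annulus edges in rescaled km, default `seq(1, 30, 0.5)`.
#' @return Object of class `radial_profile` (a data.frame): `bin_lo`,
#'   `bin_hi`, `n_cells`, `mean_pop` (rescaled persons/km^2), `mean_dT`
#'   (degC).
#' @export
build_radial_profile <- function(field_pop, field_T, stack, params,
                                 bin_edges = seq(1, 30, by = 0.5)) {
  stopifnot(inherits(stack, "city_stack"), inherits(params, "rescale_params"))
  dm <- dim(stack$land_mask)
  if (!identical(dim(field_pop), dm) || !identical(dim(field_T), dm))
    stop("invalid input: fields not aligned to the stack grid", call. = FALSE)
  ext <- dm[c(2L, 1L)] * stack$cell_km
  if (any(stack$center < 0) || stack$center[1L] > ext[1L] ||
      stack$center[2L] > ext[2L])
    stop("invalid input: centre lies outside the grid", call. = FALSE)
  land <- stack$land_mask
  r_resc <- cell_distances(stack)[land] / params$k
  dens <- (field_pop[land] / stack$cell_km^2) / params$k
  tbar <- mean(field_T[land], na.rm = TRUE)
  dT <- field_T[land] - tbar
  bin <- findInterval(r_resc, bin_edges, rightmost.closed = FALSE)
  bin[bin == length(bin_edges)] <- 0L       # beyond the last edge
  nb <- length(bin_edges) - 1L
  out <- data.frame(bin_lo = bin_edges[-length(bin_edges)],
                    bin_hi = bin_edges[-1L])
  out$n_cells <- vapply(seq_len(nb), function(i) sum(bin == i, na.rm = TRUE),
                        integer(1L))
  agg <- function(v) vapply(seq_len(nb), function(i) {
    sel <- bin == i & !is.na(v)
    if (!any(sel)) NA_real_ else mean(v[sel])
  }, numeric(1L))
  out$mean_pop <- agg(dens)
  out$mean_dT <- agg(dT)
  class(out) <- c("radial_profile", "data.frame")
  attr(out, "k") <- params$k
  attr(out, "t_bar") <- tbar
  out
}

#' Exponential fit of population against temperature deviation
#'
#' Nonlinear least squares of `mean_pop = a * exp(lam * mean_dT)` over the
#' non-empty annuli of a radial profile, on untransformed values (not
#' log-linearised). A positive `lam` quantifies the exponential concentration
#' of population toward warmer (more central) locations.
#'
#' @param profile A [build_radial_profile()] result.
#' @param response Currently only `"pop_vs_dT"`.
#' @return Object of class `exponential_fit`: list with `a`, `lam` (1/degC),
#'   `r_squared`, `n_bins`.
#' @export
fit_exponential <- function(profile, response = "pop_vs_dT") {
  response <- match.arg(response)
  d <- profile[profile$n_cells > 0 & is.finite(profile$mean_pop) &
                 is.finite(profile$mean_dT), , drop = FALSE]
  if (nrow(d) < 4L)
    stop("insufficient data: need >= 4 non-empty bins", call. = FALSE)
  if (stats::var(d$mean_pop) == 0)       # flat profile: lam = 0 exactly
    return(structure(list(a = d$mean_pop[1L], lam = 0,
                          r_squared = NA_real_, n_bins = nrow(d)),
                     class = "exponential_fit"))
  # log-linear start (guarded for non-positive values), then true NLS
  pos <- d$mean_pop > 0
  if (sum(pos) >= 2L) {
    lf <- stats::lm(log(d$mean_pop[pos]) ~ d$mean_dT[pos])
    start <- list(a = exp(unname(stats::coef(lf)[1L])),
                  lam = unname(stats::coef(lf)[2L]))
  } else {
    start <- list(a = max(d$mean_pop, 1e-6), lam = 0)
  }
  if (!all(vapply(start, is.finite, logical(1L))))
    start <- list(a = mean(d$mean_pop), lam = 0)
  fit <- tryCatch(
    minpack.lm::nlsLM(mean_pop ~ a * exp(lam * mean_dT), data = d,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("fit failure: ", conditionMessage(e),
                             call. = FALSE))
  co <- stats::coef(fit)
  res <- d$mean_pop - stats::fitted(fit)
  sstot <- sum((d$mean_pop - mean(d$mean_pop))^2)
  structure(list(a = unname(co[["a"]]), lam = unname(co[["lam"]]),
                 r_squared = if (sstot > 0) 1 - sum(res^2) / sstot
                 else NA_real_,
                 n_bins = nrow(d)),
            class = "exponential_fit")
}
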