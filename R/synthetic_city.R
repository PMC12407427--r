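#' Configuration for a synthetic city
#'
#' Defines the generative model of a monocentric city: exponential nighttime
#' population density, a radially decaying urban heat island (UHI) superposed
#' on a sinusoidal seasonal climate, a 12-month cosine cycle of total
#' nighttime population, and a gravity-law daytime commuter inflow from origin
#' sites on a ring outside the domain. Every random draw is fixed by `seed`.
#'
#' The defaults describe a mid-sized European city: a 61 x 61 km domain at
#' 1-km cells, ~1.1 million residents (central density 5,000 persons/cell,
#' e-folding radius 6 km), a 2.5 degC UHI decaying over 8 km, a 10 degC
#' seasonal temperature half-range peaking in July, a 2% seasonal population
#' cycle peaking in winter (out of phase with temperature, the majority
#' pattern among European cities), and a gravity inflow of roughly 15% of the
#' nighttime population. The record spans the calendar years 2010-2012.
#'
#' The gravity constant is named `gravity_g` (not `k`) to avoid a collision
#' with the distance/population rescaling factor `k` used by the radial
#' profile module.
#'
#' @param seed Integer seed fixing all random draws.
#' @param grid_size Odd number of cells per side (a centre cell must exist).
#' @param cell_km Cell size, km.
#' @param P0 Central nighttime population, persons per cell.
#' @param r_p Population e-folding radius, km.
#' @param T_rural Rural (far-field) annual-mean temperature, degC.
#' @param uhi_amplitude UHI intensity at the centre, degC.
#' @param r_T UHI e-folding radius, km.
#' @param season_T_amp Seasonal temperature amplitude, degC. The seasonal term
#'   is `season_T_amp * cos(2*pi*(month + season_T_phase)/12)`; the default
#'   (-10, phase -1) places the maximum in July and the minimum in January.
#' @param season_T_phase Seasonal temperature phase, months.
#' @param pop_A Amplitude of the monthly nighttime-total cosine, persons.
#'   Positive with `pop_b` in `[-2, 0]` gives a summer trough (winter-peaked
#'   city); negative gives a summer peak (touristic city). `NULL` means 2% of
#'   `pop_c`.
#' @param pop_b Phase shift of the population cosine, months, in `[-2, 0]`.
#' @param pop_c Baseline (annual mean) total population, persons. `NULL` means
#'   the total of the exponential density field.
#' @param gravity_g Gravity constant (dimensionless). Positive values produce
#'   daytime inflow; negative values are allowed to synthesize nighttime-
#'   dominant cities.
#' @param gravity_gamma Distance-decay exponent of the gravity law.
#' @param n_origins Number of origin sites on the external ring.
#' @param origin_pop Population of each origin site (recycled to
#'   `n_origins`), persons.
#' @param ring_radius_km Radius of the origin ring from the city centre;
#'   `NULL` means 1.5 times the half-extent of the domain (safely outside it).
#' @param noise_sd Daily temperature noise standard deviation, degC.
#' @param years Calendar years of the daily temperature record.
#'
#' @return An object of class `synthetic_city_config`.
#' @export
synthetic_city_config <- function(seed = 1L, grid_size = 61L, cell_km = 1,
                                  P0 = 5000, r_p = 6,
                                  T_rural = 10, uhi_amplitude = 2.5, r_T = 8,
                                  season_T_amp = -10, season_T_phase = -1,
                                  pop_A = NULL, pop_b = -1, pop_c = NULL,
                                  gravity_g = 6e-4, gravity_gamma = 2,
                                  n_origins = 8L, origin_pop = 5e4,
                                  ring_radius_km = NULL, noise_sd = 0.5,
                                  years = 2010:2012) {
  if (grid_size %% 2 == 0)
    stop("invalid config: `grid_size` must be odd", call. = FALSE)
  if (r_p <= 0 || r_T <= 0 || cell_km <= 0)
    stop("invalid config: radii and cell size must be positive",
         call. = FALSE)
  if (pop_b < -2 || pop_b > 0)
    stop("invalid config: `pop_b` must lie in [-2, 0]", call. = FALSE)
  if (is.null(ring_radius_km))
    ring_radius_km <- 1.5 * grid_size * cell_km / 2
  cfg <- structure(
    list(seed = as.integer(seed), grid_size = as.integer(grid_size),
         cell_km = cell_km, P0 = P0, r_p = r_p,
         T_rural = T_rural, uhi_amplitude = uhi_amplitude, r_T = r_T,
         season_T_amp = season_T_amp, season_T_phase = season_T_phase,
         pop_A = pop_A, pop_b = pop_b, pop_c = pop_c,
         gravity_g = gravity_g, gravity_gamma = gravity_gamma,
         n_origins = as.integer(n_origins),
         origin_pop = rep_len(origin_pop, n_origins),
         ring_radius_km = ring_radius_km,
         noise_sd = noise_sd, years = as.integer(years)),
    class = "synthetic_city_config")
  base_total <- sum(config_base_field(cfg))
  if (is.null(cfg$pop_c)) cfg$pop_c <- base_total
  if (is.null(cfg$pop_A)) cfg$pop_A <- 0.02 * cfg$pop_c
  totals <- eq1_cosine(1:12, cfg$pop_A, cfg$pop_b, cfg$pop_c)
  if (any(totals <= 0))
    stop("invalid config: monthly totals must stay positive", call. = FALSE)
  cfg
}

# distance-from-centre matrix for a config grid
config_distances <- function(config) {
  n <- config$grid_size
  coords <- (seq_len(n) - 0.5) * config$cell_km
  ctr <- n * config$cell_km / 2
  dx <- matrix(rep(coords - ctr, each = n), n, n)
  dy <- matrix(rep(coords - ctr, n), n, n)
  sqrt(dx^2 + dy^2)
}

config_base_field <- function(config) {
  config$P0 * exp(-config_distances(config) / config$r_p)
}

# the 12-month cosine model for totals
eq1_cosine <- function(t, A, b, c) A * cos(2 * pi * (t + b) / 12) + c

#' Exponential nighttime population field
#'
#' `P(cell) = P0 * exp(-r / r_p)` with `r` the distance of the cell centre
#' from the domain centre in km. Deterministic given the config.
#'
#' @param config A [synthetic_city_config()].
#' @return Numeric matrix of persons per cell.
#' @export
make_population_field <- function(config) {
  stopifnot(inherits(config, "synthetic_city_config"))
  config_base_field(config)
}

#' Daily temperature cube for a synthetic city
#'
#' `T(cell, d) = T_rural + season_T_amp * cos(2*pi*(m(d) + season_T_phase)/12)
#' + uhi_amplitude * exp(-r / r_T) + eps`, with `m(d)` the calendar month of
#' day `d` and `eps ~ Normal(0, noise_sd)` drawn independently per cell and
#' day under the config seed. Identical config and seed give a bit-identical
#' cube.
#'
#' @param config A [synthetic_city_config()].
#' @param dates `Date` vector; default all days of `config$years`.
#' @return Array `ndays x grid x grid` of degrees Celsius.
#' @export
make_temperature_cube <- function(config, dates = NULL) {
  stopifnot(inherits(config, "synthetic_city_config"))
  if (is.null(dates)) dates <- config_dates(config)
  dates <- as.Date(dates)
  n <- config$grid_size
  uhi <- config$uhi_amplitude * exp(-config_distances(config) / config$r_T)
  mon <- as.integer(format(dates, "%m"))
  seasonal <- config$T_rural +
    config$season_T_amp * cos(2 * pi * (mon + config$season_T_phase) / 12)
  nd <- length(dates)
  cube <- array(rep(seasonal, n * n), dim = c(nd, n, n)) +
    array(rep(as.vector(uhi), each = nd), dim = c(nd, n, n))
  if (config$noise_sd > 0) {
    cube <- cube + with_seed(config$seed, {
      array(stats::rnorm(nd * n * n, sd = config$noise_sd),
            dim = c(nd, n, n))
    })
  }
  cube
}

config_dates <- function(config) {
  yr <- range(config$years)
  seq(as.Date(sprintf("%d-01-01", yr[1L])),
      as.Date(sprintf("%d-12-31", yr[2L])), by = "day")
}

# run code with a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Gravity-law commuter inflow
#'
#' Aggregate flow from external origin sites to a destination city under the
#' gravity law of mobility: `flow_i = g * P_dest * P_origin_i * r_i^(-gamma)`,
#' i.e. flows proportional to the product of the populations times an inverse
#' power of distance. Summed over origins this makes the total inflow
#' proportional to the destination population, which is what produces the
#' near-linear scaling of daytime population gain with city size.
#'
#' @param origin_pops Origin populations, persons (>= 0).
#' @param origin_distances Origin-to-city distances, km (> 0).
#' @param dest_pop Destination (city) population, persons.
#' @param g Gravity constant.
#' @param gamma Distance-decay exponent.
#' @return List with `total` (persons/day) and `flows` (per origin).
#' @export
gravity_inflow <- function(origin_pops, origin_distances, dest_pop, g, gamma) {
  if (length(origin_pops) != length(origin_distances))
    stop("invalid input: origins and distances differ in length",
         call. = FALSE)
  if (any(origin_distances <= 0))
    stop("invalid input: zero or negative distance (gravity singularity)",
         call. = FALSE)
  if (any(origin_pops < 0) || dest_pop < 0)
    stop("invalid input: populations must be non-negative", call. = FALSE)
  flows <- g * dest_pop * origin_pops * origin_distances^(-gamma)
  list(total = sum(flows), flows = flows)
}

#' Monthly daytime and nighttime population frames
#'
#' Nighttime totals follow the 12-month cosine
#' `A * cos(2*pi*(t + b)/12) + c` with `(pop_A, pop_b, pop_c)` and are spread
#' over the exponential density field; daytime frames add the gravity inflow
#' from the origin ring, allocated to cells proportionally to their nighttime
#' population (the denser, warmer centre attracts more commuters), so
#' `day = night * (1 + inflow/total)`. With `gravity_g > 0` every month's
#' daytime total exceeds its nighttime total.
#'
#' @param config A [synthetic_city_config()].
#' @return List with `night` and `day` (lists of 12 matrices), `totals`
#'   (data.frame: month, night, day, inflow), and `origins` (layout used).
#' @export
make_monthly_populations <- function(config) {
  stopifnot(inherits(config, "synthetic_city_config"))
  base <- config_base_field(config)
  w <- base / sum(base)
  totals <- eq1_cosine(1:12, config$pop_A, config$pop_b, config$pop_c)
  if (any(totals <= 0))
    stop("invalid config: negative monthly total", call. = FALSE)
  dists <- rep(config$ring_radius_km, config$n_origins)
  night <- day <- vector("list", 12L)
  inflow <- numeric(12L)
  for (t in 1:12) {
    night[[t]] <- w * totals[t]
    gi <- gravity_inflow(config$origin_pop, dists, totals[t],
                         config$gravity_g, config$gravity_gamma)
    inflow[t] <- gi$total
    day[[t]] <- night[[t]] * (1 + gi$total / totals[t])
  }
  list(night = night, day = day,
       totals = data.frame(month = 1:12, night = totals,
                           day = totals + inflow, inflow = inflow),
       origins = list(pop = config$origin_pop, distance_km = dists))
}

#' Assemble a complete synthetic city stack
#'
#' Runs the population and temperature generators and packs the result into a
#' [city_stack()] (all cells land unless a mask is supplied). The config and
#' seed are recorded in the stack metadata.
#'
#' @param config A [synthetic_city_config()].
#' @param land_mask Optional logical matrix; default all land.
#' @return A [city_stack()].
#' @export
make_city_stack <- function(config, land_mask = NULL) {
  stopifnot(inherits(config, "synthetic_city_config"))
  n <- config$grid_size
  if (is.null(land_mask)) land_mask <- matrix(TRUE, n, n)
  pops <- make_monthly_populations(config)
  dates <- config_dates(config)
  temp <- make_temperature_cube(config, dates)
  city_stack(city_id = sprintf("synthetic-%d", config$seed),
             land_mask = land_mask, pop_day = pops$day,
             pop_night = pops$night, temp = temp, dates = dates,
             cell_km = config$cell_km,
             meta = list(config = unclass(config)))
}

#' Synthetic piecewise-linear exposure-response function
#'
#' A V-shaped ("U-shaped" in the limit of shallow slopes) relative-risk curve
#' with a known minimum mortality temperature:
#' `RR(T) = 1 + heat_slope * max(0, T - mmt) + cold_slope * max(0, mmt - T)`,
#' tabulated at `n_knots` equally spaced temperatures over `t_range`. The
#' vertex `mmt` is inserted as a knot if it does not fall on the grid, so the
#' tabulated curve reproduces the closed form exactly at every temperature.
#'
#' @param mmt Minimum mortality temperature, degC, inside `t_range`.
#' @param cold_slope,heat_slope RR change per degC on each arm (>= 0).
#' @param t_range Length-2 temperature range, degC.
#' @param n_knots Number of equally spaced knots.
#' @return An [erf()] object.
#' @export
make_synthetic_erf <- function(mmt, cold_slope = 0.03, heat_slope = 0.05,
                               t_range = c(-10, 35), n_knots = 46L) {
  if (mmt < t_range[1L] || mmt > t_range[2L])
    stop("invalid config: `mmt` outside `t_range`", call. = FALSE)
  if (cold_slope < 0 || heat_slope < 0)
    stop("invalid config: slopes must be >= 0", call. = FALSE)
  temps <- sort(unique(c(seq(t_range[1L], t_range[2L],
                             length.out = n_knots), mmt)))
  rr <- 1 + heat_slope * pmax(0, temps - mmt) +
    cold_slope * pmax(0, mmt - temps)
  erf(data.frame(temperature_C = temps, rr = rr), mmp = NA_real_,
      age_group = "45-65")
}

#' Rebuild a config from its serialized (list) form
#'
#' Inverse of storing `unclass(config)` in JSON/YAML metadata: revalidates and
#' returns a proper config object, preserving every stored field.
#'
#' @param x Named list of config fields.
#' @return A [synthetic_city_config()].
#' @export
as_synthetic_city_config <- function(x) {
  keep <- intersect(names(x), names(formals(synthetic_city_config)))
  cfg <- do.call(synthetic_city_config, x[keep])
  cfg
}

#' Configurations for a synthetic city ensemble
#'
#' Builds `n` configs spanning a range of city sizes (log-spaced central
#' densities) with a fixed external origin layout, cycling through the four
#' mobility quadrants via the signs of the seasonal population amplitude
#' (winter- vs summer-peaked) and of the gravity constant (day- vs night-
#' dominant). Per-city seeds are derived from `seed`.
#'
#' @param n Number of cities (>= 3).
#' @param seed Ensemble seed.
#' @param quadrants Character vector recycled over cities, entries in
#'   `c("I", "II", "III", "IV")`.
#' @param P0_range Range of central densities, persons/cell (log-spaced).
#' @param ... Further arguments passed to [synthetic_city_config()].
#' @return List of [synthetic_city_config()] objects.
#' @export
make_ensemble_configs <- function(n = 12L, seed = 1L, quadrants = "I",
                                  P0_range = c(50, 5e4), ...) {
  stopifnot(n >= 3L)
  quadrants <- rep_len(quadrants, n)
  P0s <- 10^seq(log10(P0_range[1L]), log10(P0_range[2L]), length.out = n)
  lapply(seq_len(n), function(i) {
    cfg <- synthetic_city_config(seed = seed * 1000L + i, P0 = P0s[i], ...)
    sgn_season <- if (quadrants[i] %in% c("I", "II")) 1 else -1
    sgn_day <- if (quadrants[i] %in% c("I", "IV")) 1 else -1
    cfg$pop_A <- sgn_season * abs(cfg$pop_A)
    cfg$gravity_g <- sgn_day * abs(cfg$gravity_g)
    cfg
  })
}
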