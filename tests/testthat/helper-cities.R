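# Shared fixtures, all built in code.

# Small, fast synthetic config for unit tests (one year, 31x31 km).
test_config <- function(seed = 7L, grid_size = 31L, years = 2010L, ...) {
  synthetic_city_config(seed = seed, grid_size = grid_size, years = years,
                        ...)
}

# Hand-built 2x2 city used as the exposure oracle: July temperatures
# [20, 25, 30, 35] degC (column-major), uniform nighttime population of 100
# per cell, daytime frame [50, 100, 150, 100]. January runs 10 degC colder.
toy_stack <- function() {
  t_july <- matrix(c(20, 25, 30, 35), 2, 2)
  t_jan <- t_july - 10
  night <- matrix(100, 2, 2)
  day <- matrix(c(50, 100, 150, 100), 2, 2)
  dates <- c(seq(as.Date("2010-01-01"), as.Date("2010-01-31"), by = "day"),
             seq(as.Date("2010-07-01"), as.Date("2010-07-31"), by = "day"))
  temp <- array(NA_real_, dim = c(length(dates), 2, 2))
  for (i in seq_along(dates)) {
    temp[i, , ] <- if (format(dates[i], "%m") == "07") t_july else t_jan
  }
  city_stack("toy", land_mask = matrix(TRUE, 2, 2),
             pop_day = rep(list(day), 12), pop_night = rep(list(night), 12),
             temp = temp, dates = dates)
}

# A stack with a prescribed vector of daily domain-mean temperatures on
# given dates (spatially uniform fields), for extreme-day composite tests.
ramp_stack <- function(daily_means, dates) {
  n <- length(daily_means)
  stopifnot(length(dates) == n)
  temp <- array(rep(daily_means, 4), dim = c(n, 2, 2))
  frame <- matrix(1, 2, 2)
  city_stack("ramp", matrix(TRUE, 2, 2), rep(list(frame), 12),
             rep(list(frame), 12), temp, dates)
}
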