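test_that("exposure counts honour strict MMT inequalities", {
  T4 <- matrix(c(20, 25, 30, 35), 2, 2)
  pop <- matrix(100, 2, 2)
  expect_equal(exposure_count(pop, T4, 10, "heat"), 400)
  expect_equal(exposure_count(pop, T4, 40, "heat"), 0)
  expect_equal(exposure_count(pop, T4, 28, "heat"), 200)
  expect_equal(exposure_count(pop, T4, 28, "cold"), 200)
  # ties at the threshold count in neither side
  expect_equal(exposure_count(pop, T4, 25, "heat"), 200)
  expect_equal(exposure_count(pop, T4, 25, "cold"), 100)
  expect_error(exposure_count(pop, matrix(1, 3, 3), 20, "heat"),
               "misaligned")
})

test_that("heat, cold, and at-threshold populations partition the total", {
  set.seed(14)
  for (i in 1:20) {
    T9 <- matrix(sample(seq(15, 30, by = 2.5), 9, replace = TRUE), 3, 3)
    pop <- matrix(runif(9, 0, 500), 3, 3)
    mmt <- sample(seq(15, 30, by = 2.5), 1)
    total <- exposure_count(pop, T9, mmt, "heat") +
      exposure_count(pop, T9, mmt, "cold") +
      sum(pop[T9 == mmt])
    expect_equal(total, sum(pop), tolerance = 1e-9)
  }
})

test_that("daily mobility exposure delta matches the 2x2 oracle", {
  st <- toy_stack()
  e <- make_synthetic_erf(mmt = 28, t_range = c(0, 40))
  scen <- monthly_mean_scenario(st, 7)
  d <- mobility_exposure_delta(st, e, "daily", scen, "heat")
  expect_equal(d$exposure_static, 200)
  expect_equal(d$exposure_dynamic, 250)
  expect_equal(d$delta, 50)
  expect_equal(d$delta_pct, 12.5)   # denominator: July night total of 400

  # day = night frames: no delta under any scenario
  st0 <- st
  st0$pop_day <- st0$pop_night
  d0 <- mobility_exposure_delta(st0, e, "daily", scen, "heat")
  expect_equal(d0$delta, 0)

  # identical July and January nighttime frames: no seasonal delta
  ds <- mobility_exposure_delta(st, e, "seasonal", scen, "heat")
  expect_equal(ds$delta, 0)

  # swapping static and dynamic frames negates the delta
  stsw <- st
  stsw$pop_day <- st$pop_night
  stsw$pop_night <- st$pop_day
  dsw <- mobility_exposure_delta(stsw, e, "daily", scen, "heat")
  expect_equal(dsw$delta, -d$delta)
})

test_that("seasonal exposure compares July vs January nights in July heat", {
  st <- toy_stack()
  st$pop_night[[1]] <- matrix(c(100, 100, 50, 50), 2, 2)
  e <- make_synthetic_erf(mmt = 28, t_range = c(0, 40))
  scen <- monthly_mean_scenario(st, 7)
  d <- mobility_exposure_delta(st, e, "seasonal", scen, "heat")
  expect_equal(d$exposure_static, 100)    # January night above 28 degC
  expect_equal(d$exposure_dynamic, 200)   # July night above 28 degC
  expect_equal(d$delta, 100)
  expect_equal(d$delta_pct, 100 * 100 / 400)  # July night total for heat

  dc <- mobility_exposure_delta(st, e, "daily",
                                monthly_mean_scenario(st, 1), "cold")
  expect_equal(dc$delta_pct, 100 * dc$delta / 300)  # January night total
})

test_that("population-weighted temperature uses only incoming cells", {
  T4 <- matrix(c(30, 26, 10, 10), 2, 2)
  dP <- matrix(c(100, 300, 0, -50), 2, 2)
  expect_equal(population_weighted_temperature(dP, T4), 27)

  single <- matrix(c(0, 0, 0, 7), 2, 2)
  expect_equal(population_weighted_temperature(single,
                                               matrix(30, 2, 2)), 30)

  # cells with non-positive change never move the answer
  dP2 <- dP
  dP2[2, 2] <- -999   # extreme outflow at a 10-degC cell
  expect_equal(population_weighted_temperature(dP2, T4), 27)

  expect_error(population_weighted_temperature(matrix(-1, 2, 2), T4),
               "no incoming population")
})

test_that("cumulative incoming fractions accumulate cold to warm", {
  T4 <- matrix(c(19, 21, 15, 15), 2, 2)
  dP <- matrix(c(100, 300, 0, -10), 2, 2)
  cc <- cumulative_incoming_fraction(dP, T4, 20)
  expect_equal(cc$fraction_above_mean, 75)     # 300 of 400 above the mean
  expect_equal(cc$cum_fraction, c(0.25, 1))
  expect_true(all(diff(cc$cum_fraction) >= 0))
  expect_equal(cc$cum_fraction[length(cc$cum_fraction)], 1)

  warm <- cumulative_incoming_fraction(matrix(c(5, 5, 5, 5), 2, 2),
                                       matrix(25, 2, 2), 20)
  expect_equal(warm$fraction_above_mean, 100)
})

test_that("synthetic commuting concentrates influx above the city mean", {
  cfg <- test_config(seed = 19)
  st <- make_city_stack(cfg)
  scen <- monthly_mean_scenario(st, 7)
  t_bar <- domain_mean_temperature(st, scen)
  dd <- delta_p_daily(st, 7)
  cc <- cumulative_incoming_fraction(dd$field, scen$field, t_bar)
  expect_gt(cc$fraction_above_mean, 50)
  tw <- population_weighted_temperature(dd$field, scen$field)
  expect_gt(tw, t_bar)
})
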