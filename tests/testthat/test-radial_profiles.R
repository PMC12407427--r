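test_that("rescaling follows the cube-root population rule", {
  id <- rescale_params(5e6, 5e6)
  expect_equal(id$k, 1)
  out <- rescale(c(2, 10), c(100, 400), id)
  expect_equal(out$r, c(2, 10))
  expect_equal(out$P, c(100, 400))

  half <- rescale_params(5e6 / 8, 5e6)
  expect_equal(half$k, 0.5)
  out2 <- rescale(4, 100, half)
  expect_equal(out2$r, 8)     # smaller city stretched outward
  expect_equal(out2$P, 200)

  big <- rescale_params(27 * 2e5, 2e5)
  expect_equal(big$k, 3)
  expect_equal(rescale(9, 1, big)$r, 3)

  expect_error(rescale_params(-1, 10), "positive")
})

# all-land stack with prescribed per-cell population and temperature
profile_stack <- function(pop, temp) {
  dm <- dim(pop)
  city_stack("prof", matrix(TRUE, dm[1], dm[2]),
             rep(list(pop), 12), rep(list(pop), 12),
             array(as.vector(temp), c(1, dm)), as.Date("2010-07-01"))
}

test_that("annular means reflect exactly the cells in each bin", {
  # 9x9 grid, k = 1: cells at distance [2, 2.5) from the centre are the four
  # axial offsets at r = 2 and the eight knight-ish offsets at r = sqrt(5)
  pop <- matrix(0, 9, 9)
  for (i in 1:9) {
    for (j in 1:9) {
      r <- sqrt((i - 5)^2 + (j - 5)^2)
      if (r >= 2 && r < 2.5) pop[i, j] <- 100
    }
  }
  expect_equal(sum(pop > 0), 12L)
  st <- profile_stack(pop, matrix(20, 9, 9))
  prof <- build_radial_profile(pop, matrix(20, 9, 9), st,
                               rescale_params(1, 1))
  b22 <- prof[prof$bin_lo == 2, ]
  expect_equal(b22$n_cells, 12L)
  expect_equal(b22$mean_pop, 100)
  other <- prof[prof$bin_lo != 2 & prof$n_cells > 0, ]
  expect_true(all(other$mean_pop == 0))
  expect_true(all(is.na(prof$mean_pop[prof$n_cells == 0])))

  # spatially uniform temperature: zero deviation in every occupied annulus
  expect_true(all(prof$mean_dT[prof$n_cells > 0] == 0))

  # doubling the population doubles every bin mean
  prof2 <- build_radial_profile(2 * pop, matrix(20, 9, 9), st,
                                rescale_params(1, 1))
  expect_equal(prof2$mean_pop[prof2$n_cells > 0],
               2 * prof$mean_pop[prof$n_cells > 0])
})

test_that("every land cell between 1 and 30 rescaled km is binned once", {
  cfg <- test_config(seed = 21, grid_size = 21L)
  st <- make_city_stack(cfg)
  params <- rescale_params(2e5, 8e5)   # k < 1 stretches distances
  pop <- st$pop_night[[7]]
  prof <- build_radial_profile(pop, matrix(15, 21, 21), st, params)
  r_resc <- cell_distances(st)[st$land_mask] / params$k
  expect_equal(sum(prof$n_cells), sum(r_resc >= 1 & r_resc < 30))
})

test_that("profiles are invariant to translating the whole city", {
  pop9 <- matrix(runif(81, 10, 100), 9, 9)
  t9 <- matrix(rnorm(81, 20, 1), 9, 9)
  st9 <- profile_stack(pop9, t9)
  base <- build_radial_profile(pop9, t9, st9, rescale_params(1, 1))

  # same 9x9 city embedded off-centre in a 15x15 grid, water elsewhere
  mask <- matrix(FALSE, 15, 15)
  mask[4:12, 5:13] <- TRUE
  pop15 <- matrix(0, 15, 15); pop15[4:12, 5:13] <- pop9
  t15 <- matrix(0, 15, 15); t15[4:12, 5:13] <- t9
  st15 <- city_stack("moved", mask, rep(list(pop15), 12),
                     rep(list(pop15), 12),
                     array(as.vector(t15), c(1, 15, 15)),
                     as.Date("2010-07-01"))
  moved <- build_radial_profile(mask_field(pop15, mask),
                                mask_field(t15, mask), st15,
                                rescale_params(1, 1))
  expect_equal(moved$n_cells, base$n_cells)
  expect_equal(moved$mean_pop, base$mean_pop, tolerance = 1e-12)
  expect_equal(moved$mean_dT, base$mean_dT, tolerance = 1e-12)
})

test_that("scaled-copy cities collapse onto identical rescaled profiles", {
  # a copy scaled by s: linear dimensions x s (cell size), populations x s^3,
  # and the external origin layout scaled along (distances x s, origin
  # populations x s^gamma keep the inflow fraction identical)
  s <- 2
  r0 <- 1.5 * 31 / 2
  cfg1 <- test_config(seed = 77, grid_size = 31L, P0 = 5000, r_p = 5,
                      uhi_amplitude = 3, r_T = 6, noise_sd = 0,
                      origin_pop = 5e4, ring_radius_km = r0)
  cfg2 <- test_config(seed = 77, grid_size = 31L, cell_km = s,
                      P0 = s^3 * 5000, r_p = s * 5,
                      uhi_amplitude = 3, r_T = s * 6, noise_sd = 0,
                      origin_pop = s^2 * 5e4, ring_radius_km = s * r0)
  st1 <- make_city_stack(cfg1)
  st2 <- make_city_stack(cfg2)
  p_ref <- land_total(st1$pop_day[[4]], st1$land_mask)
  pr1 <- rescale_params(land_total(st1$pop_day[[4]], st1$land_mask), p_ref)
  pr2 <- rescale_params(land_total(st2$pop_day[[4]], st2$land_mask), p_ref)
  expect_equal(pr2$k, s * pr1$k, tolerance = 1e-12)

  t1 <- monthly_mean_scenario(st1, 7)$field
  t2 <- monthly_mean_scenario(st2, 7)$field
  prof1 <- build_radial_profile(st1$pop_night[[7]], t1, st1, pr1)
  prof2 <- build_radial_profile(st2$pop_night[[7]], t2, st2, pr2)
  occ <- prof1$n_cells > 0
  expect_equal(prof2$n_cells, prof1$n_cells)
  rel <- abs(prof2$mean_pop[occ] - prof1$mean_pop[occ]) /
    abs(prof1$mean_pop[occ])
  expect_lt(max(rel), 1e-6)
  expect_equal(prof2$mean_dT[occ], prof1$mean_dT[occ], tolerance = 1e-9)
})

test_that("exponential fits recover generative parameters", {
  dT <- seq(-0.5, 2, by = 0.25)
  prof <- data.frame(bin_lo = seq_along(dT), bin_hi = seq_along(dT) + 1,
                     n_cells = 5L, mean_pop = 2 * exp(1.5 * dT),
                     mean_dT = dT)
  class(prof) <- c("radial_profile", "data.frame")
  fit <- fit_exponential(prof)
  expect_equal(fit$a, 2, tolerance = 1e-6)
  expect_equal(fit$lam, 1.5, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  flat <- prof
  flat$mean_pop <- rep(4, nrow(flat))
  ffit <- fit_exponential(flat)
  expect_equal(ffit$lam, 0, tolerance = 1e-8)

  # lambda sign follows the pop-temperature monotonicity
  dec <- prof
  dec$mean_pop <- 3 * exp(-0.8 * dT)
  expect_lt(fit_exponential(dec)$lam, 0)

  small <- prof[1:3, ]
  expect_error(fit_exponential(small), "insufficient data")
})
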