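test_that("block-mean regridding matches hand-computed aggregates", {
  expect_equal(regrid_block_mean(matrix(5, 10, 10), 10),
               matrix(5, 1, 1))
  expect_equal(regrid_block_mean(matrix(c(1, 3, 2, 4), 2, 2), 2),
               matrix(2.5, 1, 1))
  # missing cells drop out of the mean rather than polluting it
  expect_equal(regrid_block_mean(matrix(c(1, 3, NA, NA), 2, 2), 2),
               matrix(2, 1, 1))
  # all-missing block stays missing
  expect_true(is.na(regrid_block_mean(matrix(NA_real_, 2, 2), 2)[1, 1]))
})

test_that("regridding pads non-divisible rasters with missing cells", {
  m <- matrix(1:9, 3, 3) + 0
  out <- regrid_block_mean(m, 2)
  expect_equal(dim(out), c(2L, 2L))
  expect_equal(out[1, 1], mean(m[1:2, 1:2]))
  expect_equal(out[2, 2], m[3, 3])   # lone corner cell survives padding
})

test_that("regridding rejects bad arguments", {
  expect_error(regrid_block_mean(matrix(1, 2, 2), 0), "invalid argument")
  expect_error(regrid_block_mean(matrix(1, 2, 2), 1.5), "invalid argument")
  expect_error(regrid_block_mean(matrix(numeric(0), 0, 0), 2),
               "invalid input")
})

test_that("block means conserve the domain mean on complete rasters", {
  set.seed(11)
  for (f in c(2L, 5L)) {
    m <- matrix(rnorm(100 * f * f), 10 * f, 10 * f)
    expect_equal(mean(regrid_block_mean(m, f)), mean(m), tolerance = 1e-9)
  }
})

test_that("mask regridding follows the majority rule with ties to water", {
  fine <- matrix(c(TRUE, TRUE, TRUE, FALSE,     # 3/4 land -> land
                   TRUE, TRUE, FALSE, FALSE,    # 2/4 land -> water (tie)
                   TRUE, FALSE, FALSE, FALSE,   # 1/4 land -> water
                   FALSE, FALSE, FALSE, FALSE), # water
                 4, 4)
  coarse <- regrid_mask(fine, 2)
  expect_equal(as.vector(coarse), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("domain mean respects the land mask", {
  field <- matrix(c(18, 22, 99, 99), 2, 2)
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  st <- city_stack("m", mask, rep(list(matrix(1, 2, 2)), 12),
                   rep(list(matrix(1, 2, 2)), 12),
                   array(rep(as.vector(field), each = 1), c(1, 2, 2)),
                   as.Date("2010-07-01"))
  scen <- monthly_mean_scenario(st, 7)
  expect_equal(domain_mean_temperature(st, scen), 20)

  uni <- ramp_stack(20, as.Date("2010-07-01"))
  expect_equal(domain_mean_temperature(uni, monthly_mean_scenario(uni, 7)),
               20)

  nine <- city_stack("n", matrix(TRUE, 3, 3),
                     rep(list(matrix(1, 3, 3)), 12),
                     rep(list(matrix(1, 3, 3)), 12),
                     array(as.numeric(1:9), c(1, 3, 3)),
                     as.Date("2010-07-01"))
  expect_equal(domain_mean_temperature(nine, monthly_mean_scenario(nine, 7)),
               5)
})

test_that("extreme-day composites select ceil(fraction * n) ranked days", {
  # 100 July days (four pooled years): ceil(3.0) = 3, hottest are 98, 99, 100
  july4 <- as.Date(unlist(lapply(2010:2013, function(y)
    as.character(seq(as.Date(sprintf("%d-07-01", y)),
                     as.Date(sprintf("%d-07-31", y)), by = "day")))))
  dates100 <- july4[1:100]
  st <- ramp_stack(as.numeric(1:100), dates100)
  scen <- extreme_day_composite(st, 7, "hot", 0.03)
  expect_equal(scen$n_days, 3L)
  expect_equal(scen$field[1, 1], mean(c(98, 99, 100)))

  # 93 July days over three years -> ceil(2.79) = 3 days
  d3 <- as.Date(unlist(lapply(2010:2012, function(y)
    as.character(seq(as.Date(sprintf("%d-07-01", y)),
                     as.Date(sprintf("%d-07-31", y)), by = "day")))))
  st3 <- ramp_stack(as.numeric(seq_along(d3)), d3)
  scen3 <- extreme_day_composite(st3, 7, "hot", 0.03)
  expect_equal(scen3$n_days, 3L)
  expect_equal(scen3$field[2, 2], mean(c(91, 92, 93)))

  cold3 <- extreme_day_composite(st3, 7, "cold", 0.03)
  expect_equal(cold3$field[1, 1], mean(c(1, 2, 3)))

  # constant record: composite equals the constant for either side
  stc <- ramp_stack(rep(12, 31), seq(as.Date("2010-07-01"), by = "day",
                                     length.out = 31))
  expect_equal(extreme_day_composite(stc, 7, "hot")$field[1, 1], 12)
  expect_equal(extreme_day_composite(stc, 7, "cold")$field[1, 1], 12)

  # composite over all days reduces to the monthly mean exactly
  full <- extreme_day_composite(st3, 7, "hot", 1)
  expect_equal(full$field, monthly_mean_scenario(st3, 7)$field)

  expect_error(extreme_day_composite(st3, 2, "hot"), "absent")
})

test_that("land masking is idempotent", {
  mask <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  f <- matrix(1:4 + 0, 2, 2)
  once <- mask_field(f, mask)
  expect_identical(mask_field(once, mask), once)
})

test_that("ASCII grid rasters and city stacks round-trip exactly", {
  dir <- withr::local_tempdir()
  f <- matrix(c(1.25, NA, pi, -3.5e3), 2, 2)
  p <- file.path(dir, "t.asc")
  write_asc(f, p, cell_km = 1)
  back <- read_asc(p)
  expect_equal(back$field, f, tolerance = 1e-15)
  expect_equal(back$cell_km, 1)

  cfg <- test_config(seed = 3, grid_size = 7L)
  st <- make_city_stack(cfg)
  sdir <- file.path(dir, "stack")
  write_city_stack(st, sdir)
  st2 <- read_city_stack(sdir)
  expect_equal(st2$land_mask, st$land_mask)
  expect_equal(st2$pop_night, st$pop_night, tolerance = 1e-12)
  expect_equal(st2$pop_day, st$pop_day, tolerance = 1e-12)
  expect_equal(st2$temp, st$temp, tolerance = 1e-12)
  expect_equal(st2$dates, st$dates)
  expect_equal(st2$center, st$center)
})

test_that("reading flags misaligned rasters by name", {
  dir <- withr::local_tempdir()
  st <- make_city_stack(test_config(seed = 4, grid_size = 5L))
  write_city_stack(st, dir)
  bad <- file.path(dir, "pop", sprintf("%s_03_day.asc", st$city_id))
  write_asc(matrix(1, 3, 3), bad)
  expect_error(read_city_stack(dir), "03_day")
})

test_that("Kelvin-looking temperatures are converted to Celsius", {
  dir <- withr::local_tempdir()
  st <- make_city_stack(test_config(seed = 5, grid_size = 5L))
  st_k <- st
  st_k$temp <- st$temp + 273.15
  write_city_stack(st_k, dir)
  back <- read_city_stack(dir)
  expect_equal(back$temp, st$temp, tolerance = 1e-10)
})
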