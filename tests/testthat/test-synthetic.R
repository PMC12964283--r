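test_that("identity exponent with unit intercept makes supply equal population", {
  cfg <- synthetic_config(n_cities = 5, years = 2000:2002,
                          exponents_by_year = rep(1, 3), intercept = 1,
                          noise_sd = 0, seed = 4)
  pan <- generate_vertical_panel(cfg)
  expect_equal(total_supply(pan), pan$prp, tolerance = 1e-12)
})

test_that("identical config and seed reproduce identical panels", {
  cfg <- synthetic_config(exponents_by_year = seq(0.7, 1.1, length.out = 23),
                          noise_sd = 0.1, seed = 7)
  expect_identical(generate_vertical_panel(cfg), generate_vertical_panel(cfg))
  cfg2 <- synthetic_config(exponents_by_city = runif(41, 0.5, 1.5),
                           noise_sd = 0.1, seed = 7)
  expect_identical(generate_horizontal_panel(cfg2),
                   generate_horizontal_panel(cfg2))
})

test_that("noise-free panels satisfy the generating power law on the log scale", {
  b <- c(0.6, 0.9, 1.3)
  cfg <- synthetic_config(n_cities = 12, years = 2000:2002,
                          exponents_by_year = b, intercept = 0.5,
                          noise_sd = 0, seed = 9)
  pan <- generate_vertical_panel(cfg)
  for (i in seq_along(b)) {
    sub <- pan[pan$year == 2000 + i - 1, ]
    resid <- log(total_supply(sub)) - (log(0.5) + b[i] * log(sub$prp))
    expect_lt(max(abs(resid)), 1e-9)
  }
})

test_that("indicator split conserves totals at the configured shares", {
  shares <- c(institutions = 0.2, beds = 0.5, doctors = 0.3)
  cfg <- synthetic_config(n_cities = 6, years = 2000:2004,
                          exponents_by_year = rep(0.9, 5),
                          indicator_shares = shares, noise_sd = 0.2, seed = 3)
  pan <- generate_vertical_panel(cfg)
  tot <- total_supply(pan)
  expect_equal(pan$institutions / tot, rep(0.2, nrow(pan)), tolerance = 1e-12)
  expect_equal(pan$beds / tot, rep(0.5, nrow(pan)), tolerance = 1e-12)
})

test_that("zero per-city exponent yields a constant resource series", {
  cfg <- synthetic_config(n_cities = 3, years = 2000:2010,
                          exponents_by_city = c(0, 1, 2), noise_sd = 0,
                          seed = 5)
  pan <- generate_horizontal_panel(cfg)
  s <- total_supply(pan[pan$city_id == "C01", ])
  expect_equal(diff(range(s)), 0, tolerance = 1e-12)
})

test_that("config validation rejects degenerate inputs", {
  expect_error(synthetic_config(n_cities = 2,
                                exponents_by_year = rep(1, 23)),
               "n_cities")
  expect_error(synthetic_config(exponents_by_year = rep(1, 23),
                                exponents_by_city = rep(1, 41)),
               "exactly one")
  expect_error(synthetic_config(), "exactly one")
  expect_error(synthetic_config(exponents_by_year = rep(1, 23),
                                indicator_shares = c(0.5, 0.5, 0.5)),
               "indicator_shares")
  expect_error(synthetic_config(exponents_by_year = rep(1, 23),
                                noise_sd = -1), "noise_sd")
  expect_error(synthetic_config(exponents_by_year = c(1, 2)),
               "one exponent per year")
})

test_that("slope recovery from noisy trending series hits +/-0.15 in >=95% of replicates", {
  # b = 2, log-noise 0.05, 23 years; sustained-growth trajectories identify
  # the slope (frozen against an independent lm oracle: 195/200)
  ps <- population_spec(growth_mean = 0.025, growth_sd = 0.005)
  hits <- 0L
  for (s in 1:200) {
    cfg <- synthetic_config(n_cities = 3, exponents_by_city = rep(2, 3),
                            noise_sd = 0.05, population = ps, seed = s)
    sub <- generate_horizontal_panel(cfg)
    sub <- sub[sub$city_id == "C01", ]
    if (abs(ols_slope(sub$prp, total_supply(sub)) - 2) <= 0.15)
      hits <- hits + 1L
  }
  expect_gte(hits, 190L)
})

test_that("driver generator returns monotone ground-truth exponents and rejects unknown drivers", {
  expect_error(driver_spec(active = c(not_a_driver = 1)), "unknown driver")
  cfg <- synthetic_config(
    drivers = driver_spec(active = c(pc_gdp = 0.5), baseline = 0.7,
                          noise_sd = 0),
    noise_sd = 0, seed = 21)
  dp <- generate_driver_panel(cfg)
  ord <- order(dp$truth$pc_gdp)
  expect_true(all(diff(dp$truth$b_true[ord]) >= 0))
  # null model: constant true exponents
  cfg0 <- synthetic_config(drivers = no_active_drivers(noise_sd = 0),
                           noise_sd = 0, seed = 22)
  dp0 <- generate_driver_panel(cfg0)
  expect_equal(diff(range(dp0$truth$b_true)), 0)
})

test_that("packaged reference exponent schedule has the printed endpoints", {
  fx <- yrd_annual_exponents()
  expect_equal(nrow(fx), 23)
  expect_identical(fx$year, 2000:2022)
  expect_equal(fx$scale_index[fx$year == 2000], 0.7773)
  expect_identical(fx$classification[fx$year == 2000],
                   "Negative allometric level 1")
  expect_equal(fx$scale_index[fx$year == 2022], 1.0319)
  expect_identical(fx$classification[fx$year == 2022],
                   "Positive allometric level 2")
})
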