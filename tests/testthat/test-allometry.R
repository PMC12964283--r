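test_that("identity power law gives b = 1, ln_a = 0, r2 = 1", {
  f <- fit_allometry(exp(1:3), exp(1:3))
  expect_equal(f$exponent_b, 1, tolerance = 1e-12)
  expect_equal(f$ln_a, 0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
})

test_that("collinear log points match the hand OLS solution", {
  f <- fit_allometry(c(10, 100, 1000), c(2, 8, 32))
  expect_equal(f$exponent_b, log(4) / log(10), tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
})

test_that("degenerate regressions are rejected with informative errors", {
  expect_error(fit_allometry(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_allometry(c(1, 2, -3), c(1, 2, 3)), "record")
  expect_error(fit_allometry(c(1, 2, 3), c(1, 0, 3)), "record")
  expect_error(fit_allometry(c(5, 5, 5), c(1, 2, 3)), "zero variance")
})

test_that("rescaling populations shifts ln_a but not b or r2", {
  set.seed(31)
  p <- exp(rnorm(20, 14, 0.5)); m <- 0.3 * p^0.9 * exp(rnorm(20, 0, 0.1))
  f1 <- fit_allometry(p, m); f2 <- fit_allometry(1000 * p, m)
  expect_equal(f1$exponent_b, f2$exponent_b, tolerance = 1e-9)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-9)
  expect_equal(f2$ln_a, f1$ln_a - f1$exponent_b * log(1000), tolerance = 1e-6)
})

test_that("swapping regressor and response on noise-free data inverts the exponent", {
  p <- exp(seq(13, 16, length.out = 10)); m <- 2 * p^0.8
  expect_equal(fit_allometry(m, p)$exponent_b,
               1 / fit_allometry(p, m)$exponent_b, tolerance = 1e-9)
})

test_that("vertical series round-trips generator exponents exactly", {
  b <- c(0.5, 2.0)
  cfg <- synthetic_config(n_cities = 10, years = 2000:2001,
                          exponents_by_year = b, noise_sd = 0, seed = 17)
  v <- vertical_series(generate_vertical_panel(cfg))
  expect_equal(v$exponent_b, b, tolerance = 1e-9)
  expect_equal(v$year, 2000:2001)
  expect_true(all(v$r_squared > 1 - 1e-9))
})

test_that("single-year panel with unit exponent gives a length-1 series", {
  cfg <- synthetic_config(n_cities = 5, years = 2000L,
                          exponents_by_year = 1, noise_sd = 0, seed = 1)
  v <- vertical_series(generate_vertical_panel(cfg))
  expect_equal(nrow(v), 1)
  expect_equal(v$exponent_b, 1, tolerance = 1e-9)
})

test_that("vertical slope estimator is unbiased at noise 0.1, n = 41", {
  est <- vapply(1:200, function(s) {
    cfg <- synthetic_config(years = 2000L, exponents_by_year = 1.2,
                            noise_sd = 0.1, seed = s)
    vertical_series(generate_vertical_panel(cfg))$exponent_b
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 1.2), 3 * mc_se)
  # spread shrinks with more cities
  est_big <- vapply(1:100, function(s) {
    cfg <- synthetic_config(n_cities = 164, years = 2000L,
                            exponents_by_year = 1.2, noise_sd = 0.1, seed = s)
    vertical_series(generate_vertical_panel(cfg))$exponent_b
  }, numeric(1))
  expect_lt(sd(est_big), sd(est))
})

test_that("horizontal fits recover per-city exponents exactly and report exclusions", {
  b <- c(-0.3, 0.4, 1.1, 2.5)
  cfg <- synthetic_config(n_cities = 4, years = 2000:2009,
                          exponents_by_city = b, noise_sd = 0, seed = 23)
  pan <- generate_horizontal_panel(cfg)
  h <- horizontal_fits(pan)
  expect_equal(h$fits$exponent_b, b, tolerance = 1e-9)
  expect_equal(nrow(h$excluded), 0)
  # declining-resource city classifies as NAG level 3 downstream
  expect_identical(classify_exponent(h$fits$exponent_b[1])$label, "NAG3")
  # a constant-population city lands in the exclusion list
  pan2 <- pan
  pan2$prp[pan2$city_id == "C02"] <- 1e6
  h2 <- horizontal_fits(pan2)
  expect_identical(h2$excluded$city_id, "C02")
  expect_match(h2$excluded$reason, "constant population")
  expect_equal(nrow(h2$fits), 3)
})

test_that("stage partition merges contiguous years by coordination stage", {
  fx <- yrd_annual_exponents()
  sp <- stage_partition(data.frame(year = fx$year, exponent_b = fx$scale_index))
  expect_equal(nrow(sp), 3)
  expect_equal(sp$start_year, c(2000, 2004, 2015))
  expect_equal(sp$end_year, c(2003, 2014, 2022))
  expect_identical(sp$stage, c("PRP expansion", "basic coordination",
                               "M&H expansion"))
  # constant series: one range; alternating: no merging across changes
  one <- stage_partition(data.frame(year = 2000:2004,
                                    exponent_b = rep(0.9, 5)))
  expect_identical(one$stage, "basic coordination")
  alt <- stage_partition(data.frame(year = 2000:2002,
                                    exponent_b = c(0.84, 0.86, 0.84)))
  expect_equal(nrow(alt), 3)
})
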