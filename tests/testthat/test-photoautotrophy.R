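test_that("Platt curve matches closed-form values and limits", {
  p <- photo_phys_params(1, 2, 1)
  expect_equal(chl_specific_fixation(1, p), (1 - exp(-2)) * exp(-1),
               tolerance = 1e-12)
  expect_equal(chl_specific_fixation(0, p), 0)
  p_sat <- photo_phys_params(1, 1, 0)
  expect_equal(chl_specific_fixation(1e9, p_sat), 1, tolerance = 1e-6)
  expect_error(chl_specific_fixation(-1, p), "irradiance")
})

test_that("Platt curve is bounded, has the analytic interior maximum, and the small-I slope", {
  p <- photo_phys_params(0.05, 1e-3, 5e-5)
  grid <- seq(0, 2000, by = 0.25)
  v <- chl_specific_fixation(grid, p)
  expect_true(all(v >= 0 & v <= p$ps_chl))
  i_star <- (p$ps_chl / p$alpha_chl) * log((p$alpha_chl + p$beta_chl) / p$beta_chl)
  expect_equal(grid[which.max(v)], i_star, tolerance = 1 / i_star)
  # no photo-inhibition: non-decreasing
  p0 <- photo_phys_params(0.05, 1e-3, 0)
  expect_true(all(diff(chl_specific_fixation(grid, p0)) >= -1e-15))
  # initial slope
  i_small <- 1e-6 * p$ps_chl / p$alpha_chl
  expect_equal(chl_specific_fixation(i_small, p) / i_small, p$alpha_chl,
               tolerance = 1e-3)
})

test_that("diel factors follow solar geometry", {
  d <- diel_irradiance_factors(0, 80, 24)   # equator, near equinox
  expect_equal(sum(d$factors > 0), 12)      # half the steps lit
  expect_equal(d$daylength_hours, 12, tolerance = 0.05)
  expect_equal(d$factors[1], 0)             # midnight dark
  expect_false(d$polar_night)
  expect_true(max(d$factors) <= 1 + 1e-12)
  # solstice ordering at 23 N
  dl_summer <- diel_irradiance_factors(23, 172)$daylength_hours
  dl_winter <- diel_irradiance_factors(23, 355)$daylength_hours
  expect_gt(dl_summer, dl_winter)
  # polar night flagged, not an error
  pn <- diel_irradiance_factors(80, 355)
  expect_true(pn$polar_night)
  expect_true(all(pn$factors == 0))
  expect_error(diel_irradiance_factors(100, 80), "latitude")
})

test_that("daily mean fixation averages the diel cycle correctly", {
  p <- default_photophys()
  d <- default_diel()
  expect_equal(daily_mean_fixation(0, d, 1e-3, p), 0)
  # degenerate diel (factors all 1): equals the instantaneous rate scaled
  const <- d
  const$factors <- rep(1, length(d$factors))
  expect_equal(daily_mean_fixation(100, const, 1e-3, p),
               1e-3 * chl_specific_fixation(100, p) * 86400,
               tolerance = 1e-12)
  # linear in the chlorophyll-to-carbon ratio
  expect_equal(daily_mean_fixation(100, d, 5e-4, p),
               daily_mean_fixation(100, d, 1e-3, p) / 2, tolerance = 1e-12)
  expect_error(daily_mean_fixation(100, d, 0, p), "chl_to_c_ratio")
})

test_that("allocation functions have the photo-acclimation monotonicities", {
  al <- default_alloc()
  # ratio decreasing in irradiance, non-decreasing in growth rate, positive
  expect_gt(chl_to_carbon_ratio(0.3, 10, al), chl_to_carbon_ratio(0.3, 100, al))
  expect_gte(chl_to_carbon_ratio(0.5, 50, al), chl_to_carbon_ratio(0.1, 50, al))
  grid <- expand.grid(mu = seq(0, 1, 0.2), i = c(1, 10, 100, 1000))
  expect_true(all(chl_to_carbon_ratio(grid$mu, grid$i, al) > 0))
  expect_error(chl_to_carbon_ratio(0.3, 0, al), "floor")
  # max growth rate: zero in the dark, monotone, saturating
  expect_equal(max_growth_rate(0, al), 0)
  ii <- c(0, 1, 5, 25, 100, 1e4, 1e8)
  expect_true(all(diff(max_growth_rate(ii, al)) >= 0))
  expect_lt(max_growth_rate(1e8, al), al$mu_hat + 1e-9)
})

test_that("the autotrophic-rate fixed point converges and is well behaved", {
  p <- default_photophys()
  al <- default_alloc()
  d <- default_diel()
  # dark limit: raw rate is -k_r, clamped rate 0
  s0 <- solve_autotrophic_rate(0, d, p, al)
  expect_equal(s0$rate_raw, -al$k_r, tolerance = 1e-5)
  expect_equal(s0$rate, 0)
  # allocation ceiling respected
  s_hi <- solve_autotrophic_rate(600, d, photo_phys_params(0.05, 1e-3, 0), al)
  expect_lte(s_hi$rate, max_growth_rate(600, al) + 1e-9)
  # initial-guess independence across an irradiance grid
  for (i0 in c(2, 20, 80, 300, 600)) {
    a <- solve_autotrophic_rate(i0, d, p, al, init = 0.01)
    b <- solve_autotrophic_rate(i0, d, p, al, init = 1.0)
    expect_lt(abs(a$rate_raw - b$rate_raw), 10 * 1e-6)
  }
  # monotone in noon irradiance without photo-inhibition
  p0 <- photo_phys_params(0.05, 1e-3, 0)
  rates <- vapply(c(1, 5, 20, 80, 200, 600),
                  function(i) solve_autotrophic_rate(i, d, p0, al)$rate,
                  numeric(1))
  expect_true(all(diff(rates) >= -1e-9))
})
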