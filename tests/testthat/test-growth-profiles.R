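test_that("the minimum law picks the most limiting component at every depth", {
  spec <- synthetic_spec()
  env <- make_environment(spec, seed = 3)
  r <- autotrophic_profile(env, default_photophys(), default_alloc(),
                           default_nutrients())
  comp <- cbind(light = r$v_c_auto, N = r$v_n, P = r$v_p, Fe = r$v_fe)
  expect_equal(r$mu_auto, apply(comp, 1, min))
  expect_equal(r$limiter, colnames(comp)[apply(comp, 1, which.min)])
  # dark depth is light-limited at rate zero
  env0 <- environment_profile(c(0, 10), c(0, 0), c(1e-3, 1e-3),
                              c(1e-4, 1e-4))
  r0 <- autotrophic_profile(env0, default_photophys(), default_alloc(),
                            default_nutrients())
  expect_equal(r0$mu_auto, c(0, 0))
  expect_equal(r0$limiter, c("light", "light"))
})

test_that("limiter switches from a nutrient to light at a single crossover", {
  spec <- synthetic_spec()
  env <- make_environment(spec, seed = 3)
  r <- autotrophic_profile(env, default_photophys(), default_alloc(),
                           default_nutrients())
  is_light <- r$limiter == "light"
  expect_false(is_light[1])                 # nutrient-limited at the surface
  expect_true(is_light[length(is_light)])   # light-limited at depth
  expect_equal(sum(diff(is_light) != 0), 1) # exactly one switch
  # crossover depth agrees with a dense-grid oracle
  cross <- r$depth[which(is_light)[1]]
  zf <- seq(0, 200, by = 0.5)
  envf <- environment_profile(
    zf, spec$surface_noon_par * exp(-spec$k_d * zf),
    approx(env$depth, env$din, zf)$y, approx(env$depth, env$po4, zf)$y,
    fe = approx(env$depth, env$fe, zf)$y)
  rf <- autotrophic_profile(envf, default_photophys(), default_alloc(),
                            default_nutrients())
  cross_f <- rf$depth[which(rf$limiter == "light")[1]]
  expect_lt(abs(cross - cross_f), spec$depth_step + 0.5)
})

test_that("heterotrophic inference subtracts, clamps and brackets", {
  r <- fake_result(c(0, 50), mu_auto = c(0.05, 0.4), mu_obs = 0.2)
  r <- infer_heterotrophic_rate(r)
  expect_equal(r$mu_het, c(0.15, 0))
  expect_error(infer_heterotrophic_rate(fake_result(1, 0.1)), "observed")
  # envelope brackets every scenario
  spec <- synthetic_spec()
  env <- make_environment(spec, seed = 3)
  scen <- canonical_scenarios()
  results <- lapply(scen, function(p) {
    autotrophic_profile(env, p, default_alloc(), default_nutrients())
  })
  envp <- scenario_envelope(results)
  for (r in results) {
    expect_true(all(r$mu_auto >= envp$mu_auto_min - 1e-12))
    expect_true(all(r$mu_auto <= envp$mu_auto_max + 1e-12))
  }
})

test_that("vertical integration reproduces hand arithmetic and scale invariance", {
  z <- seq(0, 100, by = 10)
  r <- fake_result(z, mu_auto = 0.5, mu_het = 0, mu_obs = 0.5,
                   cell_density = 1e8)
  p <- integrate_production(r, carbon_quota = 50e-15)
  expect_equal(p$autotrophic_production, 2.5e-4, tolerance = 1e-12)
  expect_equal(p$heterotrophic_fraction, 0)
  # doubling the quota doubles rates, leaves fractions unchanged
  r2 <- fake_result(z, mu_auto = 0.3, mu_het = 0.1, mu_obs = 0.4,
                    cell_density = 1e8)
  a <- integrate_production(r2, carbon_quota = 50e-15)
  b <- integrate_production(r2, carbon_quota = 100e-15)
  expect_equal(b$autotrophic_production, 2 * a$autotrophic_production)
  expect_equal(b$heterotrophic_production, 2 * a$heterotrophic_production)
  expect_equal(b$heterotrophic_fraction, a$heterotrophic_fraction)
  expect_error(integrate_production(r, cell_density = rep(-1, length(z))),
               "negative")
})

test_that("mixotrophy onset depths follow linear-crossing arithmetic", {
  z <- seq(0, 100, by = 1)
  mu_auto <- 0.4 * (1 - z / 100)
  r <- fake_result(z, mu_auto = mu_auto, mu_obs = 0.2)
  r <- infer_heterotrophic_rate(r)
  on <- mixotrophy_onset_depth(r)
  # mu_het first positive where mu_auto drops below 0.2 (50 m); heterotrophy
  # exceeds photosynthesis where mu_auto < 0.1 (75 m)
  expect_equal(on$first_positive_depth, 50, tolerance = 1.01)
  expect_equal(on$onset_depth, 75, tolerance = 1e-6)
  # onset PAR consistent with exponential attenuation
  expect_equal(on$onset_par, 600 * exp(-0.045 * on$onset_depth),
               tolerance = 1e-6)
  # no crossing -> flagged none
  r0 <- fake_result(z, mu_auto = 0.4, mu_het = 0, mu_obs = 0.1)
  expect_equal(mixotrophy_onset_depth(r0)$onset_flag, "none")
})

test_that("observed-growth interpolation is linear and never extrapolates", {
  z <- c(0, 10, 20, 30, 40)
  og <- c(NA, 0.4, NA, 0.2, NA)
  out <- interpolate_observed_growth(z, og)
  expect_equal(out[3], 0.3)          # linear midpoint
  expect_true(is.na(out[1]) && is.na(out[5]))  # no extrapolation
})

test_that("synthetic fixture yields positive heterotrophic production, larger below onset", {
  spec <- synthetic_spec()
  env <- make_environment(spec, seed = 11)
  r <- infer_heterotrophic_rate(
    autotrophic_profile(env, default_photophys(), default_alloc(),
                        default_nutrients()))
  p <- integrate_production(r)
  expect_gt(p$heterotrophic_fraction, 0)
  expect_gt(p$below_onset_heterotrophic_fraction, p$heterotrophic_fraction)
  expect_false(is.na(p$onset$onset_depth))
})
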