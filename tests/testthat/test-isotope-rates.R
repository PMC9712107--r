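test_that("specific uptake rate implements linear isotope dilution", {
  expect_equal(as.numeric(specific_uptake_rate(0.011, 0.011, 0.05, 1)), 0)
  # 1% of the labelling distance in one day
  expect_equal(as.numeric(specific_uptake_rate(0.011 + 0.01 * (0.05 - 0.011),
                                               0.011, 0.05, 1)), 0.01)
  # halving the duration doubles the rate
  r1 <- as.numeric(specific_uptake_rate(0.02, 0.011, 0.05, 1))
  r2 <- as.numeric(specific_uptake_rate(0.02, 0.011, 0.05, 0.5))
  expect_equal(r2, 2 * r1)
  # sub-natural measurements clamp to zero with a flag
  r <- specific_uptake_rate(0.010, 0.011, 0.05, 1)
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "clamped"))
  expect_error(specific_uptake_rate(0.02, 0.05, 0.05, 1), "source")
  expect_error(specific_uptake_rate(0.02, 0.011, 0.05, 0), "duration")
})

test_that("population summary reproduces the field worked example", {
  # cells constructed so median muC = 0.024 and median muN = 0.16 day^-1
  dur <- 3.5 / 24
  n <- 5
  mu_c <- c(0.020, 0.022, 0.024, 0.026, 0.030)
  mu_n <- c(0.12, 0.15, 0.16, 0.17, 0.20)
  cells <- single_cell_measurements(
    atom_fraction_c = 0.011 + mu_c * dur * (0.05 - 0.011),
    atom_fraction_n = 0.00366 + mu_n * dur * (0.1 - 0.00366),
    incubation_duration = dur)
  s <- uptake_ratio_summary(cells)
  expect_equal(s$median_mu_c, 0.024, tolerance = 1e-10)
  expect_equal(s$median_mu_n, 0.16, tolerance = 1e-10)
  expect_equal(s$ratio_of_medians, 0.15, tolerance = 1e-10)
  expect_equal(s$heterotrophic_fraction, 0.85, tolerance = 1e-10)
  expect_gt(s$heterotrophic_fraction, 0.80)
  expect_equal(s$doubling_time_reciprocal, 6.25, tolerance = 1e-10)
  expect_equal(s$doubling_time_ln2, log(2) / 0.16, tolerance = 1e-10)
})

test_that("the muC/muN ratio is invariant to incubation duration", {
  spec <- synthetic_spec(cell_noise = 0)
  for (dur in c(1 / 24, 3.5 / 24, 1)) {
    sp <- synthetic_spec(cell_noise = 0, incubation_duration = dur)
    s <- uptake_ratio_summary(make_single_cells(sp, 20, seed = 1))
    expect_equal(s$ratio_of_medians, 0.15, tolerance = 1e-10)
  }
})

test_that("medians recover the generator truth within two standard errors", {
  spec <- synthetic_spec(cell_noise = 0.2)
  n <- 50
  reps <- 40
  est_c <- est_n <- numeric(reps)
  for (k in seq_len(reps)) {
    s <- uptake_ratio_summary(make_single_cells(spec, n, seed = 100 + k))
    est_c[k] <- s$median_mu_c
    est_n[k] <- s$median_mu_n
  }
  se_c <- sd(est_c) / 1          # sd across replicates IS the SE of one median
  se_n <- sd(est_n) / 1
  expect_lt(abs(mean(est_c) - spec$mu_c_true), 2 * se_c / sqrt(reps) * sqrt(reps))
  expect_lt(abs(median(est_c) - spec$mu_c_true), 2 * se_c)
  expect_lt(abs(median(est_n) - spec$mu_n_true), 2 * se_n)
})

test_that("invalid cells are flagged and excluded, all-invalid errors", {
  cells <- single_cell_measurements(
    atom_fraction_c = c(0.02, 0.9), atom_fraction_n = c(0.02, 0.9))
  expect_false(cells$flag_c[1])
  expect_true(cells$flag_c[2] && cells$flag_n[2])
  s <- uptake_ratio_summary(cells)
  expect_equal(s$n_cells, 1)
  bad <- single_cell_measurements(atom_fraction_c = 0.9,
                                  atom_fraction_n = 0.9)
  expect_error(uptake_ratio_summary(bad), "no valid cells")
})
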