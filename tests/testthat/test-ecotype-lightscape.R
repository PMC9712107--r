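test_that("photic depth matches the closed form and a numerical root", {
  expect_equal(photic_depth(1000, 0.04, 10), log(100) / 0.04,
               tolerance = 1e-12)
  expect_equal(photic_depth(10, 0.04, 10), 0)
  expect_equal(photic_depth(5, 0.04, 10), 0)   # surface below threshold
  # low-light threshold (2.8) lies deeper than high-light (10)
  expect_gt(photic_depth(1000, 0.04, 2.8), photic_depth(1000, 0.04, 10))
  expect_error(photic_depth(1000, 0, 10), "k_d")
  # closed form vs numerical root of the attenuation equation
  for (case in list(c(600, 0.045, 10), c(350, 0.04, 2.8), c(900, 0.06, 15))) {
    f <- function(z) case[1] * exp(-case[2] * z) - case[3]
    root <- uniroot(f, c(0, 500), tol = 1e-12)$root
    expect_equal(photic_depth(case[1], case[2], case[3]), root,
                 tolerance = 1e-9)
  }
  # strictly decreasing in threshold and attenuation
  expect_true(all(diff(photic_depth(600, 0.04, c(1, 2, 5, 10, 20))) < 0))
  expect_true(all(diff(photic_depth(600, c(0.02, 0.04, 0.08), 10)) < 0))
})

test_that("stratification mask is MLD shallower than photic depth", {
  expect_equal(stratified_mask(c(40, 200), c(115, 115)), c(TRUE, FALSE))
  expect_error(stratified_mask(1:3, 1:2), "length")
})

test_that("below-photic fractions integrate the column correctly", {
  z <- seq(0, 200, by = 2)
  # uniform profile, photic depth mid-column: 50%
  expect_equal(fraction_below_photic(z, rep(1, length(z)), 100), 50)
  # all cells above the photic depth: 0%
  shallow <- ifelse(z <= 50, 1, 0)
  expect_equal(fraction_below_photic(z, shallow, 100), 0, tolerance = 1e-9)
  # linear profile: analytic two-layer split
  expect_equal(fraction_below_photic(z, z, 100), 75)
  # monotone non-increasing in photic depth
  prof <- exp(-((z - 80) / 40)^2)
  f <- vapply(c(20, 60, 100, 140, 180),
              function(pd) fraction_below_photic(z, prof, pd), numeric(1))
  expect_true(all(diff(f) <= 0))
  expect_true(is.na(fraction_below_photic(z, rep(0, length(z)), 100)))
})

test_that("stratified means use only masked dates", {
  f <- c(10, 10, 50, 10)
  mask <- c(TRUE, TRUE, FALSE, TRUE)
  s <- stratified_mean_fraction(f, mask)
  expect_equal(s$mean, 10)
  expect_equal(s$max, 10)
  # changing non-stratified dates does not change the mean
  f2 <- f; f2[3] <- 99
  expect_equal(stratified_mean_fraction(f2, mask)$mean, 10)
  expect_error(stratified_mean_fraction(f, rep(FALSE, 4)), "stratified")
})

test_that("time-series analysis recovers the generator's ground truth", {
  spec <- synthetic_spec()
  ts <- make_timeseries(spec, seed = 2)
  truth <- attr(ts, "truth")
  out <- analyze_ecotype_timeseries(ts)
  expect_equal(out$per_date$stratified, truth$stratified)
  # winter deep mixing is non-stratified by construction
  expect_false(all(out$per_date$stratified))
  expect_true(any(out$per_date$stratified))
  # trapezoidal fractions match the analytic (error-function) truth
  expect_equal(out$per_date$frac_total, truth$total, tolerance = 5e-3)
  for (e in names(ts$profiles)) {
    expect_equal(out$per_date[[paste0("frac_", e)]], truth[[e]],
                 tolerance = 5e-3)
  }
  # low-light ecotypes with their own (deeper) photic depth have smaller
  # below-photic fractions than under the high-light threshold
  ll <- ts
  ll$thresholds["LLIV"] <- 10
  out_hl <- analyze_ecotype_timeseries(ll)
  expect_true(all(out$per_date$frac_LLIV <= out_hl$per_date$frac_LLIV + 1e-9))
})
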