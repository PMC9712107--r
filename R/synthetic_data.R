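#' Specification of the synthetic ground-truth fixtures
#'
#' Parameters of every synthetic generator: an exponentially attenuated
#' light field, sigmoidal nutriclines, an observed-growth template with a
#' deep plateau, a seasonal mixed-layer cycle with depth-structured ecotype
#' niches, and single-cell isotope truth. All generators are pure functions
#' of `(spec, seed)`; ground truth is stored alongside every output so
#' downstream checks never re-derive it.
#'
#' @param surface_noon_par Surface noon PAR, umol photons m^-2 s^-1.
#' @param k_d Attenuation coefficient, m^-1.
#' @param depth_max,depth_step Environment depth grid, m.
#' @param din_deep,din_surface,din_mid,din_width Deep and surface-floor
#'   DIN (mol N m^-3) and sigmoid nutricline midpoint/steepness (m).
#' @param po4_deep,po4_surface,po4_mid,po4_width Same for phosphate
#'   (mol P m^-3).
#' @param fe_deep,fe_mid,fe_width,fe_detection_limit Same for dissolved
#'   iron (nmol l^-1) plus the detection limit substituted near the
#'   surface.
#' @param mu_obs_surface,mu_obs_deep,mu_obs_transition,mu_obs_width
#'   Observed-growth template, day^-1: surface value, deep plateau
#'   (0.15-0.2 day^-1 persisting to 150 m), transition depth and width.
#' @param mu_obs_noise Multiplicative noise s.d. on observed-growth samples.
#' @param cell_density_surface,cell_density_dcm,dcm_depth,dcm_width Cell
#'   density background and deep-maximum bump, cells m^-3 / m.
#' @param mld_winter,mld_summer Seasonal mixed-layer extremes, m.
#' @param par0_winter,par0_summer Seasonal surface-PAR extremes.
#' @param k_d_timeseries Attenuation coefficient of the time series, m^-1.
#' @param ecotype_centres,ecotype_sigmas,ecotype_amplitudes Named vectors
#'   of Gaussian depth-niche parameters per ecotype (LL niches below HL).
#' @param mu_c_true,mu_n_true Single-cell truth, day^-1.
#' @param cell_noise Log-normal (median-preserving) noise s.d. on
#'   single-cell isotope excess enrichments.
#' @param incubation_duration Incubation length, days.
#' @param latitude,day_of_year Location/date of the environment profile.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(surface_noon_par = 600, k_d = 0.045,
                           depth_max = 200, depth_step = 5,
                           din_deep = 3e-3, din_surface = 2e-5,
                           din_mid = 110, din_width = 14,
                           po4_deep = 2e-4, po4_surface = 5e-5,
                           po4_mid = 100, po4_width = 16,
                           fe_deep = 0.6, fe_mid = 120, fe_width = 18,
                           fe_detection_limit = 0.03,
                           mu_obs_surface = 0.45, mu_obs_deep = 0.17,
                           mu_obs_transition = 70, mu_obs_width = 22,
                           mu_obs_noise = 0.0,
                           cell_density_surface = 1.5e11,
                           cell_density_dcm = 1.2e11,
                           dcm_depth = 95, dcm_width = 45,
                           mld_winter = 220, mld_summer = 30,
                           par0_winter = 350, par0_summer = 650,
                           k_d_timeseries = 0.04,
                           ecotype_centres = c(HLII = 35, HLI = 55, LLI = 90,
                                               LLII_III = 110, LLIV = 135),
                           ecotype_sigmas = c(HLII = 25, HLI = 25, LLI = 22,
                                              LLII_III = 22, LLIV = 22),
                           ecotype_amplitudes = c(HLII = 1e11, HLI = 6e10,
                                                  LLI = 5e10, LLII_III = 3e10,
                                                  LLIV = 2e10),
                           mu_c_true = 0.024, mu_n_true = 0.16,
                           cell_noise = 0.2,
                           incubation_duration = 3.5 / 24,
                           latitude = 22.75, day_of_year = 196) {
  spec <- as.list(environment())
  scalars <- c("surface_noon_par", "k_d", "depth_max", "depth_step",
               "din_deep", "po4_deep", "fe_deep", "fe_detection_limit",
               "mld_winter", "mld_summer", "par0_winter", "par0_summer",
               "k_d_timeseries", "mu_n_true", "incubation_duration")
  for (s in scalars) if (spec[[s]] <= 0) stop("`", s, "` must be > 0")
  structure(spec, class = "synthetic_spec")
}

#' Synthetic environmental depth profile
#'
#' Builds an [environment_profile()] with exponential PAR
#' (`surface * exp(-k_d * z)`), sigmoidal DIN/PO4/Fe nutriclines (the
#' concentration at the nutricline midpoint equals half the deep value),
#' below-detection surface iron replaced by the detection limit, a cell
#' density profile with a deep maximum, and a gappy observed-growth
#' profile from [make_observed_growth()]. Deterministic given the seed.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed for the observed-growth gap placement/noise.
#' @return An `environment_profile` with attribute `growth_truth` (the
#'   noise-free observed-growth template on the full grid).
#' @export
make_environment <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  z <- seq(0, spec$depth_max, by = spec$depth_step)
  par <- spec$surface_noon_par * exp(-spec$k_d * z)
  sig <- function(deep, surf, mid, width) {
    surf + (deep - surf) / (1 + exp(-(z - mid) / width))
  }
  din <- sig(spec$din_deep, spec$din_surface, spec$din_mid, spec$din_width)
  po4 <- sig(spec$po4_deep, spec$po4_surface, spec$po4_mid, spec$po4_width)
  fe <- pmax(sig(spec$fe_deep, 0, spec$fe_mid, spec$fe_width),
             spec$fe_detection_limit)
  dens <- spec$cell_density_surface * exp(-z / 250) +
    spec$cell_density_dcm * exp(-((z - spec$dcm_depth) / spec$dcm_width)^2)
  og <- make_observed_growth(spec, seed = seed)
  mu_obs <- approx(og$depth, og$mu_obs, xout = z, rule = 1)$y
  # keep the generated gaps: only depths actually sampled carry values
  mu_obs[!(z %in% og$depth[!is.na(og$mu_obs)])] <- NA_real_
  env <- environment_profile(z, par, din, po4, fe = fe, cell_density = dens,
                             observed_growth = mu_obs,
                             latitude = spec$latitude,
                             day_of_year = spec$day_of_year)
  attr(env, "growth_truth") <- og$truth_fun(z)
  attr(env, "seed") <- seed
  env
}

#' Synthetic observed-growth profile with gaps
#'
#' Smooth sigmoid template declining from the surface value to a deep
#' plateau of at least 0.1 day^-1 persisting to 150 m, sampled at sparse
#' depths with seed-reproducible gaps (for exercising the linear
#' interpolation of gappy observations) and optional multiplicative noise.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @param sample_depths Depths at which observations exist, m.
#' @param n_gaps Number of interior sample depths turned into `NA` gaps.
#' @return List with `depth`, `mu_obs` (gappy samples), `truth_fun` (the
#'   noise-free template as a function of depth) and `seed`.
#' @export
make_observed_growth <- function(spec, seed = 1L,
                                 sample_depths = seq(0, 180, by = 15),
                                 n_gaps = 3L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  truth_fun <- function(z) {
    spec$mu_obs_deep + (spec$mu_obs_surface - spec$mu_obs_deep) /
      (1 + exp((z - spec$mu_obs_transition) / spec$mu_obs_width))
  }
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    expr
  }
  mu <- truth_fun(sample_depths)
  withr_seed({
    if (spec$mu_obs_noise > 0) {
      mu <- mu * exp(rnorm(length(mu), 0, spec$mu_obs_noise))
    }
    interior <- seq(2, length(sample_depths) - 1L)
    gaps <- sample(interior, min(n_gaps, length(interior)))
    mu[gaps] <- NA_real_
  })
  list(depth = sample_depths, mu_obs = mu, truth_fun = truth_fun, seed = seed)
}

#' Analytic below-photic fraction of a Gaussian depth niche
#'
#' Closed-form (error-function) fraction of a Gaussian cell profile,
#' truncated to the column `[0, depth_max]`, lying below a photic depth.
#' Serves as the independent ground truth for the trapezoidal column
#' integrals.
#'
#' @param centre,sigma Gaussian niche centre and width, m.
#' @param pd Photic depth, m.
#' @param depth_max Column depth, m.
#' @return Percentage in `[0, 100]`.
#' @export
gaussian_fraction_below <- function(centre, sigma, pd, depth_max) {
  total <- pnorm((depth_max - centre) / sigma) - pnorm((0 - centre) / sigma)
  pd <- min(max(pd, 0), depth_max)
  below <- pnorm((depth_max - centre) / sigma) - pnorm((pd - centre) / sigma)
  100 * below / total
}

#' Synthetic seasonal ecotype time series
#'
#' Sinusoidal mixed-layer and surface-PAR seasonal cycles (winter-deep
#' mixing crossing the photic depth), Gaussian ecotype depth niches with
#' low-light niches centred below high-light niches, and analytically
#' computed ground-truth below-photic fractions stored alongside.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed (recorded; the series itself is
#'   deterministic).
#' @param n_years Number of simulated years (monthly sampling).
#' @param depth_step Depth-grid spacing of the profiles, m.
#' @return An [ecotype_timeseries()] with attributes `truth` (list of
#'   per-ecotype and total ground-truth fraction series plus the
#'   stratification mask) and `seed`.
#' @export
make_timeseries <- function(spec, seed = 1L, n_years = 3L, depth_step = 2) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nt <- 12L * n_years
  month <- seq_len(nt)
  phase <- 2 * pi * (month - 2) / 12   # MLD max near February
  mld <- exp((log(spec$mld_winter) + log(spec$mld_summer)) / 2 +
               (log(spec$mld_winter) - log(spec$mld_summer)) / 2 * cos(phase))
  par0 <- (spec$par0_winter + spec$par0_summer) / 2 -
    (spec$par0_summer - spec$par0_winter) / 2 * cos(phase)
  z <- seq(0, spec$depth_max, by = depth_step)
  eco <- names(spec$ecotype_centres)
  profiles <- lapply(eco, function(e) {
    prof <- spec$ecotype_amplitudes[[e]] *
      exp(-((z - spec$ecotype_centres[[e]])^2) /
            (2 * spec$ecotype_sigmas[[e]]^2))
    matrix(rep(prof, nt), nrow = length(z))
  })
  names(profiles) <- eco
  thresholds <- setNames(ifelse(grepl("^HL", eco), 10, 2.8), eco)
  ts <- ecotype_timeseries(month, mld, par0, spec$k_d_timeseries, z,
                           profiles, thresholds)
  pd_total <- photic_depth(par0, spec$k_d_timeseries, 10)
  truth <- list(stratified = stratified_mask(mld, pd_total))
  for (e in eco) {
    pd_e <- photic_depth(par0, spec$k_d_timeseries, thresholds[[e]])
    truth[[e]] <- vapply(pd_e, function(p) {
      gaussian_fraction_below(spec$ecotype_centres[[e]],
                              spec$ecotype_sigmas[[e]], p, spec$depth_max)
    }, numeric(1))
  }
  # total population: amplitude-sigma weighted combination of the niches
  truth$total <- vapply(seq_len(nt), function(i) {
    w <- vapply(eco, function(e) {
      spec$ecotype_amplitudes[[e]] * spec$ecotype_sigmas[[e]] *
        (pnorm((spec$depth_max - spec$ecotype_centres[[e]]) /
                 spec$ecotype_sigmas[[e]]) -
           pnorm(-spec$ecotype_centres[[e]] / spec$ecotype_sigmas[[e]]))
    }, numeric(1))
    f <- vapply(eco, function(e) {
      gaussian_fraction_below(spec$ecotype_centres[[e]],
                              spec$ecotype_sigmas[[e]], pd_total[i],
                              spec$depth_max)
    }, numeric(1))
    sum(w * f) / sum(w)
  }, numeric(1))
  attr(ts, "truth") <- truth
  attr(ts, "seed") <- seed
  ts
}

#' Synthetic single-cell isotope measurements with known truth
#'
#' Inverts the linear-dilution uptake-rate formula: the excess atom
#' fraction of each cell is `mu_true * duration * (source - natural)`,
#' multiplied by median-preserving log-normal noise, then added to the
#' natural abundance. With zero noise, [specific_uptake_rate()] recovers
#' the truth exactly.
#'
#' @param spec A [synthetic_spec()].
#' @param n_cells Number of cells (>= 1).
#' @param seed Integer seed.
#' @return A [single_cell_measurements()] data frame with attributes
#'   `mu_c_true`, `mu_n_true` and `seed`.
#' @export
make_single_cells <- function(spec, n_cells = 50L, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"), n_cells >= 1L)
  natural_c <- 0.011; source_c <- 0.05
  natural_n <- 0.00366; source_n <- 0.1
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  noise_c <- exp(rnorm(n_cells, 0, spec$cell_noise))
  noise_n <- exp(rnorm(n_cells, 0, spec$cell_noise))
  exc_c <- spec$mu_c_true * spec$incubation_duration * (source_c - natural_c) * noise_c
  exc_n <- spec$mu_n_true * spec$incubation_duration * (source_n - natural_n) * noise_n
  cells <- single_cell_measurements(
    atom_fraction_c = natural_c + exc_c,
    atom_fraction_n = natural_n + exc_n,
    natural_c = natural_c, natural_n = natural_n,
    source_c = source_c, source_n = source_n,
    incubation_duration = spec$incubation_duration,
    population = "synthetic")
  attr(cells, "mu_c_true") <- spec$mu_c_true
  attr(cells, "mu_n_true") <- spec$mu_n_true
  attr(cells, "seed") <- seed
  cells
}
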