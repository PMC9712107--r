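#' Photo-physiological parameters of the Platt P-I curve
#'
#' Bundles the three empirically determined coefficients of the Platt
#' photosynthesis-irradiance relationship for one ecotype/acclimation
#' scenario: the chlorophyll-specific maximum fixation rate, the initial
#' slope, and the photo-inhibition coefficient.
#'
#' @param ps_chl Chlorophyll-specific maximum carbon fixation rate,
#'   mol C (mol Chl)^-1 s^-1. Must be positive.
#' @param alpha_chl Initial slope of the P-I curve,
#'   mol C (mol Chl)^-1 s^-1 per (umol photons m^-2 s^-1). Must be positive.
#' @param beta_chl Photo-inhibition coefficient, same units as `alpha_chl`.
#'   `beta_chl = 0` encodes the scenario without photo-inhibition.
#' @param label Free-text ecotype/acclimation tag, e.g. `"HL"` or `"LL"`.
#' @return An object of class `photo_phys_params`.
#' @seealso [chl_specific_fixation()], [solve_autotrophic_rate()]
#' @export
photo_phys_params <- function(ps_chl, alpha_chl, beta_chl = 0, label = "") {
  stopifnot(is.numeric(ps_chl), length(ps_chl) == 1L,
            is.numeric(alpha_chl), length(alpha_chl) == 1L,
            is.numeric(beta_chl), length(beta_chl) == 1L)
  if (ps_chl <= 0) stop("`ps_chl` must be > 0")
  if (alpha_chl <= 0) stop("`alpha_chl` must be > 0")
  if (beta_chl < 0) stop("`beta_chl` must be >= 0")
  structure(list(ps_chl = ps_chl, alpha_chl = alpha_chl,
                 beta_chl = beta_chl, label = label),
            class = "photo_phys_params")
}

#' Chlorophyll-specific carbon fixation rate (Platt curve)
#'
#' Instantaneous chlorophyll-specific fixation as a function of irradiance:
#' `ps_chl * (1 - exp(-alpha_chl * I / ps_chl)) * exp(-beta_chl * I / ps_chl)`.
#' The value is bounded by `[0, ps_chl]`; with `beta_chl > 0` the curve has a
#' single interior maximum at `I* = (ps_chl / beta_chl) * log((alpha_chl +
#' beta_chl) / beta_chl)`.
#'
#' @param irradiance PAR, umol photons m^-2 s^-1 (vectorised, must be >= 0).
#' @param params A [photo_phys_params()] object.
#' @return Fixation rate, mol C (mol Chl)^-1 s^-1, same length as
#'   `irradiance`.
#' @export
chl_specific_fixation <- function(irradiance, params) {
  stopifnot(inherits(params, "photo_phys_params"))
  if (any(irradiance < 0)) stop("`irradiance` must be >= 0")
  with(params,
       ps_chl * (1 - exp(-alpha_chl * irradiance / ps_chl)) *
         exp(-beta_chl * irradiance / ps_chl))
}

#' Diel modulation factors for noon-referenced PAR
#'
#' Relative irradiance multipliers over a 24 h cycle, proportional to
#' `max(0, cos(solar zenith angle))` from standard astronomical formulae
#' (solar declination via the Cooper approximation), normalised so the value
#' of the underlying curve at local noon is 1. Factors are sampled at the
#' midpoints of `n_steps_per_day` equal intervals.
#'
#' Polar-night inputs (sun never above the horizon) yield all-zero factors
#' and are flagged via the `polar_night` element rather than an error.
#'
#' @param latitude Degrees, in `[-90, 90]`.
#' @param day_of_year Integer in `[1, 365]`.
#' @param n_steps_per_day Number of equal sub-steps of the 24 h cycle.
#' @return An object of class `diel_irradiance` with elements `factors`
#'   (length `n_steps_per_day`), `hours` (midpoint times), `latitude`,
#'   `day_of_year`, `daylength_hours` and `polar_night`.
#' @export
diel_irradiance_factors <- function(latitude, day_of_year, n_steps_per_day = 24) {
  stopifnot(length(latitude) == 1L, length(day_of_year) == 1L)
  if (abs(latitude) > 90) stop("|latitude| must be <= 90")
  if (day_of_year < 1 || day_of_year > 365) stop("`day_of_year` must be in [1, 365]")
  phi <- latitude * pi / 180
  # Cooper (1969) solar declination
  decl <- (23.44 * pi / 180) * sin(2 * pi * (284 + day_of_year) / 365)
  hours <- (seq_len(n_steps_per_day) - 0.5) * 24 / n_steps_per_day
  hour_angle <- pi * (hours - 12) / 12
  cosz <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(hour_angle)
  cosz_noon <- sin(phi) * sin(decl) + cos(phi) * cos(decl)
  polar_night <- cosz_noon <= 0
  factors <- if (polar_night) rep(0, n_steps_per_day) else pmax(0, cosz) / cosz_noon
  # astronomical daylength from the sunset hour angle
  cos_h0 <- -tan(phi) * tan(decl)
  daylength <- if (cos_h0 <= -1) 24 else if (cos_h0 >= 1) 0 else 24 * acos(cos_h0) / pi
  structure(list(factors = factors, hours = hours, latitude = latitude,
                 day_of_year = day_of_year, daylength_hours = daylength,
                 polar_night = polar_night),
            class = "diel_irradiance")
}

#' Carbon-specific, daily-averaged carbon fixation rate
#'
#' Averages `(qChl/qC) * chl_specific_fixation(noon_irradiance * factor)`
#' over the 24 h diel cycle and converts from s^-1 to day^-1. This is the
#' daily carbon-specific photosynthesis rate (symbol P in the profile
#' model).
#'
#' @param noon_irradiance Noon PAR at the depth of interest (>= 0).
#' @param diel A [diel_irradiance_factors()] object.
#' @param chl_to_c_ratio Molar chlorophyll-to-carbon ratio qChl/qC (> 0).
#' @param params A [photo_phys_params()] object.
#' @return Daily fixation rate, day^-1.
#' @export
daily_mean_fixation <- function(noon_irradiance, diel, chl_to_c_ratio, params) {
  stopifnot(inherits(diel, "diel_irradiance"))
  if (noon_irradiance < 0) stop("`noon_irradiance` must be >= 0")
  if (chl_to_c_ratio <= 0) stop("`chl_to_c_ratio` must be > 0")
  inst <- chl_specific_fixation(noon_irradiance * diel$factors, params)
  chl_to_c_ratio * mean(inst) * 86400
}

#' Macromolecular-allocation parameters (contracted form)
#'
#' Coefficients of the chlorophyll-to-carbon function and of the
#' irradiance-dependent maximum growth rate, in the contracted functional
#' form used by this package:
#' `qChl/qC = (a0 + a1 * mu) / (1 + a2 * I)` and
#' `mu_max(I) = mu_hat * I / (I + k_i)`, plus the fixed maintenance
#' respiration rate `k_r`. The contracted form preserves the photo-
#' acclimation monotonicities of the full macromolecular-allocation model
#' (ratio decreasing in irradiance, non-decreasing in growth rate) and is
#' swappable for the full published form by replacing these two functions.
#'
#' @param a0,a1,a2 Coefficients of the chlorophyll-to-carbon function.
#'   `a0 > 0`, `a1 >= 0`, `a2 >= 0`.
#' @param mu_hat Asymptotic maximum growth rate, day^-1 (> 0).
#' @param k_i Half-saturation irradiance of the maximum-growth-rate
#'   function, umol photons m^-2 s^-1 (> 0).
#' @param k_r Maintenance respiration rate, day^-1 (>= 0).
#' @return An object of class `allocation_params`.
#' @export
allocation_params <- function(a0 = 4e-4, a1 = 1.5e-3, a2 = 1.2e-3,
                              mu_hat = 0.6, k_i = 25, k_r = 0.05) {
  if (a0 <= 0 || a1 < 0 || a2 < 0) stop("invalid chl-to-carbon coefficients")
  if (mu_hat <= 0 || k_i <= 0) stop("`mu_hat` and `k_i` must be > 0")
  if (k_r < 0) stop("`k_r` must be >= 0")
  structure(list(a0 = a0, a1 = a1, a2 = a2, mu_hat = mu_hat,
                 k_i = k_i, k_r = k_r),
            class = "allocation_params")
}

#' Chlorophyll-to-carbon ratio as a function of growth rate and irradiance
#'
#' Contracted photo-acclimation function
#' `qChl/qC = (a0 + a1 * mu) / (1 + a2 * I)`: strictly decreasing in
#' irradiance at fixed growth rate, non-decreasing in growth rate at fixed
#' irradiance, and always positive.
#'
#' @param growth_rate Growth rate, day^-1 (>= 0).
#' @param irradiance PAR, umol photons m^-2 s^-1; must be strictly positive
#'   (the ratio is undefined at zero light in the contracted form; callers
#'   must apply a floor).
#' @param alloc An [allocation_params()] object.
#' @return Molar qChl/qC ratio.
#' @export
chl_to_carbon_ratio <- function(growth_rate, irradiance, alloc) {
  stopifnot(inherits(alloc, "allocation_params"))
  if (any(growth_rate < 0)) stop("`growth_rate` must be >= 0")
  if (any(irradiance <= 0)) stop("`irradiance` must be > 0 (apply a light floor)")
  (alloc$a0 + alloc$a1 * growth_rate) / (1 + alloc$a2 * irradiance)
}

#' Irradiance-limited maximum growth rate
#'
#' Contracted allocation ceiling `mu_hat * I / (I + k_i)`: zero in the dark,
#' non-decreasing in irradiance, saturating at `mu_hat`.
#'
#' @param irradiance PAR, umol photons m^-2 s^-1 (>= 0, vectorised).
#' @param alloc An [allocation_params()] object.
#' @return Maximum growth rate, day^-1.
#' @export
max_growth_rate <- function(irradiance, alloc) {
  stopifnot(inherits(alloc, "allocation_params"))
  if (any(irradiance < 0)) stop("`irradiance` must be >= 0")
  alloc$mu_hat * irradiance / (irradiance + alloc$k_i)
}

#' Solve the light-limited autotrophic growth rate iteratively
#'
#' Finds the fixed point of the coupled photo-acclimation system: the
#' chlorophyll-to-carbon ratio is evaluated from the current growth-rate
#' iterate and the noon irradiance, the daily-averaged fixation rate is
#' computed from that ratio, and the rate is updated as
#' `min(P - k_r, mu_max(I))`. The sequence is under-relaxed and repeated
#' until successive iterates differ by less than `tol`.
#'
#' The raw fixed-point rate may be negative (respiration exceeding fixation
#' in the dark); it is retained in the output alongside the value clamped at
#' zero used in limitation profiles.
#'
#' @param noon_irradiance Noon PAR (>= 0).
#' @param diel A [diel_irradiance_factors()] object.
#' @param params A [photo_phys_params()] object.
#' @param alloc An [allocation_params()] object.
#' @param tol Absolute convergence tolerance on the rate, day^-1.
#' @param max_iter Maximum number of iterations.
#' @param relax Under-relaxation factor in (0, 1].
#' @param init Initial growth-rate guess, day^-1.
#' @param light_floor Irradiance floor used when evaluating the
#'   chlorophyll-to-carbon ratio (which is undefined at zero light).
#' @return A list with elements `rate` (clamped at >= 0), `rate_raw`,
#'   `chl_to_c`, `iterations` and `converged`.
#' @export
solve_autotrophic_rate <- function(noon_irradiance, diel, params, alloc,
                                   tol = 1e-6, max_iter = 200L, relax = 0.5,
                                   init = 0.1, light_floor = 1e-3) {
  stopifnot(inherits(diel, "diel_irradiance"))
  if (noon_irradiance < 0) stop("`noon_irradiance` must be >= 0")
  i_eff <- max(noon_irradiance, light_floor)
  mu_cap <- max_growth_rate(noon_irradiance, alloc)
  rate <- init
  converged <- FALSE
  iter <- 0L
  ratio <- chl_to_carbon_ratio(max(rate, 0), i_eff, alloc)
  while (iter < max_iter) {
    iter <- iter + 1L
    ratio <- chl_to_carbon_ratio(max(rate, 0), i_eff, alloc)
    p_daily <- daily_mean_fixation(noon_irradiance, diel, ratio, params)
    rate_new <- min(p_daily - alloc$k_r, mu_cap)
    if (abs(rate_new - rate) < tol) {
      rate <- rate_new
      converged <- TRUE
      break
    }
    rate <- relax * rate_new + (1 - relax) * rate
  }
  if (!converged) {
    stop(sprintf("autotrophic-rate iteration did not converge in %d steps (last iterate %.6g day^-1)",
                 max_iter, rate))
  }
  list(rate = max(rate, 0), rate_raw = rate,
       chl_to_c = chl_to_carbon_ratio(max(rate, 0), i_eff, alloc),
       iterations = iter, converged = converged)
}
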