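#' Co-registered environmental depth profile
#'
#' A validated depth grid with noon PAR, nutrient concentrations and,
#' optionally, cell density and observed growth rates. Depths are positive
#' downward in metres and must be strictly increasing; noon PAR must be
#' non-increasing with depth; concentrations must be non-negative (iron
#' after detection-limit substitution).
#'
#' @param depth Depth grid, m, strictly increasing.
#' @param noon_par Noon PAR per depth, umol photons m^-2 s^-1.
#' @param din Dissolved inorganic nitrogen, mol N m^-3.
#' @param po4 Phosphate, mol P m^-3.
#' @param fe Dissolved iron, nmol l^-1, or `NULL` when unavailable.
#' @param cell_density Cells m^-3, or `NULL`.
#' @param observed_growth Observed growth rate, day^-1, may contain `NA`
#'   gaps (linearly interpolated downstream), or `NULL`.
#' @param latitude,day_of_year Location and date used for the diel cycle.
#' @return An object of class `environment_profile` (a data frame with
#'   attributes `latitude` and `day_of_year`).
#' @export
environment_profile <- function(depth, noon_par, din, po4, fe = NULL,
                                cell_density = NULL, observed_growth = NULL,
                                latitude = 22.75, day_of_year = 196) {
  n <- length(depth)
  if (n == 0L) stop("empty profile")
  if (any(diff(depth) <= 0)) stop("`depth` must be strictly increasing")
  stopifnot(length(noon_par) == n, length(din) == n, length(po4) == n)
  if (any(noon_par < 0) || any(diff(noon_par) > 1e-9)) {
    stop("`noon_par` must be non-negative and non-increasing with depth")
  }
  if (any(din < 0)) stop("`din` must be >= 0")
  if (any(po4 < 0)) stop("`po4` must be >= 0")
  if (!is.null(fe)) {
    stopifnot(length(fe) == n)
    if (any(fe < 0)) stop("`fe` must be >= 0")
  }
  if (!is.null(cell_density)) {
    stopifnot(length(cell_density) == n)
    if (any(cell_density < 0, na.rm = TRUE)) stop("`cell_density` must be >= 0")
  }
  if (!is.null(observed_growth)) stopifnot(length(observed_growth) == n)
  df <- data.frame(depth = depth, noon_par = noon_par, din = din, po4 = po4)
  df$fe <- if (is.null(fe)) NA_real_ else fe
  df$cell_density <- if (is.null(cell_density)) NA_real_ else cell_density
  df$observed_growth <- if (is.null(observed_growth)) NA_real_ else observed_growth
  structure(df, latitude = latitude, day_of_year = day_of_year,
            has_fe = !is.null(fe),
            class = c("environment_profile", "data.frame"))
}

#' Linear interpolation of gappy observed growth rates
#'
#' Fills `NA` gaps in an observed growth-rate profile by linear
#' interpolation in depth, never extrapolating beyond the outermost
#' observed points (values outside remain `NA`).
#'
#' @param depth Depth grid, m.
#' @param observed_growth Observed growth with `NA` gaps.
#' @return Interpolated vector of the same length.
#' @export
interpolate_observed_growth <- function(depth, observed_growth) {
  ok <- !is.na(observed_growth)
  if (sum(ok) == 0L) return(observed_growth)
  if (sum(ok) == 1L) {
    out <- rep(NA_real_, length(depth))
    out[ok] <- observed_growth[ok]
    return(out)
  }
  approx(depth[ok], observed_growth[ok], xout = depth, rule = 1)$y
}

#' Depth profile of autotrophic growth limitation (minimum law)
#'
#' Evaluates, at every depth of an environmental profile, the light-limited
#' autotrophic rate (iterative Platt/photo-acclimation solution), the N-, P-
#' and (when iron data exist) Fe-specific uptake rates, and takes the
#' minimum as the local modelled photo-autotrophic growth rate, recording
#' which component limits. One photo-physiological scenario per call; the
#' four canonical scenarios are HL and LL parameterisations each with and
#' without photo-inhibition (see [canonical_scenarios()]).
#'
#' @param env An [environment_profile()].
#' @param photophys A [photo_phys_params()] object.
#' @param alloc An [allocation_params()] object.
#' @param nutrients A [nutrient_uptake_params()] object.
#' @param n_steps_per_day Diel resolution for the daily fixation average.
#' @return An object of class `growth_profile_result`: a data frame with
#'   per-depth columns `v_c_auto`, `v_c_auto_raw`, `v_n`, `v_p`, `v_fe`,
#'   `mu_auto`, `limiter`, `mu_observed` and (after
#'   [infer_heterotrophic_rate()]) `mu_het`; the scenario label is kept in
#'   the `scenario` attribute.
#' @export
autotrophic_profile <- function(env, photophys, alloc, nutrients,
                                n_steps_per_day = 24L) {
  stopifnot(inherits(env, "environment_profile"),
            inherits(photophys, "photo_phys_params"),
            inherits(alloc, "allocation_params"),
            inherits(nutrients, "nutrient_uptake_params"))
  if (nrow(env) == 0L) stop("empty profile")
  diel <- diel_irradiance_factors(attr(env, "latitude"),
                                  attr(env, "day_of_year"),
                                  n_steps_per_day)
  sol <- lapply(env$noon_par, solve_autotrophic_rate,
                diel = diel, params = photophys, alloc = alloc)
  v_c <- vapply(sol, `[[`, numeric(1), "rate")
  v_c_raw <- vapply(sol, `[[`, numeric(1), "rate_raw")
  chl_to_c <- vapply(sol, `[[`, numeric(1), "chl_to_c")
  v_n <- michaelis_specific_rate(env$din, nutrients$vmax_n, nutrients$k_n,
                                 nutrients$q_n)
  v_p <- michaelis_specific_rate(env$po4, nutrients$vmax_p, nutrients$k_p,
                                 nutrients$q_p)
  has_fe <- isTRUE(attr(env, "has_fe"))
  v_fe <- if (has_fe) iron_specific_rate(env$fe, nutrients) else rep(NA_real_, nrow(env))
  comp <- cbind(light = v_c, N = v_n, P = v_p, Fe = v_fe)
  use <- c(TRUE, TRUE, TRUE, has_fe)
  mu_auto <- apply(comp[, use, drop = FALSE], 1, min)
  limiter <- colnames(comp)[use][apply(comp[, use, drop = FALSE], 1, which.min)]
  mu_obs <- interpolate_observed_growth(env$depth, env$observed_growth)
  out <- data.frame(depth = env$depth, noon_par = env$noon_par,
                    v_c_auto = v_c, v_c_auto_raw = v_c_raw,
                    chl_to_c = chl_to_c, v_n = v_n, v_p = v_p, v_fe = v_fe,
                    mu_auto = mu_auto, limiter = limiter,
                    mu_observed = mu_obs, mu_het = NA_real_,
                    cell_density = env$cell_density)
  structure(out, scenario = photophys$label, has_fe = has_fe,
            class = c("growth_profile_result", "data.frame"))
}

#' The four canonical photo-physiology scenarios
#'
#' Expands HL and LL parameter presets into the four scenarios used to
#' bracket the plausible autotrophic growth range: each ecotype
#' parameterisation with its configured photo-inhibition coefficient and
#' with photo-inhibition switched off (`beta_chl = 0`).
#'
#' @param hl,ll [photo_phys_params()] presets for the high-light- and
#'   low-light-adapted ecotypes. Defaults come from [default_config()].
#' @return Named list of four `photo_phys_params` objects.
#' @export
canonical_scenarios <- function(hl = NULL, ll = NULL) {
  cfg <- default_config()
  if (is.null(hl)) hl <- do.call(photo_phys_params, c(cfg$photophys$HL, list(label = "HL")))
  if (is.null(ll)) ll <- do.call(photo_phys_params, c(cfg$photophys$LL, list(label = "LL")))
  list(
    `HL+inhib` = photo_phys_params(hl$ps_chl, hl$alpha_chl, hl$beta_chl, "HL+inhib"),
    `HL-inhib` = photo_phys_params(hl$ps_chl, hl$alpha_chl, 0, "HL-inhib"),
    `LL+inhib` = photo_phys_params(ll$ps_chl, ll$alpha_chl, ll$beta_chl, "LL+inhib"),
    `LL-inhib` = photo_phys_params(ll$ps_chl, ll$alpha_chl, 0, "LL-inhib")
  )
}

#' Infer heterotrophically supported growth
#'
#' Where the observed growth rate exceeds the modelled photo-autotrophic
#' rate, the shortfall is interpreted as heterotrophically supported
#' growth: `mu_het = max(0, mu_observed - mu_auto)` at every depth.
#'
#' @param result A `growth_profile_result` from [autotrophic_profile()]
#'   with observed growth present.
#' @return The result with the `mu_het` column populated.
#' @export
infer_heterotrophic_rate <- function(result) {
  stopifnot(inherits(result, "growth_profile_result"))
  if (all(is.na(result$mu_observed))) {
    stop("observed growth is missing everywhere; cannot infer heterotrophic rate")
  }
  result$mu_het <- pmax(0, result$mu_observed - result$mu_auto)
  result
}

#' Trapezoidal integral on the native depth grid
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Vertically integrated autotrophic and heterotrophic production
#'
#' Integrates `rate * cell_density * carbon_quota` over depth by the
#' trapezoid rule for the autotrophic and inferred heterotrophic rates, and
#' reports the heterotrophic fraction of total production, overall and
#' restricted to depths below the mixotrophy onset depth.
#'
#' @param result A `growth_profile_result` with `mu_het` populated.
#' @param cell_density Cells m^-3 per depth; defaults to the profile's own
#'   column.
#' @param carbon_quota Carbon per cell, g C cell^-1.
#' @return A list: `autotrophic_production` and `heterotrophic_production`
#'   (g C m^-2 day^-1), `heterotrophic_fraction` and
#'   `below_onset_heterotrophic_fraction` (%), and `onset` (the
#'   [mixotrophy_onset_depth()] result).
#' @export
integrate_production <- function(result, cell_density = NULL,
                                 carbon_quota = 50e-15) {
  stopifnot(inherits(result, "growth_profile_result"))
  if (is.null(cell_density)) cell_density <- result$cell_density
  if (any(is.na(cell_density))) stop("cell density unavailable")
  if (any(cell_density < 0)) stop("negative cell densities")
  if (all(is.na(result$mu_het))) stop("`mu_het` not computed; run infer_heterotrophic_rate() first")
  z <- result$depth
  ok <- !is.na(result$mu_het)
  auto_rate <- ifelse(is.na(result$mu_auto), 0, result$mu_auto)
  het_rate <- ifelse(is.na(result$mu_het), 0, result$mu_het)
  auto <- trapz(z, auto_rate * cell_density * carbon_quota)
  het <- trapz(z, het_rate * cell_density * carbon_quota)
  onset <- mixotrophy_onset_depth(result)
  frac <- if (auto + het > 0) 100 * het / (auto + het) else NA_real_
  below <- NA_real_
  z_on <- onset$onset_depth
  if (!is.na(z_on)) {
    keep <- z >= z_on
    zz <- c(z_on, z[keep])
    a_on <- approx(z, auto_rate * cell_density * carbon_quota, xout = z_on)$y
    h_on <- approx(z, het_rate * cell_density * carbon_quota, xout = z_on)$y
    auto_b <- trapz(zz, c(a_on, (auto_rate * cell_density * carbon_quota)[keep]))
    het_b <- trapz(zz, c(h_on, (het_rate * cell_density * carbon_quota)[keep]))
    if (auto_b + het_b > 0) below <- 100 * het_b / (auto_b + het_b)
  }
  list(autotrophic_production = auto, heterotrophic_production = het,
       heterotrophic_fraction = frac,
       below_onset_heterotrophic_fraction = below,
       onset = onset)
}

#' First crossing of `y` above `ref` along a depth grid, interpolated
#' @noRd
first_crossing_depth <- function(z, y, ref) {
  d <- y - ref
  ok <- !is.na(d)
  z <- z[ok]; d <- d[ok]
  if (length(d) == 0L) return(NA_real_)
  if (d[1] > 0) return(z[1])
  idx <- which(d[-1] > 0 & d[-length(d)] <= 0)
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1]
  z[i] + (z[i + 1] - z[i]) * (0 - d[i]) / (d[i + 1] - d[i])
}

#' Depth at which mixotrophy becomes important
#'
#' Reports two onset definitions, both linearly interpolated between grid
#' points: the shallowest depth at which the inferred heterotrophic rate
#' first exceeds zero, and the shallowest depth at which it exceeds the
#' autotrophic rate (heterotrophy dominating photosynthesis, the headline
#' definition). Also reports the PAR at the dominance onset depth
#' (log-linear interpolation of the noon PAR profile, exact for
#' exponentially attenuated light).
#'
#' @param result A `growth_profile_result` with `mu_het` populated.
#' @return A list `onset_depth` (heterotrophy > photosynthesis; `NA` when
#'   no crossing, with `onset_flag = "none"`), `first_positive_depth`
#'   (heterotrophy > 0), `onset_par` and `onset_flag`.
#' @export
mixotrophy_onset_depth <- function(result) {
  stopifnot(inherits(result, "growth_profile_result"))
  z <- result$depth
  z_dom <- first_crossing_depth(z, result$mu_het - result$mu_auto, 0)
  z_pos <- first_crossing_depth(z, result$mu_het, 1e-12)
  par_on <- NA_real_
  if (!is.na(z_dom)) {
    if (all(result$noon_par > 0)) {
      par_on <- exp(approx(z, log(result$noon_par), xout = z_dom)$y)
    } else {
      par_on <- approx(z, result$noon_par, xout = z_dom)$y
    }
  }
  list(onset_depth = z_dom, first_positive_depth = z_pos,
       onset_par = par_on,
       onset_flag = if (is.na(z_dom)) "none" else "crossed")
}

#' Per-depth extreme range over several limitation scenarios
#'
#' Computes the per-depth minimum and maximum of the modelled autotrophic
#' rate across a list of scenario results (the envelope drawn as shading
#' around scenario curves).
#'
#' @param results List of `growth_profile_result` objects on a common grid.
#' @return Data frame with `depth`, `mu_auto_min`, `mu_auto_max`.
#' @export
scenario_envelope <- function(results) {
  stopifnot(length(results) >= 1L)
  z <- results[[1]]$depth
  for (r in results) stopifnot(identical(r$depth, z))
  m <- vapply(results, function(r) r$mu_auto, numeric(length(z)))
  m <- matrix(m, nrow = length(z))
  data.frame(depth = z,
             mu_auto_min = apply(m, 1, min),
             mu_auto_max = apply(m, 1, max))
}
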