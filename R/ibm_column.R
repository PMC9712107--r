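#' Configuration of the individual-based water-column model
#'
#' All parameters of the 1-D column simulator: column geometry, light
#' field, per-cell photo-physiology (fixed chlorophyll-to-carbon ratio),
#' quota bounds and structural stoichiometry, nutrient and DOC uptake
#' kinetics with the photosynthetic-fraction gate, maintenance and
#' biosynthesis rates, division and grazing probability parameters,
#' two-layer eddy diffusivity, boundary restoring, and run control.
#'
#' The desk-scale default is a 0-200 m column on a 2 m grid, a 10-minute
#' timestep, 120 simulated days and ~2,000 super-agents, with profiles
#' averaged over the final quarter of the run.
#'
#' @param ... Named overrides of any default field (see
#'   [ibm_default_config()] for the full list).
#' @param mixotrophy Logical: can cells assimilate DOC?
#' @return An object of class `ibm_config` (a named list).
#' @export
ibm_config <- function(..., mixotrophy = TRUE) {
  cfg <- ibm_default_config()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg$mixotrophy <- mixotrophy
  if (cfg$f_ps_min <= 0 || cfg$f_ps_min >= 1) stop("f_ps_min must be in (0, 1)")
  if (cfg$dt <= 0) stop("timestep must be > 0")
  if (cfg$qc_max <= cfg$qc_min) stop("qc_max must exceed qc_min")
  if (86400 %% cfg$dt != 0) stop("dt must divide 86400 s")
  structure(cfg, class = "ibm_config")
}

#' Default parameter set of the individual-based model
#'
#' @return Named list of defaults (units in the comments of the source).
#' @export
ibm_default_config <- function() {
  list(
    # column
    depth_max = 200, dz = 2,                     # m
    # light
    i0 = 600, kd = 0.055,                        # umol photons m^-2 s^-1; m^-1
    latitude = 22.75, day_of_year = 172,
    # per-cell photo-physiology (fixed acclimation in the IBM)
    ps_chl = 0.05, alpha_chl = 2e-3, beta_chl = 2e-5,
    chl2c = 1.08e-3,                             # mol Chl (mol C)^-1
    # quotas / structure
    c0 = 2e-15,                                  # structural mol C at size 1
    qc_min = 4e-16, qc_max = 8e-15,              # mol C cell^-1
    qn_min = 6e-17, qn_max = 3e-16,              # mol N cell^-1
    qp_min = 4e-18, qp_max = 2e-17,              # mol P cell^-1
    r_n = 1 / 6.6, r_p = 1 / 106,                # structural N:C, P:C
    # nutrient uptake (per cell, per second)
    vmax_n = 8e-21, k_n = 5e-4,                  # mol N s^-1; mol N m^-3
    vmax_p = 5e-22, k_p = 5e-5,                  # mol P s^-1; mol P m^-3
    # DOC uptake and the photosynthetic-fraction gate
    v_doc_max = 9e-20, k_doc_sat = 2e-3,         # mol C s^-1; mol C m^-3
    f_ps_min = 0.01,
    # DOC-like tracer: surface background plus a remineralisation maximum
    # (Gaussian bump) just below the photic zone
    doc_background = 3e-4, doc_deep_background = 5.5e-3,
    doc_deep_mid = 119, doc_deep_width = 15,
    doc_restore_days = 8,
    graze_doc_frac = 0.3, graze_export_frac = 0.25,
    # maintenance and biosynthesis
    k_r = 0.45, mu_syn_max = 1.4,                # day^-1
    # division: logistic in relative size, midpoint at twice minimum size
    nu_max = 1.4, s_mid = 2, ks = 10,
    # quadratic grazing
    g_quad = 1e-12,                              # m^3 cell^-1 day^-1
    # mixing
    kappa_ml = 1e-2, kappa_deep = 2e-4,          # m^2 s^-1
    mld = 50, mld_width = 5,                     # m
    # boundary restoring and initial nutricline shape
    din_deep = 1.3e-2, po4_deep = 3e-4,          # mol m^-3
    nutricline_init_mid = 75, nutricline_init_width = 10,  # m
    restore_tau_days = 6, restore_thickness = 10,
    closed_boundaries = FALSE,
    # run control
    dt = 600, n_days = 240, n_super_agents = 2000,
    init_density = 5e10,                         # cells m^-3, uniform
    mixotrophy = TRUE
  )
}

#' Cell-specific DOC uptake rate (pre-gating quota regulation)
#'
#' `v_doc_max * clamp((qc_max - qc)/(qc_max - qc_min), 0, 1) *
#' DOC/(DOC + k_doc_sat)`: uptake vanishes when the carbon reserve is full
#' and saturates in ambient DOC. Returns 0 when the mixotrophy flag is
#' off.
#'
#' @param agent A list/row with at least `qc` (mol C cell^-1).
#' @param doc_concentration Ambient DOC, mol C m^-3 (>= 0).
#' @param config An [ibm_config()].
#' @return Uptake rate, mol C cell^-1 s^-1.
#' @export
doc_uptake <- function(agent, doc_concentration, config) {
  stopifnot(inherits(config, "ibm_config"))
  if (any(doc_concentration < 0)) stop("`doc_concentration` must be >= 0")
  if (!isTRUE(config$mixotrophy)) return(0 * doc_concentration)
  head_c <- pmin(1, pmax(0, (config$qc_max - agent$qc) /
                           (config$qc_max - config$qc_min)))
  config$v_doc_max * head_c *
    doc_concentration / (doc_concentration + config$k_doc_sat)
}

#' Photosynthetic fraction and the DOC-uptake gate
#'
#' `f_PS = P_S / (P_S + V_DOC)` (defined as 1 when both rates are zero) is
#' the fraction of incorporated carbon originating from photosynthesis;
#' DOC uptake is gated off entirely when `f_PS` falls below `f_ps_min`
#' (1% by default), encoding the inability of *Prochlorococcus* to live
#' heterotrophically in prolonged darkness. `1 - f_PS` is the recorded DOC
#' contribution.
#'
#' @param photosynthesis_rate P_S, mol C cell^-1 s^-1 (>= 0).
#' @param v_doc Ungated DOC uptake, mol C cell^-1 s^-1 (>= 0).
#' @param config An [ibm_config()] (only `f_ps_min` is used).
#' @return List with `f_ps`, `v_doc_gated` and `doc_contribution`
#'   (`1 - f_ps`).
#' @export
photosynthesis_fraction_gate <- function(photosynthesis_rate, v_doc, config) {
  if (any(photosynthesis_rate < 0) || any(v_doc < 0)) {
    stop("rates must be >= 0")
  }
  tot <- photosynthesis_rate + v_doc
  f_ps <- ifelse(tot > 0, photosynthesis_rate / tot, 1)
  gated <- ifelse(f_ps < config$f_ps_min, 0, v_doc)
  list(f_ps = f_ps, v_doc_gated = gated, doc_contribution = 1 - f_ps)
}

#' Initial agent population and tracer fields
#'
#' Agents at uniformly spaced depths over the column with mid-range
#' reserves and size 1; multiplicity chosen so the initial cell density
#' matches `init_density`. DIN and PO4 start on a sigmoid nutricline
#' (surface-depleted, deep values at the boundary concentrations), DOC at
#' its background.
#'
#' @param config An [ibm_config()].
#' @param n_agents Number of initial super-agents (default: half the cap,
#'   leaving room for division).
#' @return List with `agents` (matrix) and `tracers` (matrix).
#' @export
ibm_initial_state <- function(config, n_agents = NULL) {
  stopifnot(inherits(config, "ibm_config"))
  if (is.null(n_agents)) n_agents <- max(2L, config$n_super_agents %/% 2L)
  z <- seq(0, config$depth_max, length.out = n_agents + 2)[2:(n_agents + 1)]
  mult <- config$init_density * config$depth_max / n_agents
  agents <- cbind(depth = z,
                  qc = (config$qc_min + config$qc_max) / 2,
                  qn = (config$qn_min + config$qn_max) / 2,
                  qp = (config$qp_min + config$qp_max) / 2,
                  size = 1, mult = mult)
  ngrid <- round(config$depth_max / config$dz)
  zc <- (seq_len(ngrid) - 0.5) * config$dz
  sig <- function(deep) {
    deep / (1 + exp(-(zc - config$nutricline_init_mid) /
                      config$nutricline_init_width))
  }
  tracers <- cbind(din = sig(config$din_deep),
                   po4 = sig(config$po4_deep),
                   doc = rep(config$doc_background, ngrid))
  list(agents = agents, tracers = tracers)
}

#' Advance the population and tracers by one or more timesteps
#'
#' Thin wrapper around the compiled core loop: per step, light at each
#' agent's depth (surface diel PAR, exponential attenuation),
#' photosynthesis into the carbon reserve, quota-regulated DIN/PO4 uptake
#' depleting the tracers, gated DOC uptake, biosynthesis with maintenance
#' respiration, sigmoidal-size probabilistic division, quadratic grazing
#' with remineralisation, vertical random-walk mixing, implicit tracer
#' diffusion and boundary restoring. Set the R RNG seed beforehand for a
#' reproducible trajectory.
#'
#' @param agents Agent matrix (columns depth, qc, qn, qp, size, mult).
#' @param tracers Tracer matrix (ngrid x 3: din, po4, doc).
#' @param time_of_day Seconds since midnight at the start of the call.
#' @param config An [ibm_config()].
#' @param n_steps Number of timesteps to take.
#' @param check_conservation Assert closed-column N/P conservation to
#'   1e-9 relative per step (bug detector; use with
#'   `closed_boundaries = TRUE`).
#' @return List with updated `agents`, `tracers`, and the accumulator
#'   fields of the core (all zero unless `n_steps` exceeds the averaging
#'   start, which for this wrapper is step 0).
#' @export
step_population <- function(agents, tracers, time_of_day, config,
                            n_steps = 1L, check_conservation = FALSE) {
  stopifnot(inherits(config, "ibm_config"))
  diel <- diel_irradiance_factors(config$latitude, config$day_of_year,
                                  n_steps_per_day = 86400 / config$dt)
  ibm_core_run(unclass(config), agents, tracers, diel$factors,
               as.integer(n_steps), time_of_day, 0L, check_conservation)
}

#' Run one scenario of the individual-based model as an ensemble
#'
#' Runs `n_ensemble` members with distinct seeds (`seed + member - 1`),
#' each for `config$n_days` simulated days, averaging all profiles over
#' the final quarter of the run (the quasi-steady state). Returns
#' per-depth ensemble means and min/max bands of cell density, division
#' rate, DIN, PO4, DOC, the mean DOC contribution `1 - f_PS`, and the
#' actual photosynthetic/DOC carbon acquisition used for contribution
#' integrals, plus reserve-saturation diagnostics used to locate the
#' nutrient-to-carbon limitation transition.
#'
#' @param config An [ibm_config()].
#' @param n_ensemble Number of ensemble members (>= 1).
#' @param seed Integer base seed.
#' @return An object of class `ibm_scenario`: list with `depth` (bin
#'   centres), `members` (per-member profile lists), `mean` (ensemble-mean
#'   profiles), `band` (per-depth min/max of density and division rate),
#'   `extinct` (logical vector) and `config`.
#' @export
run_scenario <- function(config, n_ensemble = 5L, seed = 1L) {
  stopifnot(inherits(config, "ibm_config"), n_ensemble >= 1L)
  diel <- diel_irradiance_factors(config$latitude, config$day_of_year,
                                  n_steps_per_day = 86400 / config$dt)
  n_steps <- as.integer(round(config$n_days * 86400 / config$dt))
  avg_start <- as.integer(round(n_steps * 0.75))
  ngrid <- round(config$depth_max / config$dz)
  zc <- (seq_len(ngrid) - 0.5) * config$dz
  init <- ibm_initial_state(config)
  members <- vector("list", n_ensemble)
  extinct <- logical(n_ensemble)
  for (m in seq_len(n_ensemble)) {
    set.seed(seed + m - 1L)
    res <- ibm_core_run(unclass(config), init$agents, init$tracers,
                        diel$factors, n_steps, 0, avg_start, FALSE)
    nav <- max(res$n_avg_steps, 1)
    avg_days <- nav * config$dt / 86400
    binvol <- config$dz
    dens <- res$acc_mult / nav / binvol
    divr <- ifelse(res$acc_mult > 0, res$acc_div / (res$acc_mult * config$dt / 86400), NA_real_)
    members[[m]] <- list(
      density = dens,
      division_rate = divr,
      din = res$acc_din / nav, po4 = res$acc_po4 / nav,
      doc = res$acc_doc_tracer / nav,
      doc_contribution = ifelse(res$acc_mult > 0,
                                res$acc_one_minus_fps / res$acc_mult, NA_real_),
      ps_acquired = res$acc_ps / avg_days,   # mol C m^-1 day^-1 per bin
      doc_acquired = res$acc_doc / avg_days,
      production = res$acc_prod / avg_days,  # biosynthesis, mol C m^-1 day^-1
      lim_c = ifelse(res$acc_mult > 0, res$acc_lc / res$acc_mult, NA_real_),
      lim_n = ifelse(res$acc_mult > 0, res$acc_ln / res$acc_mult, NA_real_),
      lim_p = ifelse(res$acc_mult > 0, res$acc_lp / res$acc_mult, NA_real_),
      div_events = res$acc_div, avg_days = avg_days)
    extinct[m] <- isTRUE(res$extinct)
  }
  fields <- c("density", "division_rate", "din", "po4", "doc",
              "doc_contribution", "ps_acquired", "doc_acquired",
              "production", "lim_c", "lim_n", "lim_p")
  mean_prof <- lapply(fields, function(f) {
    m <- vapply(members, `[[`, numeric(ngrid), f)
    rowMeans(m, na.rm = TRUE)
  })
  names(mean_prof) <- fields
  safe_range <- function(x, fun) if (all(is.na(x))) NA_real_ else fun(x, na.rm = TRUE)
  band <- lapply(c("density", "division_rate"), function(f) {
    m <- vapply(members, `[[`, numeric(ngrid), f)
    list(min = apply(m, 1, safe_range, min),
         max = apply(m, 1, safe_range, max))
  })
  names(band) <- c("density", "division_rate")
  structure(list(depth = zc, members = members, mean = mean_prof,
                 band = band, extinct = extinct, config = config,
                 n_ensemble = n_ensemble, seed = seed),
            class = "ibm_scenario")
}

#' Per-depth daily division rate from a division-event log
#'
#' Division events per day per cell, binned by depth: the event count
#' (cells dividing, multiplicity-weighted) divided by the time-integrated
#' cell count in the bin. Bins that never held cells are reported as
#' missing, not zero.
#'
#' @param division_events Per-bin multiplicity-weighted division events
#'   over the averaging window.
#' @param cell_time Per-bin time-integrated cell count, cell-days (i.e.
#'   mean cell count times window length in days).
#' @return Per-bin division rate, day^-1 (`NA` for empty bins).
#' @export
division_rate_profile <- function(division_events, cell_time) {
  stopifnot(length(division_events) == length(cell_time))
  ifelse(cell_time > 0, division_events / cell_time, NA_real_)
}

#' Nutricline depth by threshold crossing
#'
#' Shallowest depth at which a (surface-depleted, monotone-increasing
#' below the mixed layer) nutrient profile crosses a threshold
#' concentration, linearly interpolated between grid points. Returns `NA`
#' with flag `"none"` when the profile never reaches the threshold.
#'
#' @param depth Depth grid, m.
#' @param concentration Nutrient concentration per depth.
#' @param threshold Threshold concentration (same units).
#' @return List with `depth` (m or `NA`) and `flag`.
#' @export
nutricline_depth <- function(depth, concentration, threshold) {
  stopifnot(length(depth) == length(concentration))
  z <- first_crossing_depth(depth, concentration, threshold)
  list(depth = z, flag = if (is.na(z)) "none" else "crossed")
}

#' Depth of the nutrient-to-carbon limitation transition
#'
#' Shallowest depth at which the population-mean carbon-reserve
#' saturation drops below the nitrogen-reserve saturation, i.e. where
#' carbon (light) replaces nitrogen as the scarcer resource.
#'
#' @param scenario An `ibm_scenario` from [run_scenario()].
#' @return Transition depth, m (`NA` if never).
#' @export
limitation_transition_depth <- function(scenario) {
  stopifnot(inherits(scenario, "ibm_scenario"))
  lc <- scenario$mean$lim_c
  ln <- scenario$mean$lim_n
  ok <- which(!is.na(lc) & !is.na(ln))
  idx <- ok[lc[ok] < ln[ok]]
  if (length(idx) == 0L) return(NA_real_)
  scenario$depth[min(idx)]
}

#' Contribution of DOC uptake to vertically integrated production
#'
#' Production-weighted DOC share: each depth bin's biosynthesis flux is
#' weighted by the bin's DOC fraction of total carbon acquisition
#' (photosynthesis + DOC uptake), integrated over depth and divided by
#' total integrated production; optionally restricted to depths at or
#' below `below_depth`.
#'
#' @param scenario An `ibm_scenario`.
#' @param below_depth Restrict the integral to bins at or deeper than
#'   this depth, m (`NULL` for the whole column).
#' @return Percentage.
#' @export
doc_contribution_integrated <- function(scenario, below_depth = NULL) {
  stopifnot(inherits(scenario, "ibm_scenario"))
  keep <- rep(TRUE, length(scenario$depth))
  if (!is.null(below_depth)) keep <- scenario$depth >= below_depth
  acq <- scenario$mean$ps_acquired + scenario$mean$doc_acquired
  share <- ifelse(acq > 0, scenario$mean$doc_acquired / acq, 0)
  prod <- scenario$mean$production
  tot <- sum(prod[keep])
  if (tot <= 0) return(NA_real_)
  100 * sum(prod[keep] * share[keep]) / tot
}

#' Depth at which the division rate falls to zero
#'
#' Shallowest depth below which the steady-state division-rate profile
#' stays at (effectively) zero for the rest of the column: the depth of
#' the first bin after the deepest bin with a division rate above
#' `min_rate`.
#'
#' @param scenario An `ibm_scenario`.
#' @param min_rate Rates at or below this are treated as zero, day^-1.
#' @return Cutoff depth, m (`NA` if division occurs everywhere).
#' @export
division_cutoff_depth <- function(scenario, min_rate = 0.01) {
  stopifnot(inherits(scenario, "ibm_scenario"))
  r <- scenario$mean$division_rate
  r[is.na(r)] <- 0
  active <- which(r > min_rate)
  if (length(active) == 0L) return(scenario$depth[1])
  last <- max(active)
  if (last == length(r)) return(NA_real_)
  (scenario$depth[last] + scenario$depth[last + 1]) / 2
}

#' Division rate in the bin containing a given depth
#'
#' @param scenario An `ibm_scenario`.
#' @param depth Target depth, m.
#' @return Ensemble-mean division rate, day^-1.
#' @export
division_rate_at <- function(scenario, depth) {
  stopifnot(inherits(scenario, "ibm_scenario"))
  i <- which.min(abs(scenario$depth - depth))
  scenario$mean$division_rate[i]
}
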