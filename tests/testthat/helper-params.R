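# shared fixtures: default parameter objects and a small synthetic profile
default_photophys <- function(which = "HL") {
  cfg <- default_config()
  do.call(photo_phys_params, c(cfg$photophys[[which]], list(label = which)))
}

default_alloc <- function() do.call(allocation_params, default_config()$allocation)

default_nutrients <- function() do.call(nutrient_uptake_params, default_config()$nutrients)

default_diel <- function(n = 24) diel_irradiance_factors(22.75, 196, n)

# a bare-bones growth_profile_result for integration tests
fake_result <- function(depth, mu_auto, mu_het = NA_real_, mu_obs = NA_real_,
                        noon_par = 600 * exp(-0.045 * depth),
                        cell_density = NA_real_) {
  n <- length(depth)
  structure(
    data.frame(depth = depth, noon_par = noon_par,
               v_c_auto = mu_auto, v_c_auto_raw = mu_auto,
               chl_to_c = NA_real_, v_n = Inf, v_p = Inf, v_fe = NA_real_,
               mu_auto = mu_auto, limiter = "light",
               mu_observed = rep_len(mu_obs, n),
               mu_het = rep_len(mu_het, n),
               cell_density = rep_len(cell_density, n)),
    scenario = "test", has_fe = FALSE,
    class = c("growth_profile_result", "data.frame"))
}

# tiny IBM config for fast step-level tests
tiny_ibm_config <- function(...) {
  ibm_config(depth_max = 40, dz = 2, n_super_agents = 100,
             init_density = 1e10, n_days = 1, ...)
}
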