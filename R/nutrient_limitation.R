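#' Nutrient-uptake parameters
#'
#' Maximum uptake rates, half-saturations and cell quotas for fixed
#' nitrogen and phosphate (saturating Michaelis-Menten kinetics) and the
#' surface-area-scaled linear rate constant for dissolved iron. Defaults
#' follow empirical allometric scalings for a *Prochlorococcus*-sized cell
#' (~0.6 um diameter) and are plain config entries intended to be replaced
#' by literature values where available.
#'
#' @param vmax_n Maximum N uptake, mol N cell^-1 day^-1.
#' @param k_n N half-saturation, mol N m^-3.
#' @param q_n N cell quota, mol N cell^-1.
#' @param vmax_p Maximum P uptake, mol P cell^-1 day^-1.
#' @param k_p P half-saturation, mol P m^-3.
#' @param q_p P cell quota, mol P cell^-1.
#' @param k_fe_sa Iron uptake rate constant per unit cell surface area,
#'   mol Fe um^-2 day^-1 per (nmol Fe l^-1).
#' @param surface_area Cell surface area, um^2.
#' @param q_fe Iron cell quota, mol Fe cell^-1.
#' @param fe_detection_limit Substitution value for below-detection iron
#'   concentrations, nmol l^-1.
#' @return An object of class `nutrient_uptake_params`.
#' @export
nutrient_uptake_params <- function(vmax_n = 3.2e-16, k_n = 1e-5, q_n = 4e-16,
                                   vmax_p = 2.5e-17, k_p = 5e-6, q_p = 2.5e-17,
                                   k_fe_sa = 3e-18, surface_area = 1.13,
                                   q_fe = 2e-19, fe_detection_limit = 0.03) {
  vals <- c(vmax_n = vmax_n, k_n = k_n, q_n = q_n, vmax_p = vmax_p,
            k_p = k_p, q_p = q_p, k_fe_sa = k_fe_sa,
            surface_area = surface_area, q_fe = q_fe,
            fe_detection_limit = fe_detection_limit)
  if (any(vals <= 0)) {
    stop("all nutrient-uptake parameters must be > 0; offending: ",
         paste(names(vals)[vals <= 0], collapse = ", "))
  }
  structure(as.list(vals), class = "nutrient_uptake_params")
}

#' Nutrient-specific uptake rate (Michaelis-Menten)
#'
#' Quota-normalised saturating uptake
#' `(vmax / quota) * conc / (conc + half_sat)`, used for both fixed
#' nitrogen and phosphate. The value lies in `[0, vmax/quota)` and is
#' concave and monotone non-decreasing in concentration.
#'
#' @param concentration Ambient concentration, mol m^-3 (vectorised, >= 0).
#' @param vmax Maximum uptake rate, mol cell^-1 day^-1 (> 0).
#' @param half_sat Half-saturation concentration, mol m^-3 (> 0).
#' @param quota Cell quota, mol cell^-1 (> 0).
#' @return Specific uptake (growth) rate, day^-1.
#' @export
michaelis_specific_rate <- function(concentration, vmax, half_sat, quota) {
  if (any(concentration < 0)) stop("`concentration` must be >= 0")
  if (vmax <= 0 || half_sat <= 0 || quota <= 0) {
    stop("`vmax`, `half_sat` and `quota` must be > 0")
  }
  (vmax / quota) * concentration / (concentration + half_sat)
}

#' Iron-specific uptake rate (linear in concentration and surface area)
#'
#' Dissolved-iron uptake modelled as a linear function of cell surface
#' area: `k_fe_sa * surface_area * fe / q_fe`. Below-detection iron values
#' are expected to be substituted with the detection limit upstream (see
#' [read_profile_table()]).
#'
#' @param fe_concentration Dissolved iron, nmol l^-1 (vectorised, >= 0).
#' @param params A [nutrient_uptake_params()] object.
#' @return Specific uptake (growth) rate, day^-1.
#' @export
iron_specific_rate <- function(fe_concentration, params) {
  stopifnot(inherits(params, "nutrient_uptake_params"))
  if (any(fe_concentration < 0)) stop("`fe_concentration` must be >= 0")
  params$k_fe_sa * params$surface_area * fe_concentration / params$q_fe
}
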