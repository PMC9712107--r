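#' Photic depth for a growth-supporting light threshold
#'
#' Depth at which exponentially attenuated PAR falls to the threshold that
#' supports laboratory growth of a representative strain:
#' `log(surface_par / threshold) / k_d`, or 0 when the surface value is
#' already at or below the threshold. Default thresholds are
#' 10 umol photons m^-2 s^-1 for high-light-adapted strains and
#' 2.8 umol photons m^-2 s^-1 for low-light-adapted strains.
#'
#' @param surface_par Surface noon PAR (> 0, vectorised).
#' @param k_d Diffuse attenuation coefficient, m^-1 (> 0).
#' @param threshold Growth-supporting light threshold (> 0).
#' @return Photic depth, m.
#' @export
photic_depth <- function(surface_par, k_d, threshold = 10) {
  if (any(k_d <= 0)) stop("`k_d` must be > 0")
  if (any(surface_par <= 0) || any(threshold <= 0)) {
    stop("`surface_par` and `threshold` must be > 0")
  }
  pmax(0, log(surface_par / threshold) / k_d)
}

#' Stratification mask from mixed-layer and photic depths
#'
#' A date is stratified exactly when the mixed layer is shallower than the
#' photic depth; only stratified dates enter the below-photic-depth cell
#' fractions (at other times cells below the photic depth may be mixed up
#' into the light).
#'
#' @param mld_series Mixed-layer depth per date, m.
#' @param photic_depth_series Photic depth per date, m (same length).
#' @return Logical vector, `TRUE` where stratified.
#' @export
stratified_mask <- function(mld_series, photic_depth_series) {
  if (length(mld_series) != length(photic_depth_series)) {
    stop("series lengths differ")
  }
  mld_series < photic_depth_series
}

#' Fraction of column-integrated cells below the photic depth
#'
#' Trapezoidal column integrals of a cell-concentration profile above and
#' below the photic depth, with the straddling layer split linearly.
#' Returns a percentage of the total column inventory.
#'
#' @param depth Depth grid, m, increasing.
#' @param concentration Cells m^-3 per depth (non-negative).
#' @param pd Photic depth, m.
#' @return Percentage in `[0, 100]`, or `NA` when the column holds no
#'   cells.
#' @export
fraction_below_photic <- function(depth, concentration, pd) {
  stopifnot(length(depth) == length(concentration))
  if (any(diff(depth) <= 0)) stop("`depth` must be strictly increasing")
  if (any(concentration < 0)) stop("`concentration` must be >= 0")
  total <- trapz(depth, concentration)
  if (total <= 0) return(NA_real_)
  if (pd <= depth[1]) return(100)
  if (pd >= depth[length(depth)]) return(0)
  c_pd <- approx(depth, concentration, xout = pd)$y
  keep <- depth > pd
  below <- trapz(c(pd, depth[keep]), c(c_pd, concentration[keep]))
  100 * below / total
}

#' Mean below-photic fraction over stratified dates
#'
#' Arithmetic mean (dates weighted equally) and maximum of the
#' below-photic-depth cell fractions restricted to stratified dates.
#'
#' @param fractions Per-date percentages (may contain `NA`).
#' @param mask Logical stratification mask from [stratified_mask()].
#' @return List with `mean`, `max` and `n_dates`.
#' @export
stratified_mean_fraction <- function(fractions, mask) {
  stopifnot(length(fractions) == length(mask))
  if (!any(mask)) stop("no stratified dates")
  f <- fractions[mask]
  f <- f[!is.na(f)]
  if (length(f) == 0L) stop("no stratified dates with defined fractions")
  list(mean = mean(f), max = max(f), n_dates = length(f))
}

#' Ecotype time series container
#'
#' Aligns a seasonal forcing series (mixed-layer depth, surface noon PAR,
#' attenuation coefficient) with per-ecotype cell-concentration profiles
#' and per-ecotype light thresholds.
#'
#' @param dates Date (or numeric) vector.
#' @param mld Mixed-layer depth per date, m (> 0).
#' @param surface_par Surface noon PAR per date.
#' @param k_d Attenuation coefficient, m^-1 (scalar or per date).
#' @param depth Common depth grid of the profiles, m.
#' @param profiles Named list of ecotypes; each element a matrix
#'   (depth x date) of cell concentrations.
#' @param thresholds Named numeric vector of light thresholds per ecotype,
#'   umol photons m^-2 s^-1 (defaults: 10 for HL-named, 2.8 for LL-named
#'   ecotypes).
#' @return An object of class `ecotype_timeseries`.
#' @export
ecotype_timeseries <- function(dates, mld, surface_par, k_d, depth, profiles,
                               thresholds = NULL) {
  nt <- length(dates)
  stopifnot(length(mld) == nt, length(surface_par) == nt)
  if (any(mld <= 0)) stop("MLD must be > 0")
  k_d <- rep_len(k_d, nt)
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  for (nm in names(profiles)) {
    p <- profiles[[nm]]
    if (!is.matrix(p) || nrow(p) != length(depth) || ncol(p) != nt) {
      stop("profile for ", nm, " must be a depth x date matrix")
    }
    if (any(p < 0)) stop("profiles must be non-negative")
  }
  if (is.null(thresholds)) {
    thresholds <- ifelse(grepl("^HL", names(profiles)), 10, 2.8)
    names(thresholds) <- names(profiles)
  }
  if (any(thresholds <= 0)) stop("thresholds must be > 0")
  structure(list(dates = dates, mld = mld, surface_par = surface_par,
                 k_d = k_d, depth = depth, profiles = profiles,
                 thresholds = thresholds),
            class = "ecotype_timeseries")
}

#' Below-photic-depth cell fractions over an ecotype time series
#'
#' For every date and every ecotype, computes the photic depth from that
#' ecotype's own light threshold, the fraction of the ecotype's cells below
#' it, and the total-population fraction below the high-light photic depth;
#' applies the stratification mask and summarises stratified dates.
#'
#' @param ts An [ecotype_timeseries()].
#' @param total_threshold Threshold used for the total-population photic
#'   depth (default 10, the high-light strain threshold).
#' @return A list: `per_date` (data frame with date, mld, photic depths,
#'   stratification flag and per-ecotype fractions), and `summary` (list
#'   per ecotype plus `"total"` with stratified mean/max).
#' @export
analyze_ecotype_timeseries <- function(ts, total_threshold = 10) {
  stopifnot(inherits(ts, "ecotype_timeseries"))
  nt <- length(ts$dates)
  eco <- names(ts$profiles)
  pd_total <- photic_depth(ts$surface_par, ts$k_d, total_threshold)
  strat <- stratified_mask(ts$mld, pd_total)
  total_profile <- Reduce(`+`, ts$profiles)
  frac_total <- vapply(seq_len(nt), function(i) {
    fraction_below_photic(ts$depth, total_profile[, i], pd_total[i])
  }, numeric(1))
  per_date <- data.frame(date = ts$dates, mld = ts$mld,
                         photic_depth_total = pd_total,
                         stratified = strat, frac_total = frac_total)
  summary <- list(total = stratified_mean_fraction(frac_total, strat))
  for (e in eco) {
    pd_e <- photic_depth(ts$surface_par, ts$k_d, ts$thresholds[[e]])
    frac_e <- vapply(seq_len(nt), function(i) {
      fraction_below_photic(ts$depth, ts$profiles[[e]][, i], pd_e[i])
    }, numeric(1))
    per_date[[paste0("photic_depth_", e)]] <- pd_e
    per_date[[paste0("frac_", e)]] <- frac_e
    summary[[e]] <- stratified_mean_fraction(frac_e, strat)
  }
  list(per_date = per_date, summary = summary)
}
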