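#' Default analysis configuration
#'
#' The package's parameter presets as one nested list: photo-physiology
#' presets for high-light- and low-light-adapted ecotypes (Platt
#' coefficients), the contracted macromolecular-allocation coefficients,
#' nutrient-uptake parameters, and the per-cell carbon quota used for
#' vertical integration. Values are plain config entries, editable and
#' persistable as YAML via [write_config()] / [read_config()]; the
#' photo-physiology numbers are package calibrations (surface growth of
#' the high-light preset in 0.4-0.6 day^-1, light-limited growth vanishing
#' near 1-2% of surface PAR), intended to be replaced with laboratory
#' values by users who have them.
#'
#' @return Nested named list with blocks `photophys` (`HL`, `LL`),
#'   `allocation`, `nutrients` and `integration`.
#' @export
default_config <- function() {
  list(
    photophys = list(
      HL = list(ps_chl = 0.05, alpha_chl = 1e-3, beta_chl = 2e-5),
      LL = list(ps_chl = 0.03, alpha_chl = 2e-3, beta_chl = 1.5e-4)
    ),
    allocation = list(a0 = 4e-4, a1 = 1.5e-3, a2 = 1.2e-3,
                      mu_hat = 0.6, k_i = 25, k_r = 0.05),
    nutrients = list(vmax_n = 3.2e-16, k_n = 1e-5, q_n = 4e-16,
                     vmax_p = 2.5e-17, k_p = 5e-6, q_p = 2.5e-17,
                     k_fe_sa = 3e-18, surface_area = 1.13, q_fe = 2e-19,
                     fe_detection_limit = 0.03),
    integration = list(carbon_quota = 50e-15)
  )
}

#' Read / write a configuration file (YAML)
#'
#' @param path File path.
#' @param config Nested configuration list (see [default_config()]).
#' @return `read_config()` returns the nested list; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Read a depth-profile table from CSV
#'
#' Expects a comma-delimited, UTF-8, headered table with one row per
#' depth and columns `depth_m`, `par_noon`, `din`, `po4` (required) and
#' `fe`, `cells_per_m3`, `mu_obs` (optional). Below-detection iron values
#' written as tokens like `"<0.03"` are substituted with the detection
#' limit (with a message); rows are sorted by depth and duplicate depths
#' are an error.
#'
#' @param path CSV file path.
#' @param fe_detection_limit Substitution value for below-detection iron,
#'   nmol l^-1.
#' @param latitude,day_of_year Passed to [environment_profile()].
#' @return An [environment_profile()].
#' @export
read_profile_table <- function(path, fe_detection_limit = 0.03,
                               latitude = 22.75, day_of_year = 196) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("depth_m", "par_noon", "din", "po4")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$depth_m)) {
    stop("duplicate depth_m rows: ",
         paste(unique(df$depth_m[duplicated(df$depth_m)]), collapse = ", "))
  }
  df <- df[order(df$depth_m), , drop = FALSE]
  fe <- NULL
  if ("fe" %in% names(df)) {
    fe_raw <- as.character(df$fe)
    below <- grepl("^\\s*<", fe_raw)
    fe <- suppressWarnings(as.numeric(fe_raw))
    if (any(below)) {
      message(sum(below), " below-detection iron value(s) substituted with ",
              fe_detection_limit, " nmol l^-1")
      fe[below] <- fe_detection_limit
    }
    if (any(is.na(fe))) stop("unparseable values in column fe")
    fe <- pmax(fe, fe_detection_limit)
  }
  environment_profile(
    depth = df$depth_m, noon_par = df$par_noon, din = df$din, po4 = df$po4,
    fe = fe,
    cell_density = if ("cells_per_m3" %in% names(df)) df$cells_per_m3 else NULL,
    observed_growth = if ("mu_obs" %in% names(df)) df$mu_obs else NULL,
    latitude = latitude, day_of_year = day_of_year)
}

#' Write a growth-profile result (CSV) and its summary (JSON)
#'
#' The per-depth table goes to `<path>.csv`; if `summary` is supplied
#' (e.g. the output of [integrate_production()] plus scenario metadata)
#' it goes to `<path>.json`. A run manifest listing every written file is
#' written alongside as `<path>_manifest.json`.
#'
#' @param result A `growth_profile_result` (or any data frame).
#' @param path Output path stem (no extension).
#' @param summary Optional list serialised as JSON.
#' @param seed Seed(s) recorded in the manifest.
#' @return Invisibly, the character vector of files written.
#' @export
write_growth_results <- function(result, path, summary = NULL, seed = NA) {
  csv <- paste0(path, ".csv")
  write.csv(as.data.frame(result), csv, row.names = FALSE)
  files <- csv
  if (!is.null(summary)) {
    js <- paste0(path, ".json")
    jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA,
                         na = "null")
    files <- c(files, js)
  }
  manifest <- paste0(path, "_manifest.json")
  write_run_manifest(manifest, command = "write_growth_results",
                     seed = seed, outputs = files)
  invisible(c(files, manifest))
}

#' Read back a growth-profile CSV
#'
#' @param path Path to a CSV written by [write_growth_results()].
#' @param scenario Scenario label to restore as attribute.
#' @return A `growth_profile_result` data frame.
#' @export
read_growth_results <- function(path, scenario = "") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  structure(df, scenario = scenario,
            class = c("growth_profile_result", "data.frame"))
}

# stable order-dependent content hash (FNV-1a over the serialized object)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Write a run manifest
#'
#' Records the command, a content hash of the configuration, the seed(s),
#' the package version, a timestamp and the list of output files, as
#' JSON. Every writer in the package emits exactly one manifest per
#' invocation so a run can be reproduced from its metadata.
#'
#' @param path Manifest file path.
#' @param command Free-text command/stage name.
#' @param seed Seed(s) used.
#' @param config Optional configuration list (hashed into the manifest).
#' @param outputs Character vector of files written.
#' @return Invisibly, `path`.
#' @export
write_run_manifest <- function(path, command, seed = NA, config = NULL,
                               outputs = character()) {
  manifest <- list(
    command = command,
    config_hash = if (is.null(config)) NA else config_hash(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("mixopro")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       na = "null")
  invisible(path)
}
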