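#' Default NCPT-style site table
#'
#' Coordinates of the trial and selection locations used by the US National
#' Chip Processing Trial, with the nearest weather-station coordinates.
#' Sites that act as both a breeding program's selection site and a trial
#' location are listed first (with the trial-site coordinates), followed by
#' trial-only and selection-only sites.
#'
#' @return A tibble with one row per site: `site_id`, `nearest_city`,
#'   `is_selection`, `is_trial`, `latitude`, `longitude`, `station_latitude`,
#'   `station_longitude` (degrees).
#' @export
ncpt_site_table <- function() {
  tibble::tribble(
    ~site_id, ~nearest_city, ~is_selection, ~is_trial, ~latitude, ~longitude, ~station_latitude, ~station_longitude,
    "WI", "Hancock",            TRUE,  TRUE, 44.12,  -89.54, 44.12,  -89.54,
    "MI", "Lakeview",           TRUE,  TRUE, 43.35,  -85.17, 42.88,  -85.52,
    "NC", "Plymouth",           TRUE,  TRUE, 35.87,  -76.65, 35.85,  -77.03,
    "ND", "Hoople",             TRUE,  TRUE, 48.53,  -97.62, 47.95,  -97.18,
    "NY", "Ithaca",             TRUE,  TRUE, 42.43,  -76.39, 42.49,  -76.46,
    "OR", "Hermiston",          TRUE,  TRUE, 45.81, -119.28, 45.83, -119.26,
    "TX", "Dalhart",            TRUE,  TRUE, 35.97, -102.73, 36.02, -102.55,
    "CA", "Bakersfield",        FALSE, TRUE, 35.26, -118.88, 35.43, -119.06,
    "FL", "Hastings",           FALSE, TRUE, 29.68,  -81.43, 29.77,  -81.47,
    "MO", "Charleston",         FALSE, TRUE, 36.93,  -89.38, 37.23,  -89.58,
    "CO", "San Luis Valley",    TRUE,  FALSE, 37.71, -106.14, 37.69, -106.31,
    "ID", "Aberdeen",           TRUE,  FALSE, 42.95, -112.83, 43.86, -111.28,
    "ME", "Presque Isle",       TRUE,  FALSE, 46.65,  -68.01, 46.68,  -68.05
  )
}

#' Simulate breeding-program and trial sites
#'
#' Returns a table of sites with coordinates, a growing-season window and
#' daily-climate parameters.  The first `n_sites` rows of
#' [ncpt_site_table()] are used by default; requesting more sites than the
#' default table holds generates additional synthetic sites by jittering
#' existing coordinates (seeded, hence reproducible).  Climate parameters
#' follow a simple latitudinal gradient: cooler and later seasons farther
#' north.
#'
#' @param n_sites Number of sites (>= 2).
#' @param seed Integer seed; the output is deterministic given the seed.
#' @param sites Optional site table overriding [ncpt_site_table()].
#' @return A tibble of `SiteDef` rows: site identity and roles, coordinates,
#'   `season_start`/`season_end` (day of year, inclusive), and climate
#'   parameters `tmax_mean`, `tmax_sd`, `tmin_mean`, `tmin_sd` (deg C),
#'   `precip_mean`, `precip_sd` (cm/day).
#' @export
simulate_programs <- function(n_sites = 10, seed = 1, sites = ncpt_site_table()) {
  if (!is.numeric(n_sites) || length(n_sites) != 1 || n_sites < 2) {
    abort("`n_sites` must be a single number >= 2.", class = "envgxe_config_error")
  }
  n_sites <- as.integer(n_sites)
  base <- sites
  if (n_sites > nrow(base)) {
    extra_n <- n_sites - nrow(base)
    set.seed(seed)
    idx <- sample.int(nrow(base), extra_n, replace = TRUE)
    extra <- base[idx, ]
    extra$site_id <- sprintf("S%02d", seq_len(extra_n))
    extra$latitude <- pmin(90, pmax(-90, extra$latitude + rnorm(extra_n, 0, 1.5)))
    extra$longitude <- pmin(180, pmax(-180, extra$longitude + rnorm(extra_n, 0, 3)))
    extra$is_selection <- TRUE
    extra$is_trial <- TRUE
    base <- dplyr::bind_rows(base, extra)
  }
  out <- base[seq_len(n_sites), ]
  if (sum(out$is_selection) < 1 || sum(out$is_trial) < 2) {
    abort("Site set must contain at least one selection site and two trial sites.",
          class = "envgxe_config_error")
  }
  lat <- out$latitude
  out$season_start <- as.integer(round(105 + 0.8 * lat)) # later start farther north
  out$season_end <- out$season_start + 130L
  out$tmax_mean <- 32 - 0.35 * (lat - 30)
  out$tmax_sd <- 4
  out$tmin_mean <- out$tmax_mean - 13
  out$tmin_sd <- 4
  # wetter toward the east coast, drier toward the interior west
  out$precip_mean <- pmax(0.05, 0.25 + 0.004 * (out$longitude + 95))
  out$precip_sd <- 0.45
  stopifnot(all(out$season_start < out$season_end))
  out
}
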