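#' Extract the numeric dosage matrix from a dosage table
#'
#' Dosage tables are tibbles mirroring the genotype CSV layout: columns
#' `Marker`, `Chrom`, `Position`, then one 0-4 integer column per clone.
#'
#' @param dosage A dosage tibble.
#' @return Integer matrix, markers in rows (rownames = marker ids), clones in
#'   columns.
#' @export
dosage_matrix <- function(dosage) {
  check_dosage(dosage)
  m <- as.matrix(dosage[, setdiff(names(dosage), c("Marker", "Chrom", "Position"))])
  rownames(m) <- dosage$Marker
  storage.mode(m) <- "double"
  m
}

#' @rdname dosage_matrix
#' @return `marker_map()`: tibble with `Marker`, `Chrom`, `Position`.
#' @export
marker_map <- function(dosage) {
  check_dosage(dosage)
  dosage[, c("Marker", "Chrom", "Position")]
}

#' @rdname dosage_matrix
#' @export
clone_ids <- function(dosage) {
  check_dosage(dosage)
  setdiff(names(dosage), c("Marker", "Chrom", "Position"))
}

check_dosage <- function(dosage) {
  if (!is.data.frame(dosage) ||
      !all(c("Marker", "Chrom", "Position") %in% names(dosage))) {
    abort("Expected a dosage table with columns Marker, Chrom, Position and one column per clone.",
          class = "envgxe_data_error")
  }
  if (anyDuplicated(dosage$Marker)) {
    abort("Duplicate marker ids in dosage table.", class = "envgxe_data_error")
  }
  invisible(dosage)
}

#' Ground truth for a simulated trial
#'
#' Collects the parameters used by [simulate_genotypes()],
#' [simulate_yields()] and [simulate_submission_years()]: planted
#' environmental-cline QTL, reaction-norm slope QTL, generation-trend QTL,
#' the variance components of the yield model
#' (yield = mu + Y + L + YL + g + gY + gL + gYL + e) and its fixed effects.
#'
#' @param variance_components Named numeric: `g`, `gY`, `gL`, `gYL`, `e`
#'   (kg^2 per plot). Defaults mirror the genetic-variance split reported
#'   for national chip trial yield (27.6 / 5.56 / 22.7 / 34.1 percent of
#'   genetic variance for g / gY / gL / gYL) with residual noise of
#'   comparable size.
#' @param mu Grand mean plot yield, kg.
#' @param year_effects,loc_effects,yl_effects Optional named numeric vectors
#'   (names = year, location, "location:year").  If omitted they are derived
#'   deterministically inside [simulate_yields()]: location effects spread so
#'   per-trial means differ several-fold, small year and year-by-location
#'   effects.
#' @param env_qtl Tibble `marker`, `variable`, `strength`: allele-frequency
#'   cline per standardized unit of the program-level environmental variable.
#' @param slope_qtl Tibble `marker`, `variable`, `beta`: per-dosage-copy
#'   reaction-norm slope on the normalized log-yield scale, per unit of the
#'   trial environmental variable.
#' @param gpsm_qtl Tibble `marker`, `delta`: allele-frequency change per
#'   submission year.
#' @return A list of class `sim_truth`.
#' @export
sim_truth <- function(variance_components = c(g = 2.76, gY = 0.556, gL = 2.27, gYL = 3.41, e = 6),
                      mu = 20,
                      year_effects = NULL, loc_effects = NULL, yl_effects = NULL,
                      env_qtl = NULL, slope_qtl = NULL, gpsm_qtl = NULL) {
  vc <- variance_components
  needed <- c("g", "gY", "gL", "gYL", "e")
  if (!all(needed %in% names(vc))) {
    abort("variance_components must name g, gY, gL, gYL and e.",
          class = "envgxe_config_error")
  }
  if (any(vc[needed] < 0)) {
    abort("Variance components must be non-negative.", class = "envgxe_config_error")
  }
  structure(
    list(variance_components = vc[needed], mu = mu,
         year_effects = year_effects, loc_effects = loc_effects,
         yl_effects = yl_effects,
         env_qtl = env_qtl, slope_qtl = slope_qtl, gpsm_qtl = gpsm_qtl),
    class = "sim_truth"
  )
}

# Program-level value of an environmental variable, used to build clines.
program_env_value <- function(sites, variable) {
  switch(variable,
    latitude = sites$latitude,
    longitude = sites$longitude,
    minTemp_sel = , minTemp = sites$tmin_mean,
    maxTemp_sel = , maxTemp = sites$tmax_mean,
    precip_sel = , precip = sites$precip_mean * (sites$season_end - sites$season_start + 1),
    abort(paste0("Unknown environmental variable `", variable, "`."),
          class = "envgxe_config_error")
  )
}

#' Simulate tetraploid genotypes with optional environmental clines
#'
#' Draws autotetraploid dosages as Binomial(4, p) per marker and clone
#' (autotetraploid Hardy-Weinberg).  Neutral markers share one base allele
#' frequency across programs; env-QTL markers get a per-program frequency
#' p = p0 + strength * z, where z is the standardized program-level value of
#' the named environmental variable (a linear cline).  Frequencies are
#' clipped to [0.005, 0.995]; markers whose realized frequency falls outside
#' that band are redrawn so every emitted marker is polymorphic.
#'
#' @param n_clones,n_markers Panel dimensions.
#' @param sites Site table from [simulate_programs()]; clones are assigned
#'   uniformly at random to its selection sites.
#' @param env_qtl Tibble `marker` (index into 1..n_markers), `variable`,
#'   `strength`; may be NULL.
#' @param n_chrom Number of chromosomes markers are spread over.
#' @param chrom_length Chromosome length in bp for uniform marker placement.
#' @param p0 Optional vector of base allele frequencies (length `n_markers`
#'   or recycled); by default drawn from a U-shaped Beta(0.8, 0.8) spectrum.
#' @param seed Integer seed.
#' @return List: `dosage` (dosage tibble), `truth` (a [sim_truth()] with
#'   `env_qtl` resolved to marker ids and base frequencies recorded),
#'   `clone_programs` (tibble `clone`, `program`).
#' @export
simulate_genotypes <- function(n_clones, n_markers, sites, env_qtl = NULL,
                               n_chrom = 12, chrom_length = 6e7, p0 = NULL,
                               seed = 1) {
  if (!is.null(env_qtl) && n_markers < nrow(env_qtl)) {
    abort("Fewer markers than requested QTL.", class = "envgxe_config_error")
  }
  sel <- sites[sites$is_selection, ]
  if (nrow(sel) < 1) abort("No selection sites.", class = "envgxe_config_error")
  set.seed(seed)

  clones <- sprintf("C%04d", seq_len(n_clones))
  program <- sample(sel$site_id, n_clones, replace = TRUE)

  # genomic map: contiguous blocks per chromosome, sorted positions
  chrom <- sort(rep_len(sprintf("chr%02d", seq_len(n_chrom)), n_markers))
  pos <- unlist(lapply(split(seq_len(n_markers), chrom), function(ix) {
    sort(sample.int(chrom_length, length(ix)))
  }), use.names = FALSE)
  marker <- sprintf("M%05d", seq_len(n_markers))

  if (is.null(p0)) {
    p0 <- pmin(0.99, pmax(0.01, rbeta(n_markers, 0.8, 0.8)))
  } else {
    p0 <- rep_len(p0, n_markers)
  }

  # per-program frequency matrix for cline markers
  pmat <- matrix(rep(p0, each = nrow(sel)), nrow = nrow(sel))  # programs x markers
  rownames(pmat) <- sel$site_id
  if (!is.null(env_qtl) && nrow(env_qtl)) {
    for (i in seq_len(nrow(env_qtl))) {
      j <- env_qtl$marker[i]
      z <- program_env_value(sel, env_qtl$variable[i])
      # population-sd standardization: a two-program contrast maps to z = +/-1
      z <- (z - mean(z)) / sqrt(mean((z - mean(z))^2))
      pmat[, j] <- pmin(0.995, pmax(0.005, p0[j] + env_qtl$strength[i] * z))
    }
  }

  prog_idx <- match(program, sel$site_id)
  draw_marker <- function(j) rbinom(n_clones, 4L, pmat[prog_idx, j])
  G <- vapply(seq_len(n_markers), draw_marker, integer(n_clones))  # clones x markers

  # redraw markers whose realized frequency leaves the polymorphic band
  for (pass in 1:20) {
    f <- colMeans(G) / 4
    bad <- which(f < 0.005 | f > 0.995)
    if (!length(bad)) break
    for (j in bad) {
      pmat[, j] <- pmin(0.9, pmax(0.1, pmat[, j]))  # pull extreme frequencies inward
      G[, j] <- draw_marker(j)
    }
  }

  dosage <- dplyr::bind_cols(
    tibble::tibble(Marker = marker, Chrom = chrom, Position = pos),
    tibble::as_tibble(t(G), .name_repair = ~clones)
  )

  truth_env <- NULL
  if (!is.null(env_qtl) && nrow(env_qtl)) {
    truth_env <- tibble::tibble(
      marker = marker[env_qtl$marker],
      variable = env_qtl$variable,
      strength = env_qtl$strength,
      p0 = p0[env_qtl$marker]
    )
  }
  list(
    dosage = dosage,
    truth = sim_truth(env_qtl = truth_env),
    clone_programs = tibble::tibble(clone = clones, program = program)
  )
}

#' Simulate daily weather for a set of sites
#'
#' Independent daily draws around each site's climate parameters: normal
#' temperatures (days where the drawn minimum exceeds the maximum are
#' swapped so `tmax_c >= tmin_c` always holds) and gamma-distributed daily
#' precipitation matching the requested mean and sd.  A fraction of days can
#' be masked to NA to exercise station-fallback imputation.
#'
#' @param sites Site table from [simulate_programs()].
#' @param years Integer vector of calendar years.
#' @param seed Integer seed.
#' @param missing_frac Fraction of site-days whose values are set to NA.
#' @return Tibble `station`, `date`, `tmax_c`, `tmin_c`, `precip_cm`.
#' @export
simulate_weather <- function(sites, years, seed = 1, missing_frac = 0) {
  if (is.null(sites) || nrow(sites) == 0) {
    abort("Empty site list.", class = "envgxe_config_error")
  }
  if (length(years) == 0) abort("`years` must be non-empty.", class = "envgxe_config_error")
  set.seed(seed)
  rows <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    dates <- do.call(c, lapply(years, function(y) {
      seq(as.Date(sprintf("%d-01-01", y)), as.Date(sprintf("%d-12-31", y)), by = "day")
    }))
    n <- length(dates)
    tmax <- rnorm(n, s$tmax_mean, s$tmax_sd)
    tmin <- rnorm(n, s$tmin_mean, s$tmin_sd)
    swap <- tmin > tmax
    if (any(swap)) {
      tmp <- tmax[swap]; tmax[swap] <- tmin[swap]; tmin[swap] <- tmp
    }
    if (s$precip_sd > 0 && s$precip_mean > 0) {
      shape <- (s$precip_mean / s$precip_sd)^2
      precip <- rgamma(n, shape = shape, scale = s$precip_sd^2 / s$precip_mean)
    } else {
      precip <- rep(max(0, s$precip_mean), n)
    }
    tibble::tibble(station = s$site_id, date = dates,
                   tmax_c = tmax, tmin_c = tmin, precip_cm = precip)
  })
  if (missing_frac > 0) {
    mask <- runif(nrow(rows)) < missing_frac
    rows$tmax_c[mask] <- NA_real_
    rows$tmin_c[mask] <- NA_real_
    rows$precip_cm[mask] <- NA_real_
  }
  rows
}

#' Build a plot-level trial layout
#'
#' Assigns each clone to a contiguous window of trial years and to every
#' trial location in those years, with `n_reps` plots per clone-trial cell.
#'
#' @param clones Character vector of clone ids.
#' @param sites Site table; rows with `is_trial` define trial locations.
#' @param years Integer vector of trial years.
#' @param n_years_per_clone Number of consecutive years each clone is tested.
#' @param n_reps Plots per clone within a trial.
#' @param seed Integer seed.
#' @return Tibble `clone`, `location`, `year`, `rep`.
#' @export
simulate_trial_layout <- function(clones, sites, years, n_years_per_clone = 2,
                                  n_reps = 1, seed = 1) {
  trial_sites <- sites$site_id[sites$is_trial]
  if (length(trial_sites) < 2) abort("Need at least two trial locations.",
                                     class = "envgxe_config_error")
  n_years_per_clone <- min(n_years_per_clone, length(years))
  set.seed(seed)
  start <- sample.int(length(years) - n_years_per_clone + 1, length(clones), replace = TRUE)
  purrr::map_dfr(seq_along(clones), function(i) {
    yr <- years[start[i] + seq_len(n_years_per_clone) - 1]
    tidyr::expand_grid(clone = clones[i], location = trial_sites, year = yr,
                       rep = seq_len(n_reps))
  })
}

#' Simulate plot-level yields under the multi-environment trial model
#'
#' Yields follow yield = mu + Y + L + YL + g + gY + gL + gYL + e on the kg
#' scale, with independent normal genetic draws at the clone, clone-by-year,
#' clone-by-location and clone-by-trial levels.  Planted reaction-norm QTL
#' enter multiplicatively as exp(sum dosage * beta * centered E), so that
#' `beta` is exactly the per-dosage-copy slope of normalized log yield on
#' the trial environmental variable.  Yields below `floor_frac` of the trial
#' fixed-effect mean are truncated to that floor and flagged.
#'
#' @param dosage Dosage tibble (needed only when `truth$slope_qtl` is set).
#' @param truth A [sim_truth()].
#' @param trial_layout Tibble `clone`, `location`, `year` (from
#'   [simulate_trial_layout()] or user-built).
#' @param trial_env Tibble `location`, `year`, plus one column per
#'   environmental variable named in `truth$slope_qtl`.
#' @param seed Integer seed.
#' @param floor_frac Positivity floor as a fraction of the trial mean.
#' @param plot_area_ha Plot area written into the records (ha).
#' @return Tibble `clone`, `location`, `year`, `plot_yield_kg`,
#'   `plot_area_ha`, `floored`; attribute `n_floored` counts truncations.
#' @export
simulate_yields <- function(dosage, truth, trial_layout, trial_env = NULL,
                            seed = 1, floor_frac = 0.01, plot_area_ha = 0.0015) {
  stopifnot(inherits(truth, "sim_truth"))
  vc <- truth$variance_components
  if (any(vc < 0)) abort("Negative variance component.", class = "envgxe_config_error")
  lay <- trial_layout
  set.seed(seed)

  years <- sort(unique(lay$year))
  locs <- sort(unique(lay$location))
  clones <- sort(unique(lay$clone))

  ye <- truth$year_effects %||%
    setNames(rnorm(length(years), 0, 0.05 * truth$mu), years)
  le <- truth$loc_effects %||%
    setNames(seq(-0.55, 1.2, length.out = length(locs)) * truth$mu, locs)
  cells <- tidyr::expand_grid(location = locs, year = years)
  yle <- truth$yl_effects %||%
    setNames(rnorm(nrow(cells), 0, 0.03 * truth$mu),
             paste(cells$location, cells$year, sep = ":"))

  base <- truth$mu + ye[as.character(lay$year)] + le[lay$location] +
    yle[paste(lay$location, lay$year, sep = ":")]
  if (any(is.na(base))) abort("Fixed effects missing for some trials.",
                              class = "envgxe_config_error")

  g <- setNames(rnorm(length(clones), 0, sqrt(vc["g"])), clones)
  cy <- unique(paste(lay$clone, lay$year, sep = ":"))
  gy <- setNames(rnorm(length(cy), 0, sqrt(vc["gY"])), cy)
  cl <- unique(paste(lay$clone, lay$location, sep = ":"))
  gl <- setNames(rnorm(length(cl), 0, sqrt(vc["gL"])), cl)
  cyl <- unique(paste(lay$clone, lay$location, lay$year, sep = ":"))
  gyl <- setNames(rnorm(length(cyl), 0, sqrt(vc["gYL"])), cyl)

  lin <- base + g[lay$clone] +
    gy[paste(lay$clone, lay$year, sep = ":")] +
    gl[paste(lay$clone, lay$location, sep = ":")] +
    gyl[paste(lay$clone, lay$location, lay$year, sep = ":")] +
    rnorm(nrow(lay), 0, sqrt(vc["e"]))

  fac <- rep(1, nrow(lay))
  if (!is.null(truth$slope_qtl) && nrow(truth$slope_qtl)) {
    if (is.null(trial_env)) {
      abort("slope QTL planted but `trial_env` not supplied.",
            class = "envgxe_config_error")
    }
    G <- dosage_matrix(dosage)
    eta <- rep(0, nrow(lay))
    for (i in seq_len(nrow(truth$slope_qtl))) {
      q <- truth$slope_qtl[i, ]
      if (!q$variable %in% names(trial_env)) {
        abort(paste0("trial_env lacks variable `", q$variable, "`."),
              class = "envgxe_config_error")
      }
      ev <- trial_env[[q$variable]]
      ec <- ev - mean(ev)
      e_row <- ec[match(paste(lay$location, lay$year),
                        paste(trial_env$location, trial_env$year))]
      if (any(is.na(e_row))) abort("trial_env missing some trials.",
                                   class = "envgxe_config_error")
      d <- G[q$marker, lay$clone]
      eta <- eta + d * q$beta * e_row
    }
    fac <- exp(eta)
  }

  yield <- lin * fac
  floor_v <- floor_frac * base * fac
  floored <- yield < floor_v
  yield[floored] <- floor_v[floored]

  out <- tibble::tibble(
    clone = lay$clone, location = lay$location, year = lay$year,
    plot_yield_kg = as.numeric(yield), plot_area_ha = plot_area_ha,
    floored = floored
  )
  attr(out, "n_floored") <- sum(floored)
  out
}

#' Simulate submission years and generation-trend markers
#'
#' Assigns each clone a first submission year uniformly over `year_range`.
#' Markers listed in `gpsm_qtl` are redrawn with an allele frequency that
#' changes linearly in submission year, p(year) = p0 + delta * (year -
#' min(year)), clipped to [0.005, 0.995] (with a warning when clipping
#' occurs); all other markers are untouched, so they carry no systematic
#' frequency trend.
#'
#' @param dosage Dosage tibble.
#' @param gpsm_qtl Tibble `marker` (id or index), `delta` (frequency change
#'   per year); may be NULL.
#' @param year_range Integer vector of candidate submission years.
#' @param seed Integer seed.
#' @return List: `submission_years` (tibble `clone`, `submission_year`) and
#'   `dosage` (with trend markers resampled).
#' @export
simulate_submission_years <- function(dosage, gpsm_qtl = NULL,
                                      year_range = 2010:2022, seed = 1) {
  clones <- clone_ids(dosage)
  set.seed(seed)
  yrs <- sample(year_range, length(clones), replace = TRUE)
  if (!is.null(gpsm_qtl) && nrow(gpsm_qtl)) {
    G <- dosage_matrix(dosage)
    for (i in seq_len(nrow(gpsm_qtl))) {
      mk <- gpsm_qtl$marker[i]
      if (is.numeric(mk)) mk <- dosage$Marker[mk]
      j <- match(mk, dosage$Marker)
      if (is.na(j)) abort(paste0("GPSM marker `", mk, "` not in dosage table."),
                          class = "envgxe_config_error")
      p0 <- mean(G[j, ]) / 4
      p <- p0 + gpsm_qtl$delta[i] * (yrs - min(year_range))
      if (any(p < 0.005 | p > 0.995)) {
        warn(paste0("GPSM frequency trajectory for `", mk,
                    "` clipped to [0.005, 0.995]."))
        p <- pmin(0.995, pmax(0.005, p))
      }
      dosage[j, clones] <- as.list(rbinom(length(clones), 4L, p))
    }
  }
  list(
    submission_years = tibble::tibble(clone = clones, submission_year = yrs),
    dosage = dosage
  )
}
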