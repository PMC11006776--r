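#' Fill missing weather days from proximal fallback stations
#'
#' Completes a primary station's daily series using a list of fallback
#' station series ordered by proximity: each missing value (or wholly
#' missing day) is taken from the first fallback that has it.  Provenance is
#' recorded per day so imputed values can be audited.
#'
#' @param primary Daily weather tibble (`station`, `date`, `tmax_c`,
#'   `tmin_c`, `precip_cm`) for the primary station.
#' @param fallbacks List of daily weather tibbles, nearest first.
#' @param dates Optional vector of dates the completed series must cover;
#'   defaults to the range of dates present in `primary`.
#' @return Completed tibble with one row per requested day and a `source`
#'   column: `"primary"` or `"fallback <k>"` (per day; a day is attributed
#'   to the station that supplied any of its values).  Attribute
#'   `n_imputed` counts value-level imputations.
#' @export
impute_missing_days <- function(primary, fallbacks = list(), dates = NULL) {
  vars <- c("tmax_c", "tmin_c", "precip_cm")
  if (is.null(dates)) {
    dates <- seq(min(primary$date), max(primary$date), by = "day")
  }
  out <- tibble::tibble(date = as.Date(dates))
  out <- dplyr::left_join(out, primary[, c("date", vars)], by = "date")
  out$source <- "primary"
  n_imputed <- 0L
  for (k in seq_along(fallbacks)) {
    miss_rows <- which(rowSums(is.na(out[vars])) > 0)
    if (!length(miss_rows)) break
    fb <- fallbacks[[k]]
    idx <- match(out$date[miss_rows], fb$date)
    for (v in vars) {
      need <- is.na(out[[v]][miss_rows]) & !is.na(idx)
      repl <- fb[[v]][idx[need]]
      ok <- !is.na(repl)
      if (any(ok)) {
        rows <- miss_rows[need][ok]
        out[[v]][rows] <- repl[ok]
        out$source[rows] <- paste("fallback", k)
        n_imputed <- n_imputed + sum(ok)
      }
    }
  }
  still <- which(rowSums(is.na(out[vars])) > 0)
  if (length(still)) {
    abort(paste0("No station has data for: ",
                 paste(format(out$date[head(still, 5)]), collapse = ", "),
                 if (length(still) > 5) " ..." else ""),
          class = "envgxe_data_error")
  }
  station <- if (nrow(primary)) primary$station[1] else NA_character_
  out <- dplyr::mutate(out, station = station, .before = 1)
  attr(out, "n_imputed") <- n_imputed
  out
}

#' Growing-season weather summary for one site-year
#'
#' Seasonal maxTemp and minTemp are means of the daily maxima and minima
#' over the window; precipitation is the sum.  The window is given in days
#' of year and is inclusive of both endpoints.
#'
#' @param daily Completed daily weather tibble (see [impute_missing_days()]).
#' @param site Station id to summarize.
#' @param year Calendar year.
#' @param window Length-2 integer vector `(start_doy, end_doy)`.
#' @return One-row tibble: `site_id`, `year`, `maxTemp`, `minTemp` (deg C),
#'   `precip` (cm), `n_days_used`, `n_days_imputed`.
#' @export
season_summary <- function(daily, site, year, window) {
  if (length(window) != 2 || window[1] > window[2]) {
    abort("`window` must be (start_doy, end_doy) with start <= end.",
          class = "envgxe_config_error")
  }
  d <- daily[daily$station == site & as.integer(format(daily$date, "%Y")) == year, ]
  doy <- as.integer(format(d$date, "%j"))
  d <- d[doy >= window[1] & doy <= window[2], ]
  if (nrow(d) == 0) abort("Empty season window.", class = "envgxe_data_error")
  if (anyNA(d[c("tmax_c", "tmin_c", "precip_cm")])) {
    abort("Season window contains missing days; impute first.",
          class = "envgxe_data_error")
  }
  tibble::tibble(
    site_id = site, year = year,
    maxTemp = mean(d$tmax_c), minTemp = mean(d$tmin_c),
    precip = sum(d$precip_cm),
    n_days_used = nrow(d),
    n_days_imputed = if ("source" %in% names(d)) sum(d$source != "primary") else 0L
  )
}

#' Season summaries for many site-years
#'
#' Convenience wrapper applying [season_summary()] over every site-year in
#' a site table, using each site's own season window.
#'
#' @param daily Daily weather tibble.
#' @param sites Site table with `site_id`, `season_start`, `season_end`.
#' @param years Years to summarize.
#' @return Tibble of season summaries.
#' @export
season_summaries <- function(daily, sites, years) {
  purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    purrr::map_dfr(years, function(y) {
      season_summary(daily, sites$site_id[i], y,
                     c(sites$season_start[i], sites$season_end[i]))
    })
  })
}

#' Selection environment of each clone
#'
#' The selection environment is the mean of the growing-season summaries at
#' the clone's home (selection) site over the three years preceding its
#' first trial submission: submission_year - 3 .. submission_year - 1, the
#' years during which early phenotypic selection happened.
#'
#' @param clones Tibble `clone`, `program`, `submission_year`.
#' @param summaries Season-summary tibble from [season_summaries()].
#' @param sites Site table supplying home-site coordinates.
#' @return Tibble `clone`, `program`, `submission_year`, `minTemp_sel`,
#'   `maxTemp_sel`, `precip_sel`, `latitude`, `longitude`.
#' @export
selection_env <- function(clones, summaries, sites) {
  out <- purrr::map_dfr(seq_len(nrow(clones)), function(i) {
    cl <- clones[i, ]
    yrs <- (cl$submission_year - 3):(cl$submission_year - 1)
    s <- summaries[summaries$site_id == cl$program & summaries$year %in% yrs, ]
    if (nrow(s) != 3) {
      missing_yrs <- setdiff(yrs, s$year)
      abort(paste0("Clone ", cl$clone, ": missing season summaries for ",
                   cl$program, " ", paste(missing_yrs, collapse = ", ")),
            class = "envgxe_data_error")
    }
    tibble::tibble(
      clone = cl$clone, program = cl$program,
      submission_year = cl$submission_year,
      minTemp_sel = mean(s$minTemp), maxTemp_sel = mean(s$maxTemp),
      precip_sel = mean(s$precip)
    )
  })
  site_ix <- match(out$program, sites$site_id)
  out$latitude <- sites$latitude[site_ix]
  out$longitude <- sites$longitude[site_ix]
  out
}

#' Pairwise Pearson correlations between environmental variables
#'
#' Pairwise-complete Pearson correlations; zero-variance columns yield NA
#' entries and a warning rather than a silent 0.
#'
#' @param env Data frame of environmental variables (rows = sites or trials).
#' @param vars Columns to correlate; defaults to all numeric columns.
#' @return Correlation matrix with attribute `n`, the matrix of pairwise
#'   complete observation counts.
#' @export
env_correlations <- function(env, vars = NULL) {
  if (is.null(vars)) vars <- names(env)[vapply(env, is.numeric, logical(1))]
  x <- as.matrix(env[, vars, drop = FALSE])
  if (nrow(x) < 3) abort("Need at least 3 observations.", class = "envgxe_data_error")
  sds <- apply(x, 2, sd, na.rm = TRUE)
  degen <- names(sds)[!is.na(sds) & sds == 0]
  if (length(degen)) {
    warn(paste0("Zero-variance variable(s): ", paste(degen, collapse = ", "),
                "; correlations undefined (NA)."))
  }
  r <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  r[degen, ] <- NA_real_
  r[, degen] <- NA_real_
  diag(r) <- ifelse(colnames(r) %in% degen, NA_real_, 1)
  nmat <- crossprod(!is.na(x))
  attr(r, "n") <- nmat
  r
}
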