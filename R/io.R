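#' Read and write the package's CSV formats
#'
#' Genotype CSV: header `Marker,Chrom,Position` then one 0-4 dosage column
#' per clone.  Phenotype CSV: `clone,program,submission_year,location,year,
#' plot_yield_kg,plot_area_ha`.  Weather CSV: `station,date,tmax_c,tmin_c,
#' precip_cm`.  Truth JSON stores the generator's ground-truth parameters.
#'
#' @param path File path.
#' @param dosage,records,weather,truth Objects to write.
#' @return Readers return tibbles (the truth reader a list); writers return
#'   the input invisibly.
#' @name envgxe_io
NULL

#' @rdname envgxe_io
#' @export
read_dosage_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  check_dosage(d)
  d
}

#' @rdname envgxe_io
#' @export
write_dosage_csv <- function(dosage, path) {
  check_dosage(dosage)
  readr::write_csv(dosage, path)
  invisible(dosage)
}

#' @rdname envgxe_io
#' @export
read_phenotype_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    clone = readr::col_character(),
                    location = readr::col_character(),
                    .default = readr::col_guess()
                  ))
}

#' @rdname envgxe_io
#' @export
write_phenotype_csv <- function(records, path) {
  readr::write_csv(records, path)
  invisible(records)
}

#' @rdname envgxe_io
#' @export
read_weather_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    station = readr::col_character(),
                    date = readr::col_date(),
                    .default = readr::col_double()
                  ))
}

#' @rdname envgxe_io
#' @export
write_weather_csv <- function(weather, path) {
  readr::write_csv(weather, path)
  invisible(weather)
}

#' @rdname envgxe_io
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(truth)
}

#' @rdname envgxe_io
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  vc <- unlist(x$variance_components)
  sim_truth(
    variance_components = vc,
    mu = x$mu,
    year_effects = unlist(x$year_effects),
    loc_effects = unlist(x$loc_effects),
    yl_effects = unlist(x$yl_effects),
    env_qtl = if (!is.null(x$env_qtl)) tibble::as_tibble(x$env_qtl),
    slope_qtl = if (!is.null(x$slope_qtl)) tibble::as_tibble(x$slope_qtl),
    gpsm_qtl = if (!is.null(x$gpsm_qtl)) tibble::as_tibble(x$gpsm_qtl)
  )
}
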