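#' Analysis configuration
#'
#' Defaults mirror the study conditions: programs enter the case-control
#' envGWAS only if they contributed at least 10 percent of genotyped
#' clones; genome-wide alpha 0.05 adjusted for the effective marker count;
#' MAF filter 0.01; reaction-norm slopes need 3 distinct trial
#' environments; hit-overlap windows of 1, 2 and 5 Mb.
#'
#' @param program_fraction Inclusion fraction for case-control programs.
#' @param alpha Genome-wide significance level.
#' @param maf MAF threshold.
#' @param min_trials Minimum distinct environments per clone for slopes.
#' @param windows Overlap windows, bp.
#' @param seed Seed recorded with the configuration.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(program_fraction = 0.10, alpha = 0.05, maf = 0.01,
                            min_trials = 3, windows = c(1e6, 2e6, 5e6),
                            seed = 1) {
  if (program_fraction <= 0 || program_fraction >= 1) {
    abort("`program_fraction` must be in (0, 1).", class = "envgxe_config_error")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).",
                                      class = "envgxe_config_error")
  if (any(windows <= 0)) abort("`windows` must be positive.",
                               class = "envgxe_config_error")
  structure(list(program_fraction = program_fraction, alpha = alpha, maf = maf,
                 min_trials = min_trials, windows = windows, seed = seed),
            class = "analysis_config")
}

#' Programs eligible for the case-control envGWAS
#'
#' A program qualifies when it contributed at least
#' `ceiling(fraction * n_clones)` genotyped clones; with 840 clones and the
#' default 10 percent this reproduces the cutoff of 84.
#'
#' @param clone_programs Tibble `clone`, `program`.
#' @param fraction Inclusion fraction in (0, 1).
#' @return Tibble `program`, `n` for eligible programs (possibly empty),
#'   with attribute `cutoff`.
#' @export
eligible_programs <- function(clone_programs, fraction = 0.10) {
  if (fraction <= 0 || fraction >= 1) {
    abort("`fraction` must be in (0, 1).", class = "envgxe_config_error")
  }
  cutoff <- ceiling(fraction * nrow(clone_programs))
  counts <- dplyr::count(clone_programs, .data$program, name = "n")
  out <- counts[counts$n >= cutoff, ]
  if (nrow(out) == 0) inform("No program meets the inclusion cutoff.")
  attr(out, "cutoff") <- cutoff
  out
}

# Shared scan path: MAF-filtered dosage -> kinship null -> P3D scan ->
# Meff threshold -> significant set -> PVE by backward elimination.
run_scan <- function(dosage_f, response, K, thr, trait) {
  nf <- fit_null(response, K)
  scan <- score_markers(dosage_f, response, nf)
  scan <- apply_threshold(scan, thr)
  attr(scan, "trait") <- trait
  sig <- significant_markers(scan)
  pve <- NULL
  sig_tbl <- empty_sig_table()
  if (nrow(sig) > 0) {
    pve <- pve_backward_elimination(response, sig$Marker, dosage_f, nf)
    sig_tbl <- tibble::tibble(
      Trait = trait, Marker = sig$Marker, Chr = sig$Chrom,
      Position = sig$Position, LOD = sig$lod, Effect = sig$effect,
      PVE = pve$pve[match(sig$Marker, pve$Marker)]
    )
  }
  list(scan = scan, significant = sig_tbl, pve = pve, nullfit = nf)
}

empty_sig_table <- function() {
  tibble::tibble(Trait = character(), Marker = character(), Chr = character(),
                 Position = integer(), LOD = numeric(), Effect = numeric(),
                 PVE = numeric())
}

finish_analysis <- function(runs, kind, thr, config) {
  structure(
    list(kind = kind,
         scans = purrr::map(runs, "scan"),
         significant = dplyr::bind_rows(purrr::map(runs, "significant")),
         pve = purrr::map(runs, "pve"),
         m_eff = thr$m_eff, threshold = thr$threshold, config = config),
    class = "gwas_analysis"
  )
}

#' Environmental GWAS
#'
#' Reverse-regression scans where a descriptor of each clone's selection
#' environment is the response and allele dosage the regressor: discrete
#' home program (case-control, one scan per eligible program), latitude or
#' longitude of the selection site, or the 3-year selection-environment
#' averages of minTemp, maxTemp and precipitation.
#'
#' @param dosage Dosage tibble (genotyped clones, checks excluded).
#' @param response_kind One of `"program"`, `"latitude"`, `"longitude"`,
#'   `"minTemp_sel"`, `"maxTemp_sel"`, `"precip_sel"`.
#' @param clone_env Tibble from [selection_env()] (`clone`, `program`, and
#'   the environmental descriptor columns).
#' @param config An [analysis_config()].
#' @return Object of class `gwas_analysis`: thresholded scans, combined
#'   significant table (Trait, Marker, Chr, Position, LOD, Effect, PVE)
#'   and per-trait PVE reports.
#' @export
run_env_gwas <- function(dosage, response_kind, clone_env,
                         config = analysis_config()) {
  kinds <- c("program", "latitude", "longitude", "minTemp_sel", "maxTemp_sel",
             "precip_sel")
  response_kind <- match.arg(response_kind, kinds)
  dosage_f <- maf_filter(dosage, config$maf)
  keep <- intersect(clone_ids(dosage_f), clone_env$clone)
  dosage_f <- dosage_f[, c("Marker", "Chrom", "Position", keep)]
  clone_env <- clone_env[match(keep, clone_env$clone), ]
  K <- kinship(dosage_f)
  thr <- meff_threshold(dosage_f, config$alpha)

  if (response_kind == "program") {
    elig <- eligible_programs(clone_env[, c("clone", "program")],
                              config$program_fraction)
    runs <- purrr::map(elig$program, function(pr) {
      resp <- binary_response(clone_env[, c("clone", "program")], pr)
      run_scan(dosage_f, resp, K, thr, trait = pr)
    })
    names(runs) <- elig$program
  } else {
    v <- clone_env[[response_kind]]
    if (is.null(v)) abort(paste0("clone_env lacks `", response_kind, "`."),
                          class = "envgxe_data_error")
    resp <- tibble::tibble(clone = clone_env$clone, value = v)
    runs <- list(run_scan(dosage_f, resp, K, thr, trait = response_kind))
    names(runs) <- response_kind
  }
  finish_analysis(runs, paste0("envGWAS:", response_kind), thr, config)
}

#' Regression (reaction-norm slope) GWAS
#'
#' Scans the per-clone reaction-norm slope of normalized yield on a trial
#' environmental variable as a quantitative response, locating markers
#' that shift environmental sensitivity (GxE QTL).
#'
#' @param dosage Dosage tibble (checks and named varieties included).
#' @param slopes A [estimate_slopes()] table for one variable.
#' @param config An [analysis_config()].
#' @return A `gwas_analysis`.
#' @export
run_regression_gwas <- function(dosage, slopes, config = analysis_config()) {
  dosage_f <- maf_filter(dosage, config$maf)
  keep <- intersect(clone_ids(dosage_f), slopes$clone)
  if (length(keep) < 30) {
    abort(sprintf("Only %d clones with both slopes and genotypes (< 30).",
                  length(keep)), class = "envgxe_data_error")
  }
  dosage_f <- dosage_f[, c("Marker", "Chrom", "Position", keep)]
  slopes <- slopes[match(keep, slopes$clone), ]
  K <- kinship(dosage_f)
  thr <- meff_threshold(dosage_f, config$alpha)
  resp <- tibble::tibble(clone = slopes$clone, value = slopes$slope)
  trait <- paste0(slopes$variable[1], " slope")
  runs <- list(run_scan(dosage_f, resp, K, thr, trait = trait))
  names(runs) <- trait
  finish_analysis(runs, paste0("regressionGWAS:", slopes$variable[1]), thr, config)
}

#' Generation proxy selection mapping (GPSM)
#'
#' Scans the year a clone was first submitted to the trial (its generation
#' proxy) as a quantitative response under the kinship null, detecting
#' markers whose allele frequency changed directionally over the trial
#' period while accounting for relatedness.
#'
#' @param dosage Dosage tibble.
#' @param submission_years Tibble `clone`, `submission_year`.
#' @param config An [analysis_config()].
#' @return A `gwas_analysis`.
#' @export
run_gpsm <- function(dosage, submission_years, config = analysis_config()) {
  if (length(unique(submission_years$submission_year)) < 2) {
    abort("All clones share one submission year; GPSM needs response variance.",
          class = "envgxe_data_error")
  }
  dosage_f <- maf_filter(dosage, config$maf)
  keep <- intersect(clone_ids(dosage_f), submission_years$clone)
  dosage_f <- dosage_f[, c("Marker", "Chrom", "Position", keep)]
  sy <- submission_years[match(keep, submission_years$clone), ]
  K <- kinship(dosage_f)
  thr <- meff_threshold(dosage_f, config$alpha)
  resp <- tibble::tibble(clone = sy$clone, value = as.numeric(sy$submission_year))
  runs <- list(run_scan(dosage_f, resp, K, thr, trait = "submission year"))
  names(runs) <- "submission year"
  finish_analysis(runs, "GPSM", thr, config)
}

#' Convert a latitude effect size to kilometres
#'
#' A latitude effect of one degree per dosage copy corresponds to 111 km of
#' north-south displacement per copy (mean length of one degree of
#' latitude); an effect of 2 degrees means a copy of the alternative allele
#' is associated with a selection site 222 km farther north.  Longitude is
#' refused because the length of a degree of longitude varies with
#' latitude.
#'
#' @param effect_degrees Effect size in degrees.
#' @param axis Must be `"latitude"`.
#' @return Kilometres per dosage copy.
#' @export
effect_to_distance <- function(effect_degrees, axis = "latitude") {
  if (!identical(axis, "latitude")) {
    abort("Only latitude effects convert to a fixed distance; degree length along longitude varies with latitude.",
          class = "envgxe_config_error")
  }
  if (!all(is.finite(effect_degrees))) {
    abort("`effect_degrees` must be finite.", class = "envgxe_config_error")
  }
  effect_degrees * 111
}

#' Pairs of hits within a genomic window
#'
#' All cross-set pairs of markers on the same chromosome whose positions
#' differ by at most `window_bp` (inclusive at the boundary).  Used to ask
#' whether markers under directional selection (GPSM) coincide with the
#' envGWAS or regression-GWAS hits.
#'
#' @param hits_a,hits_b Tibbles with `Marker`, `Chr` (or `Chrom`) and
#'   `Position`.
#' @param window_bp Window size, bp.
#' @return Tibble `marker_a`, `marker_b`, `chrom`, `distance_bp`,
#'   `window_bp`.
#' @export
window_overlap <- function(hits_a, hits_b, window_bp) {
  std <- function(h) {
    chr <- h[["Chr"]] %||% h[["Chrom"]]
    tibble::tibble(marker = h$Marker, chrom = as.character(chr),
                   position = h$Position)
  }
  a <- std(hits_a); b <- std(hits_b)
  pairs <- dplyr::inner_join(a, b, by = "chrom", suffix = c("_a", "_b"),
                             relationship = "many-to-many")
  pairs$distance_bp <- abs(pairs$position_a - pairs$position_b)
  pairs <- pairs[pairs$distance_bp <= window_bp, ]
  tibble::tibble(marker_a = pairs$marker_a, marker_b = pairs$marker_b,
                 chrom = pairs$chrom, distance_bp = pairs$distance_bp,
                 window_bp = window_bp)
}

#' Round-and-sum cumulative PVE
#'
#' Cumulative percent variance explained as printed in result tables: the
#' per-marker PVE values summed and rounded to one decimal place.
#'
#' @param pve Numeric per-marker PVE values (percent).
#' @return Single number.
#' @export
cumulative_pve <- function(pve) round(sum(pve), 1)

#' Collect analyses into result tables
#'
#' Builds the combined significant-marker table (columns Trait, Marker,
#' Chr, Position, LOD Score, Effect, PVE), cumulative PVE per trait, and a
#' machine-readable summary; optionally writes per-analysis CSVs (including
#' full per-marker scans for Manhattan plotting) and a JSON summary.
#'
#' @param analyses Named list of `gwas_analysis` objects.
#' @param out_dir Optional output directory.
#' @return List: `significant` (tibble), `cumulative` (tibble `Trait`,
#'   `cumulative_pve`), `summary` (list).
#' @export
report_results <- function(analyses, out_dir = NULL) {
  if (length(analyses) == 0) abort("No completed analyses.", class = "envgxe_data_error")
  sig <- dplyr::bind_rows(purrr::map(analyses, "significant"))
  cum <- sig |>
    dplyr::group_by(.data$Trait) |>
    dplyr::summarise(cumulative_pve = cumulative_pve(.data$PVE), .groups = "drop")
  summary <- list(
    analyses = purrr::imap(analyses, function(a, nm) {
      list(kind = a$kind, m_eff = a$m_eff, threshold = a$threshold,
           n_significant = nrow(a$significant))
    })
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    sig_out <- dplyr::rename(sig, `LOD Score` = "LOD")
    readr::write_csv(sig_out, file.path(out_dir, "significant_markers.csv"))
    readr::write_csv(cum, file.path(out_dir, "cumulative_pve.csv"))
    purrr::iwalk(analyses, function(a, nm) {
      scans <- dplyr::bind_rows(purrr::imap(a$scans, function(s, tr) {
        dplyr::mutate(tibble::as_tibble(s), Trait = tr, .before = 1)
      }))
      readr::write_csv(scans, file.path(out_dir, paste0(nm, "_scan.csv")))
    })
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(significant = sig, cumulative = cum, summary = summary)
}
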