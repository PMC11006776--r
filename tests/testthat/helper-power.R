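# Replicate functions for the calibration / power suites.  Planted QTL get
# mid-range base frequencies (a cline or trend on a near-fixed allele is
# undetectable by construction); neutral markers keep the default spectrum.

spectrum_with_qtl <- function(n_markers, qtl_index, qtl_p0, seed) {
  set.seed(seed)
  p0 <- pmin(0.99, pmax(0.01, rbeta(n_markers, 0.8, 0.8)))
  p0[qtl_index] <- qtl_p0
  p0
}

# One null-calibration replicate: polygenic heritable response, no QTL.
null_scan_rep <- function(seed, n_clones = 300, n_markers = 2000) {
  g <- simulate_genotypes(n_clones, n_markers, default_sites, seed = seed)
  K <- kinship(g$dosage)
  resp <- sim_polygenic(K, h2 = 0.5, seed = seed + 1000000)
  nf <- fit_null(resp, K)
  sc <- score_markers(g$dosage, resp, nf)
  thr <- meff_threshold(g$dosage, 0.05)
  list(any_sig = any(sc$lod >= thr$threshold), p = sc$p)
}

# One envGWAS power replicate: a single minTemp_sel cline QTL.
env_power_rep <- function(seed, n_clones = 500, n_markers = 1000,
                          strength = 0.15) {
  qtl <- n_markers %/% 2
  p0 <- spectrum_with_qtl(n_markers, qtl, 0.5, seed)
  g <- simulate_genotypes(n_clones, n_markers, default_sites,
                          env_qtl = tibble::tibble(marker = qtl,
                                                   variable = "minTemp_sel",
                                                   strength = strength),
                          p0 = p0, seed = seed)
  w <- simulate_weather(default_sites, 2009:2013, seed = seed + 1)
  ss <- season_summaries(w, default_sites, 2009:2013)
  sy <- simulate_submission_years(g$dosage, year_range = 2012:2014,
                                  seed = seed + 2)
  ce <- selection_env(
    dplyr::left_join(g$clone_programs, sy$submission_years, by = "clone"),
    ss, default_sites)
  res <- run_env_gwas(g$dosage, "minTemp_sel", ce)
  g$truth$env_qtl$marker[1] %in% res$significant$Marker
}

# One regression-GWAS power replicate: a slope QTL of beta per dosage copy,
# 8 trials spanning ~10 degrees C of seasonal maxTemp.
slope_power_rep <- function(seed, n_clones = 500, n_markers = 1000,
                            beta = 0.05) {
  qtl <- n_markers %/% 2
  p0 <- spectrum_with_qtl(n_markers, qtl, 0.4, seed)
  g <- simulate_genotypes(n_clones, n_markers, default_sites, p0 = p0,
                          seed = seed)
  qtl_id <- g$dosage$Marker[qtl]
  locs <- default_sites$site_id[default_sites$is_trial][1:4]
  lay <- tidyr::expand_grid(clone = clone_ids(g$dosage), location = locs,
                            year = 2015:2016)
  te <- tidyr::expand_grid(location = locs, year = 2015:2016)
  set.seed(seed + 1)
  te$maxTemp <- runif(nrow(te), 22, 32)
  truth <- sim_truth(
    variance_components = c(g = .5, gY = .1, gL = .2, gYL = .3, e = 1.5),
    slope_qtl = tibble::tibble(marker = qtl_id, variable = "maxTemp",
                               beta = beta))
  y <- simulate_yields(g$dosage, truth, lay, te, seed = seed + 2)
  nv <- normalize_yield(suppressMessages(filter_yields(y)))
  st <- estimate_slopes(nv, te, "maxTemp")
  res <- run_regression_gwas(g$dosage, st)
  scan <- res$scans[[1]]
  list(detected = qtl_id %in% res$significant$Marker,
       effect = scan$effect[scan$Marker == qtl_id])
}

# One GPSM power replicate: an allele-frequency trend of delta per year.
gpsm_power_rep <- function(seed, n_clones = 800, n_markers = 1000,
                           delta = 0.02) {
  qtl <- n_markers %/% 2
  p0 <- spectrum_with_qtl(n_markers, qtl, 0.3, seed)
  g <- simulate_genotypes(n_clones, n_markers, default_sites, p0 = p0,
                          seed = seed)
  qtl_id <- g$dosage$Marker[qtl]
  sy <- simulate_submission_years(g$dosage,
                                  gpsm_qtl = tibble::tibble(marker = qtl_id,
                                                            delta = delta),
                                  year_range = 2010:2022, seed = seed + 1)
  res <- run_gpsm(sy$dosage, sy$submission_years)
  qtl_id %in% res$significant$Marker
}

# One transience replicate: disjoint env and GPSM QTL; returns TRUE when the
# 1-Mb overlap between the two hit sets is empty.
transience_rep <- function(seed, n_clones = 400, n_markers = 800) {
  env_qtl_ix <- 100L   # chr02 block
  gpsm_qtl_ix <- 700L  # chr11 block
  p0 <- spectrum_with_qtl(n_markers, c(env_qtl_ix, gpsm_qtl_ix), c(0.5, 0.3), seed)
  g <- simulate_genotypes(n_clones, n_markers, default_sites,
                          env_qtl = tibble::tibble(marker = env_qtl_ix,
                                                   variable = "minTemp_sel",
                                                   strength = 0.15),
                          p0 = p0, seed = seed)
  w <- simulate_weather(default_sites, 2007:2021, seed = seed + 1)
  ss <- season_summaries(w, default_sites, 2007:2021)
  sy <- simulate_submission_years(
    g$dosage,
    gpsm_qtl = tibble::tibble(marker = g$dosage$Marker[gpsm_qtl_ix], delta = 0.02),
    year_range = 2010:2022, seed = seed + 2)
  ce <- selection_env(
    dplyr::left_join(g$clone_programs, sy$submission_years, by = "clone"),
    ss, default_sites)
  env <- run_env_gwas(sy$dosage, "minTemp_sel", ce)
  gpsm <- run_gpsm(sy$dosage, sy$submission_years)
  nrow(window_overlap(gpsm$significant, env$significant, 1e6)) == 0
}
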