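test_that("default site table carries the trial coordinates and roles", {
  sites <- simulate_programs(10, seed = 1)
  expect_equal(sites$latitude[sites$site_id == "WI"], 44.12)
  expect_equal(sites$longitude[sites$site_id == "WI"], -89.54)
  expect_gte(sum(sites$is_selection), 1)
  expect_gte(sum(sites$is_trial), 2)
  expect_true(all(sites$season_start < sites$season_end))
  expect_error(simulate_programs(1), class = "envgxe_config_error")
})

test_that("simulate_programs is deterministic under a fixed seed", {
  expect_identical(simulate_programs(15, seed = 7), simulate_programs(15, seed = 7))
  g1 <- simulate_genotypes(50, 80, default_sites, seed = 11)
  g2 <- simulate_genotypes(50, 80, default_sites, seed = 11)
  expect_identical(g1$dosage, g2$dosage)
  w1 <- simulate_weather(default_sites, 2015, seed = 3)
  w2 <- simulate_weather(default_sites, 2015, seed = 3)
  expect_identical(w1, w2)
})

test_that("written simulation files are byte-identical across runs", {
  run_once <- function(dir) {
    g <- simulate_genotypes(40, 60, default_sites, seed = 5)
    w <- simulate_weather(default_sites[1:3, ], 2015, seed = 5)
    write_dosage_csv(g$dosage, file.path(dir, "geno.csv"))
    write_weather_csv(w, file.path(dir, "weather.csv"))
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_once(d1); run_once(d2)
  for (f in c("geno.csv", "weather.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("dosages follow the autotetraploid binomial model", {
  g <- simulate_genotypes(2000, 5, default_sites, p0 = 0.3, seed = 21)
  G <- dosage_matrix(g$dosage)
  expect_true(all(G %in% 0:4))
  # mean dosage = 4p, tolerance 3 sd / sqrt(n) per marker
  tol <- 3 * sqrt(4 * 0.3 * 0.7) / sqrt(2000)
  expect_true(all(abs(rowMeans(G) - 1.2) < tol))
  # marker frequencies stay inside the emitted polymorphic band
  f <- rowMeans(dosage_matrix(simulate_genotypes(300, 500, default_sites, seed = 22)$dosage)) / 4
  expect_true(all(f >= 0.005 & f <= 0.995))
})

test_that("environmental clines shift allele frequencies between programs", {
  two <- default_sites[default_sites$site_id %in% c("ND", "NC"), ] # far north vs south
  two$is_selection <- TRUE
  g <- simulate_genotypes(3000, 4, two,
                          env_qtl = tibble::tibble(marker = 1L, variable = "latitude",
                                                   strength = 0.1),
                          p0 = 0.5, seed = 23)
  d <- dplyr::left_join(
    tibble::tibble(clone = clone_ids(g$dosage),
                   dose = as.numeric(dosage_matrix(g$dosage)[1, ])),
    g$clone_programs, by = "clone")
  freq <- tapply(d$dose, d$program, mean) / 4
  # z = +/-1 across the two programs => frequency difference of 2 * 0.1
  expect_equal(unname(abs(diff(freq))), 0.2, tolerance = 0.15)
  expect_error(
    simulate_genotypes(50, 1, two,
                       env_qtl = tibble::tibble(marker = 1:2, variable = "latitude",
                                                strength = c(.1, .1))),
    class = "envgxe_config_error")
})

test_that("weather generator enforces its invariants", {
  w <- simulate_weather(default_sites, 2016:2017, seed = 31)
  expect_true(all(w$tmax_c >= w$tmin_c))
  expect_true(all(w$precip_cm >= 0))
  expect_equal(nrow(w), nrow(default_sites) * (366 + 365)) # 2016 is a leap year
  # zero-variance climate collapses to the site means
  s0 <- default_sites[1, ]
  s0$tmax_sd <- 0; s0$tmin_sd <- 0; s0$precip_sd <- 0
  w0 <- simulate_weather(s0, 2016, seed = 32)
  expect_true(all(w0$tmax_c == s0$tmax_mean))
  expect_true(all(w0$precip_cm == s0$precip_mean))
  # tmin mean above tmax mean still yields tmax >= tmin (swap rule)
  sx <- default_sites[1, ]
  sx$tmin_mean <- sx$tmax_mean + 5
  expect_true(all(with(simulate_weather(sx, 2016, seed = 33), tmax_c >= tmin_c)))
  expect_error(simulate_weather(default_sites[0, ], 2016), class = "envgxe_config_error")
})

test_that("masking flags roughly the requested fraction of days", {
  w <- simulate_weather(default_sites, 2015:2017, seed = 34, missing_frac = 0.1)
  frac <- mean(is.na(w$tmax_c))
  expect_equal(frac, 0.1, tolerance = 0.02)
})

test_that("noise-free yields equal the fixed-effect surface exactly", {
  locs <- default_sites$site_id[default_sites$is_trial][1:3]
  lay <- tidyr::expand_grid(clone = c("A", "B"), location = locs, year = 2015:2016)
  truth <- sim_truth(
    variance_components = c(g = 0, gY = 0, gL = 0, gYL = 0, e = 0),
    mu = 20,
    year_effects = c(`2015` = -1, `2016` = 2),
    loc_effects = setNames(c(-5, 0, 10), locs),
    yl_effects = setNames(rep(0.5, 6),
                          paste(rep(locs, each = 2), rep(2015:2016, 3), sep = ":"))
  )
  y <- simulate_yields(NULL, truth, lay, seed = 1)
  expected <- 20 + c(`2015` = -1, `2016` = 2)[as.character(lay$year)] +
    setNames(c(-5, 0, 10), locs)[lay$location] + 0.5
  expect_equal(y$plot_yield_kg, unname(expected))
  expect_equal(attr(y, "n_floored"), 0L)
  expect_error(sim_truth(variance_components = c(g = -1, gY = 0, gL = 0, gYL = 0, e = 1)),
               class = "envgxe_config_error")
})

test_that("clone variance component propagates to per-clone means", {
  clones <- sprintf("C%04d", 1:1000)
  lay <- simulate_trial_layout(clones, default_sites, 2015:2016,
                               n_years_per_clone = 2, seed = 2)
  truth <- sim_truth(variance_components = c(g = 1, gY = 0, gL = 0, gYL = 0, e = 0),
                     mu = 10,
                     year_effects = c(`2015` = 0, `2016` = 0),
                     loc_effects = setNames(rep(0, 10), unique(lay$location)),
                     yl_effects = setNames(rep(0, 20), unique(paste(lay$location, lay$year, sep = ":"))))
  y <- simulate_yields(NULL, truth, lay, seed = 3)
  clone_means <- tapply(y$plot_yield_kg - 10, y$clone, mean)
  expect_equal(var(clone_means), 1, tolerance = 0.1)
})

test_that("planted slope QTL is recovered by per-dosage-class regression", {
  sites <- default_sites
  g <- simulate_genotypes(400, 30, sites, p0 = 0.4, seed = 41)
  locs <- sites$site_id[sites$is_trial]
  lay <- tidyr::expand_grid(clone = clone_ids(g$dosage), location = locs, year = 2015L)
  trial_env <- tibble::tibble(location = locs, year = 2015L,
                              maxTemp = seq(22, 32, length.out = length(locs)))
  truth <- sim_truth(
    variance_components = c(g = 0, gY = 0, gL = 0, gYL = 0, e = 0.01),
    mu = 20,
    year_effects = c(`2015` = 0),
    loc_effects = setNames(rep(0, length(locs)), locs),
    yl_effects = setNames(rep(0, length(locs)), paste(locs, 2015, sep = ":")),
    slope_qtl = tibble::tibble(marker = "M00003", variable = "maxTemp", beta = 0.05)
  )
  y <- simulate_yields(g$dosage, truth, lay, trial_env, seed = 42)
  y$E <- trial_env$maxTemp[match(y$location, trial_env$location)]
  y$dose <- dosage_matrix(g$dosage)["M00003", y$clone]
  for (d in c(0, 2, 4)) {
    sub <- y[y$dose == d, ]
    if (nrow(sub) < 50) next
    sl <- coef(lm(log(plot_yield_kg) ~ E, data = sub))[["E"]]
    expect_equal(sl, 0.05 * d, tolerance = 0.01)
  }
})

test_that("submission-year trends resample only the GPSM markers", {
  g <- simulate_genotypes(1500, 10, default_sites, p0 = 0.4, seed = 51)
  res <- simulate_submission_years(g$dosage,
                                   gpsm_qtl = tibble::tibble(marker = "M00004", delta = 0.02),
                                   year_range = 2010:2022, seed = 52)
  d <- dosage_matrix(res$dosage)
  yrs <- res$submission_years$submission_year
  # planted marker: frequency rises ~0.02/yr
  sl <- coef(lm(d["M00004", ] / 4 ~ yrs))[["yrs"]]
  expect_lt(abs(sl - 0.02), 0.006)
  # untouched neutral marker: no systematic trend
  sl0 <- coef(lm(d["M00001", ] / 4 ~ yrs))[["yrs"]]
  expect_lt(abs(sl0), 0.006)
  expect_identical(d["M00001", ], dosage_matrix(g$dosage)["M00001", ])
  # trajectory leaving [0,1] warns and clips
  expect_warning(
    simulate_submission_years(g$dosage,
                              gpsm_qtl = tibble::tibble(marker = "M00005", delta = 0.2),
                              year_range = 2010:2022, seed = 53),
    "clipped")
})
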