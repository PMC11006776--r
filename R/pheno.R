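#' Filter plot-level yield records
#'
#' Drops records with missing, zero or negative plot yield (only non-zero
#' yield observations enter the analyses).  Optionally restricts to
#' genotyped clones: the variance decomposition uses all records, the GWAS
#' analyses only genotyped ones.
#'
#' @param records Tibble with at least `clone` and `plot_yield_kg`.
#' @param genotyped Optional character vector of genotyped clone ids; when
#'   supplied, records for other clones are dropped.
#' @return Filtered tibble; attribute `dropped` holds the counts by reason.
#' @export
filter_yields <- function(records, genotyped = NULL) {
  n0 <- nrow(records)
  y <- records$plot_yield_kg
  keep <- !is.na(y) & y > 0
  dropped <- c(missing = sum(is.na(y)), nonpositive = sum(!is.na(y) & y <= 0))
  out <- records[keep, ]
  if (!is.null(genotyped)) {
    ungeno <- !(out$clone %in% genotyped)
    dropped <- c(dropped, ungenotyped = sum(ungeno))
    out <- out[!ungeno, ]
  }
  if (nrow(out) == 0) {
    abort("No yield records survive filtering.", class = "envgxe_data_error")
  }
  inform(sprintf("filter_yields: kept %d of %d records (dropped %s).",
                 nrow(out), n0,
                 paste(names(dropped), dropped, sep = "=", collapse = ", ")))
  attr(out, "dropped") <- dropped
  out
}

#' Normalize yields to log relative performance within trial
#'
#' Each plot yield is divided by the mean plot yield of its trial (a
#' location-year pair) and log-transformed (natural log), giving the
#' relative performance of each clone within each trial centered on zero.
#' By construction the within-trial mean of `exp(value)` is exactly 1.
#' Trials with a single record are excluded with a warning.
#'
#' @param records Filtered yield tibble (`clone`, `location`, `year`,
#'   `plot_yield_kg`).
#' @param min_records Minimum records per trial (trials below are excluded).
#' @return Tibble `clone`, `location`, `year`, `trial`, `value`.
#' @export
normalize_yield <- function(records, min_records = 2) {
  records$trial <- paste(records$location, records$year, sep = ":")
  sizes <- table(records$trial)
  small <- names(sizes)[sizes < min_records]
  if (length(small)) {
    warn(paste0("Excluding ", length(small),
                " trial(s) with a single record: ",
                paste(head(small, 5), collapse = ", ")))
    records <- records[!records$trial %in% small, ]
  }
  if (nrow(records) == 0) abort("No multi-record trials.", class = "envgxe_data_error")
  dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(records, .data$trial),
    value = log(.data$plot_yield_kg / mean(.data$plot_yield_kg))
  ))[, c("clone", "location", "year", "trial", "value")]
}

#' Partition genotypic variance for yield
#'
#' REML fit of the multi-environment trial model
#' yield = mu + Y + L + YL + g + gY + gL + gYL + e, with year, location and
#' their interaction as fixed effects and genotype (g), genotype-by-year
#' (gY), genotype-by-location (gL) and genotype-by-year-by-location (gYL)
#' as independent random effects.  Reported proportions express each
#' genetic component as a percentage of the summed genetic variance
#' (g + gY + gL + gYL); proportions of total phenotypic variance (including
#' the residual) are reported alongside.
#'
#' @param records Filtered yield tibble (`clone`, `location`, `year`,
#'   `plot_yield_kg`).
#' @param response Column holding the response; raw plot yield by default.
#' @return Object of class `variance_decomposition` with `components`
#'   (tibble of variances and percent shares), `fit` (the lme4 fit),
#'   and convergence diagnostics.  Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
partition_variance <- function(records, response = "plot_yield_kg") {
  d <- tibble::tibble(
    y = records[[response]],
    clone = factor(records$clone),
    year = factor(records$year),
    location = factor(records$location)
  )
  if (nlevels(d$year) < 2 || nlevels(d$location) < 2) {
    abort("Need at least two years and two locations.", class = "envgxe_data_error")
  }
  n_trials_per_clone <- tapply(paste(d$location, d$year), d$clone,
                               function(x) length(unique(x)))
  if (max(n_trials_per_clone) < 2) {
    abort("Design confounded: no clone observed in more than one trial.",
          class = "envgxe_data_error")
  }
  fit <- lme4::lmer(
    y ~ year * location + (1 | clone) + (1 | clone:year) +
      (1 | clone:location) + (1 | clone:year:location),
    data = d, REML = TRUE,
    control = lme4::lmerControl(calc.derivs = FALSE,
                                check.nobs.vs.nlev = "ignore",
                                check.nobs.vs.nRE = "ignore")
  )
  conv <- fit@optinfo$conv$opt
  vc <- as.data.frame(lme4::VarCorr(fit))
  grp <- c("clone" = "g", "clone:year" = "gY", "clone:location" = "gL",
           "clone:year:location" = "gYL", "Residual" = "e")
  sig2 <- setNames(vc$vcov[match(names(grp), vc$grp)], grp)
  gen <- sig2[c("g", "gY", "gL", "gYL")]
  comp <- tibble::tibble(
    component = names(sig2),
    variance = as.numeric(sig2),
    pct_genetic = c(100 * gen / sum(gen), NA_real_),
    pct_total = 100 * as.numeric(sig2) / sum(sig2)
  )
  structure(
    list(components = comp, fit = fit, converged = conv == 0,
         logLik = as.numeric(stats::logLik(fit)), n = nrow(d)),
    class = "variance_decomposition"
  )
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("Variance decomposition of yield (REML)\n")
  cat(sprintf("  n = %d records, REML logLik = %.2f%s\n", x$n, x$logLik,
              if (x$converged) "" else "  [did not converge]"))
  print(as.data.frame(x$components), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname partition_variance
#' @param x A `variance_decomposition`.
#' @param ... Unused.
#' @export
tidy.variance_decomposition <- function(x, ...) x$components

#' @rdname partition_variance
#' @export
glance.variance_decomposition <- function(x, ...) {
  gen <- x$components$variance[x$components$component %in% c("g", "gY", "gL", "gYL")]
  tibble::tibble(
    n = x$n, logLik = x$logLik, converged = x$converged,
    genetic_variance = sum(gen),
    total_variance = sum(x$components$variance)
  )
}
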