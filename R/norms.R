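#' Per-genotype reaction-norm slopes
#'
#' For each clone, ordinary least squares of its normalized log yield on
#' the growing-season value of one environmental variable in the trials
#' where it was grown (the model value = mu + g + E per genotype).  The
#' slope measures that clone's environmental sensitivity along the
#' gradient; differences in slope between clones are GxE.
#'
#' Clones observed with fewer than `min_trials` distinct environmental
#' values, or with zero variance in the environmental value, are excluded
#' and listed in the `excluded` attribute.
#'
#' @param normalized Tibble from [normalize_yield()] (`clone`, `location`,
#'   `year`, `value`).
#' @param trial_env Tibble `location`, `year`, plus a column named
#'   `variable`: the within-trial growing-season value.
#' @param variable Environmental variable name (e.g. `"maxTemp"`).
#' @param min_trials Minimum number of distinct environmental values.
#' @param conf_level Confidence level for the slope interval.
#' @return Tibble of class `slope_table`: `clone`, `variable`, `slope`,
#'   `se`, `ci_lo`, `ci_hi`, `intercept`, `n_trials`.
#' @export
estimate_slopes <- function(normalized, trial_env, variable, min_trials = 3,
                            conf_level = 0.95) {
  if (!variable %in% names(trial_env)) {
    abort(paste0("`trial_env` has no column `", variable, "`."),
          class = "envgxe_config_error")
  }
  e_val <- trial_env[[variable]][match(paste(normalized$location, normalized$year),
                                       paste(trial_env$location, trial_env$year))]
  if (anyNA(e_val)) {
    abort("Some trials lack an environmental value.", class = "envgxe_data_error")
  }
  d <- tibble::tibble(clone = normalized$clone, e = e_val, y = normalized$value)

  per_clone <- d |>
    dplyr::group_by(.data$clone) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_env = dplyr::n_distinct(e),
      ebar = mean(e), ybar = mean(y),
      sxx = sum((e - ebar)^2),
      sxy = sum((e - ebar) * (y - ybar)),
      slope = ifelse(sxx > 0, sxy / sxx, NA_real_),
      intercept = ybar - slope * ebar,
      rss = sum((y - intercept - slope * e)^2),
      .groups = "drop"
    )

  bad <- per_clone$n_env < min_trials | per_clone$sxx <= 0
  excluded <- tibble::tibble(
    clone = per_clone$clone[bad],
    reason = ifelse(per_clone$sxx[bad] <= 0, "zero env variance",
                    sprintf("fewer than %d distinct env values", min_trials))
  )
  ok <- per_clone[!bad, ]
  dfree <- ok$n_trials - 2
  sigma2 <- ifelse(dfree > 0, ok$rss / dfree, NA_real_)
  se <- sqrt(sigma2 / ok$sxx)
  tq <- qt(1 - (1 - conf_level) / 2, pmax(dfree, 1))
  out <- tibble::tibble(
    clone = ok$clone, variable = variable,
    slope = ok$slope, se = se,
    ci_lo = ok$slope - tq * se, ci_hi = ok$slope + tq * se,
    intercept = ok$intercept, n_trials = ok$n_trials
  )
  class(out) <- c("slope_table", class(out))
  attr(out, "excluded") <- excluded
  out
}

#' Summary of a reaction-norm slope table
#'
#' Reports the slope range, the SE distribution and the fraction of
#' confidence intervals crossing zero -- in the national trial data those
#' intervals were wide relative to the slope range, an important caveat on
#' slope-based GWAS.
#'
#' @param slopes A [estimate_slopes()] table.
#' @return One-row tibble: counts, slope range, median SE, fraction of CIs
#'   containing zero.
#' @export
slope_summary <- function(slopes) {
  if (nrow(slopes) == 0) abort("Empty slope table.", class = "envgxe_data_error")
  crosses <- slopes$ci_lo <= 0 & slopes$ci_hi >= 0
  tibble::tibble(
    variable = slopes$variable[1],
    n_clones = nrow(slopes),
    slope_min = min(slopes$slope), slope_max = max(slopes$slope),
    slope_sd = sd(slopes$slope),
    se_median = stats::median(slopes$se, na.rm = TRUE),
    frac_ci_cross_zero = mean(crosses, na.rm = TRUE)
  )
}
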