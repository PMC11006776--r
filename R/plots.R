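#' Manhattan plot of a marker scan
#'
#' LOD score against cumulative genomic position, chromosomes alternately
#' shaded, with the genome-wide threshold as a dashed line when present.
#'
#' @param object A `gwas_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gwas_scan <- function(object, ...) {
  d <- tidy(object)
  chrom_sizes <- d |>
    dplyr::group_by(.data$Chrom) |>
    dplyr::summarise(len = max(.data$Position), .groups = "drop") |>
    dplyr::arrange(.data$Chrom) |>
    dplyr::mutate(offset = cumsum(dplyr::lag(.data$len, default = 0)))
  d <- dplyr::left_join(d, chrom_sizes, by = "Chrom")
  d$x <- d$Position + d$offset
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$lod,
                                       colour = .data$Chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::scale_x_continuous(
      breaks = chrom_sizes$offset + chrom_sizes$len / 2,
      labels = chrom_sizes$Chrom) +
    ggplot2::labs(x = NULL, y = "LOD") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  thr <- attr(object, "threshold")
  if (!is.null(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = thr, linetype = "dashed")
  }
  p
}

#' Bar chart of genetic variance shares
#'
#' @param object A `variance_decomposition`.
#' @param ... Unused.
#' @return A ggplot object showing each genetic component's percent of the
#'   summed genetic variance.
#' @export
autoplot.variance_decomposition <- function(object, ...) {
  d <- object$components
  d <- d[!is.na(d$pct_genetic), ]
  d$component <- factor(d$component, levels = c("g", "gY", "gL", "gYL"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$pct_genetic)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "% of genetic variance") +
    ggplot2::theme_minimal()
}

#' Reaction-norm slope distribution
#'
#' Slope estimates with their confidence intervals, ordered by slope;
#' intervals crossing zero are drawn in grey, a visual account of how much
#' of the slope variation is estimation error.
#'
#' @param object A `slope_table`.
#' @param max_clones Subsample this many clones for legibility.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.slope_table <- function(object, max_clones = 200, ...) {
  d <- tibble::as_tibble(object)
  if (nrow(d) > max_clones) d <- d[sort(sample.int(nrow(d), max_clones)), ]
  d <- dplyr::arrange(d, .data$slope)
  d$ix <- seq_len(nrow(d))
  d$crosses <- d$ci_lo <= 0 & d$ci_hi >= 0
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ix, y = .data$slope,
                                  colour = .data$crosses)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                            alpha = 0.5) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "grey60", `FALSE` = "black"),
                                 guide = "none") +
    ggplot2::labs(x = "clone (ordered)", y = paste0("slope (", d$variable[1], ")")) +
    ggplot2::theme_minimal()
}
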