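#' Tidy a marker scan
#'
#' @param x A `gwas_scan`.
#' @param ... Unused.
#' @return The per-marker tibble (Marker, Chrom, Position, effect, se, p,
#'   lod, and `significant` if thresholded).
#' @export
tidy.gwas_scan <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "gwas_scan")
  for (a in c("nullfit", "threshold", "m_eff", "trait")) attr(out, a) <- NULL
  tibble::as_tibble(out)
}

#' @rdname tidy.gwas_scan
#' @export
glance.gwas_scan <- function(x, ...) {
  nf <- attr(x, "nullfit")
  tibble::tibble(
    n_markers = nrow(x),
    n_clones = nf$n %||% NA_integer_,
    h2 = nf$h2 %||% NA_real_,
    sigma2_poly = nf$sigma2_poly %||% NA_real_,
    sigma2_e = nf$sigma2_e %||% NA_real_,
    threshold = attr(x, "threshold") %||% NA_real_,
    m_eff = attr(x, "m_eff") %||% NA_real_,
    n_significant = if ("significant" %in% names(x)) sum(x$significant) else NA_integer_
  )
}

#' @export
print.gwas_analysis <- function(x, ...) {
  cat(sprintf("<gwas_analysis> %s\n", x$kind))
  cat(sprintf("  scans: %s\n", paste(names(x$scans), collapse = ", ")))
  cat(sprintf("  M_eff = %.1f, LOD threshold = %.3f\n", x$m_eff, x$threshold))
  cat(sprintf("  %d significant marker(s)\n", nrow(x$significant)))
  if (nrow(x$significant)) print(as.data.frame(x$significant), row.names = FALSE)
  invisible(x)
}

#' @rdname tidy.gwas_scan
#' @export
tidy.gwas_analysis <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$scans, function(s, tr) {
    dplyr::mutate(tidy(s), trait = tr, .before = 1)
  }))
}

#' @rdname tidy.gwas_scan
#' @export
glance.gwas_analysis <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_scans = length(x$scans),
                 m_eff = x$m_eff, threshold = x$threshold,
                 n_significant = nrow(x$significant))
}
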