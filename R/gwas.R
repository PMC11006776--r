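#' Minor-allele-frequency filter
#'
#' Allele frequency is mean dosage / 4 (autotetraploid coding 0-4), folded
#' at 0.5.  Markers with folded frequency below `threshold`, and strictly
#' monomorphic markers, are removed.
#'
#' @param dosage Dosage tibble.
#' @param threshold MAF threshold in `[0, 0.5)`; default 0.01.
#' @return Filtered dosage tibble; attribute `removed` lists dropped
#'   markers with their frequencies.
#' @export
maf_filter <- function(dosage, threshold = 0.01) {
  if (threshold < 0 || threshold >= 0.5) {
    abort("`threshold` must be in [0, 0.5).", class = "envgxe_config_error")
  }
  G <- dosage_matrix(dosage)
  f <- unname(rowMeans(G) / 4)
  maf <- pmin(f, 1 - f)
  keep <- maf >= threshold & maf > 0
  if (!any(keep)) abort("All markers removed by MAF filter.", class = "envgxe_data_error")
  out <- dosage[keep, ]
  attr(out, "removed") <- tibble::tibble(
    Marker = dosage$Marker[!keep], freq = f[!keep], maf = maf[!keep]
  )
  out
}

#' Realized relationship (kinship) matrix from dosages
#'
#' K = Z Z' / c with Z the column-centered clone-by-marker dosage matrix
#' and c chosen so the mean diagonal of K is 1.  Models the polygenic
#' covariance among clones in the mixed-model scans.
#'
#' @param dosage Dosage tibble with >= 2 clones and >= 2 polymorphic markers.
#' @return Symmetric positive semidefinite matrix with clone dimnames.
#' @export
kinship <- function(dosage) {
  G <- dosage_matrix(dosage)
  Z <- t(G)                                  # clones x markers
  keep <- apply(Z, 2, function(col) var(col) > 0)
  if (sum(keep) < 2) abort("Need >= 2 polymorphic markers.", class = "envgxe_data_error")
  if (nrow(Z) < 2) abort("Need >= 2 clones.", class = "envgxe_data_error")
  Z <- scale(Z[, keep, drop = FALSE], center = TRUE, scale = FALSE)
  KK <- tcrossprod(Z)
  c0 <- mean(diag(KK))
  K <- KK / c0
  dimnames(K) <- list(rownames(Z), rownames(Z))
  K
}

#' Principal components of the dosage matrix
#'
#' PCA of centered clone-by-marker dosages, used to check for population
#' structure among programs.
#'
#' @param dosage Dosage tibble.
#' @param n_components Number of components to return.
#' @return List: `scores` (tibble `clone`, `PC1`, ...), `explained`
#'   (variance fractions, non-increasing).
#' @export
dosage_pca <- function(dosage, n_components = 10) {
  G <- dosage_matrix(dosage)
  X <- t(G)
  n_components <- as.integer(n_components)
  if (n_components > min(dim(X))) {
    abort("`n_components` exceeds min(clones, markers).", class = "envgxe_config_error")
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x[, seq_len(n_components), drop = FALSE])
  scores <- dplyr::mutate(scores, clone = rownames(X), .before = 1)
  list(scores = scores, explained = expl[seq_len(n_components)])
}

#' Fit the null polygenic model by spectral REML
#'
#' One-kinship mixed model y = X beta + u + e with u ~ N(0, sigma2_poly K)
#' and e ~ N(0, sigma2_e I).  The REML optimum is found by a
#' one-dimensional search over the variance ratio delta = sigma2_e /
#' sigma2_poly after eigen-decomposing K; the rotation is cached and reused
#' for every marker test (the P3D approximation: population parameters
#' previously determined).
#'
#' @param response Tibble (`clone`, `value`) or named numeric vector.
#' @param K Kinship matrix from [kinship()] (clone dimnames required).
#' @param covariates Optional numeric matrix of clone-level covariates
#'   (rownames = clone ids); an intercept is always included.
#' @return Object of class `null_fit`: variance components, heritability
#'   on the K scale, REML log-likelihood, and the cached spectral rotation.
#' @export
fit_null <- function(response, K, covariates = NULL) {
  if (is.data.frame(response)) {
    y <- setNames(response$value, response$clone)
  } else {
    y <- response
  }
  clones <- rownames(K)
  if (is.null(clones)) abort("K must carry clone dimnames.", class = "envgxe_data_error")
  if (!all(clones %in% names(y))) {
    abort("Response missing for some clones in K.", class = "envgxe_data_error")
  }
  y <- y[clones]
  if (anyNA(y)) abort("Response contains NA.", class = "envgxe_data_error")
  if (var(y) <= 0) abort("Response has zero variance.", class = "envgxe_data_error")
  n <- length(y)
  X <- matrix(1, n, 1, dimnames = list(clones, "(Intercept)"))
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (!is.null(rownames(cv))) cv <- cv[clones, , drop = FALSE]
    X <- cbind(X, cv)
  }
  q <- ncol(X)

  ek <- eigen(K, symmetric = TRUE)
  U <- ek$vectors
  dvals <- pmax(ek$values, 0)
  ystar <- drop(crossprod(U, y))
  Xstar <- crossprod(U, X)
  ldet_XtX <- determinant(crossprod(Xstar), logarithm = TRUE)$modulus

  reml_parts <- function(delta) {
    w <- dvals + delta
    XtWX <- crossprod(Xstar, Xstar / w)
    beta <- solve(XtWX, crossprod(Xstar, ystar / w))
    r <- ystar - drop(Xstar %*% beta)
    rss <- sum(r^2 / w)
    sigma2 <- rss / (n - q)
    ll <- -0.5 * ((n - q) * log(2 * pi * sigma2) + (n - q) +
                    sum(log(w)) +
                    as.numeric(determinant(XtWX, logarithm = TRUE)$modulus) -
                    as.numeric(ldet_XtX))
    list(ll = ll, sigma2 = sigma2, beta = beta, w = w)
  }
  opt <- optimize(function(ld) reml_parts(exp(ld))$ll,
                  interval = c(log(1e-6), log(1e6)), maximum = TRUE)
  delta <- exp(opt$maximum)
  at <- reml_parts(delta)
  sigma2_poly <- at$sigma2
  sigma2_e <- delta * sigma2_poly

  structure(
    list(sigma2_poly = sigma2_poly, sigma2_e = sigma2_e, delta = delta,
         h2 = sigma2_poly / (sigma2_poly + sigma2_e),
         loglik = at$ll, beta = drop(at$beta),
         U = U, d = dvals, w = dvals + delta,
         ystar = ystar, Xstar = Xstar, clones = clones, n = n, q = q),
    class = "null_fit"
  )
}

#' @export
print.null_fit <- function(x, ...) {
  cat(sprintf(
    "Null polygenic fit: n = %d, sigma2_poly = %.4g, sigma2_e = %.4g, h2 = %.3f\n",
    x$n, x$sigma2_poly, x$sigma2_e, x$h2))
  invisible(x)
}

#' Mixed-model marker scan (P3D)
#'
#' Generalized least squares of the response on each marker's dosage
#' (additive 0-4 coding) plus covariates, under the null covariance
#' sigma2_poly K + sigma2_e I cached in `nullfit`.  In envGWAS the response
#' is an environmental descriptor regressed on dosage (reverse regression,
#' valid because dosages are measured essentially without error).  Reports
#' Wald effect, SE, p and LOD = -log10(p) per marker.  Markers monomorphic
#' on the scanned clones get p = 1 and are flagged.
#'
#' @param dosage Dosage tibble.
#' @param response Tibble (`clone`, `value`) or named vector; must cover
#'   the clones of `nullfit`.
#' @param nullfit A [fit_null()] object computed on the same clones.
#' @return Tibble of class `gwas_scan`: `Marker`, `Chrom`, `Position`,
#'   `effect`, `se`, `p`, `lod`, `monomorphic`, with the null fit and
#'   response name as attributes.
#' @export
score_markers <- function(dosage, response, nullfit) {
  stopifnot(inherits(nullfit, "null_fit"))
  G <- dosage_matrix(dosage)
  missing_cl <- setdiff(nullfit$clones, colnames(G))
  if (length(missing_cl)) {
    abort(paste0("Dosage table lacks clones: ", paste(head(missing_cl, 3), collapse = ", ")),
          class = "envgxe_data_error")
  }
  G <- G[, nullfit$clones, drop = FALSE]
  n <- nullfit$n; q <- nullfit$q
  w <- nullfit$d + nullfit$delta
  X <- nullfit$Xstar
  y <- nullfit$ystar

  Gs <- G %*% nullfit$U                       # m x n, rows are rotated markers
  XtWXi <- solve(crossprod(X, X / w))
  yt <- y - drop(X %*% (XtWXi %*% crossprod(X, y / w)))
  Bg <- XtWXi %*% crossprod(X, t(Gs) / w)     # q x m
  Gt <- t(Gs) - X %*% Bg                      # n x m residualized markers

  Sgg <- colSums(Gt^2 / w)
  Sgy <- colSums(Gt * (yt / w))
  mono <- Sgg < 1e-10
  eff <- ifelse(mono, NA_real_, Sgy / Sgg)
  rss0 <- sum(yt^2 / w)
  rss <- rss0 - ifelse(mono, 0, eff * Sgy)
  dfree <- n - q - 1
  sigma2 <- rss / dfree
  se <- ifelse(mono, NA_real_, sqrt(sigma2 / Sgg))
  tstat <- eff / se
  p <- ifelse(mono, 1, 2 * pt(-abs(tstat), dfree))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  out <- dplyr::bind_cols(
    marker_map(dosage),
    tibble::tibble(effect = eff, se = se, p = p, lod = -log10(p),
                   monomorphic = mono)
  )
  class(out) <- c("gwas_scan", class(out))
  attr(out, "nullfit") <- nullfit[c("sigma2_poly", "sigma2_e", "delta", "h2", "n")]
  out
}

# Effective test count from correlation-matrix eigenvalues: the number of
# leading eigenvalues needed to account for `var_cut` of the total variance.
# Fully duplicated markers double every eigenvalue without changing the
# count, so perfect LD collapses to one effective test, while mutually
# independent markers (eigenvalues near 1) count fully.
eigen_meff <- function(ev, var_cut = 0.995) {
  ev <- sort(pmax(ev, 0), decreasing = TRUE)
  sum(cumsum(ev) < var_cut * sum(ev)) + 1
}

#' Effective number of markers and genome-wide LOD threshold
#'
#' The effective number of independent tests M_eff is computed from the
#' eigenvalues of the marker correlation matrix, chromosome by chromosome
#' and summed: within a chromosome, M_eff is the number of leading
#' eigenvalues needed to capture 99.5 percent of the dosage variance.  The
#' genome-wide 5 percent threshold is then LOD = -log10(alpha / M_eff)
#' (a Bonferroni correction on M_eff tests).
#'
#' @param dosage Dosage tibble with >= 2 markers.
#' @param alpha Genome-wide significance level in (0, 1).
#' @return List: `m_eff`, `threshold` (LOD), `alpha`, `per_chrom` tibble.
#' @export
meff_threshold <- function(dosage, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0,1).",
                                      class = "envgxe_config_error")
  G <- dosage_matrix(dosage)
  if (nrow(G) < 2) abort("Need >= 2 markers.", class = "envgxe_data_error")
  map <- marker_map(dosage)
  per_chrom <- purrr::map_dfr(split(seq_len(nrow(G)), map$Chrom), function(ix) {
    Z <- t(G[ix, , drop = FALSE])
    Z <- Z[, apply(Z, 2, var) > 0, drop = FALSE]
    m <- ncol(Z)
    if (m == 0) return(tibble::tibble(chrom = map$Chrom[ix[1]], n_markers = 0L, m_eff = 0))
    if (m == 1) return(tibble::tibble(chrom = map$Chrom[ix[1]], n_markers = 1L, m_eff = 1))
    ev <- eigen(cor(Z), symmetric = TRUE, only.values = TRUE)$values
    tibble::tibble(chrom = map$Chrom[ix[1]], n_markers = m,
                   m_eff = eigen_meff(ev))
  })
  m_eff <- sum(per_chrom$m_eff)
  list(m_eff = m_eff, threshold = -log10(alpha / m_eff), alpha = alpha,
       per_chrom = per_chrom)
}

#' Apply a genome-wide threshold to a scan
#'
#' Adds a `significant` column (LOD at or above the threshold counts as
#' significant -- inclusive boundary) and records `m_eff`/`threshold` as
#' attributes.
#'
#' @param scan A [score_markers()] result.
#' @param thr A [meff_threshold()] result (or a bare LOD value).
#' @return The scan with a `significant` column.
#' @export
apply_threshold <- function(scan, thr) {
  threshold <- if (is.list(thr)) thr$threshold else thr
  scan$significant <- scan$lod >= threshold
  attr(scan, "threshold") <- threshold
  attr(scan, "m_eff") <- if (is.list(thr)) thr$m_eff else NA_real_
  scan
}

#' Significant markers of a thresholded scan
#' @param scan A thresholded [apply_threshold()] scan.
#' @return Tibble of significant rows sorted by decreasing LOD.
#' @export
significant_markers <- function(scan) {
  if (!"significant" %in% names(scan)) {
    abort("Apply a threshold first (see `apply_threshold()`).",
          class = "envgxe_config_error")
  }
  out <- scan[scan$significant, ]
  out[order(-out$lod), ]
}

#' Percent variance explained by backward elimination
#'
#' Fits all significant markers jointly as fixed effects under the null
#' covariance (GLS), then defines each marker's PVE as the drop in model
#' R-squared when that marker alone is removed from the joint model, times
#' 100; the cumulative PVE is the joint-model R-squared times 100.
#' R-squared is measured on the whitened scale against the covariate-only
#' model.  Collinear markers are eliminated (the member with the smaller
#' marginal effect is dropped, with a warning).
#'
#' @param response Tibble (`clone`, `value`) or named vector.
#' @param significant Character vector of significant marker ids.
#' @param dosage Dosage tibble.
#' @param nullfit A [fit_null()] for this response.
#' @param tol Markers whose removal changes R-squared by less than `tol`
#'   report a PVE of 0.
#' @return Tibble of class `pve_report`: `Marker`, `pve`, `order` (backward
#'   elimination order, 1 = eliminated first); attributes `cumulative`
#'   (joint R-squared x 100) and `dropped` (collinear markers removed).
#' @export
pve_backward_elimination <- function(response, significant, dosage, nullfit,
                                     tol = 1e-8) {
  if (length(significant) == 0) {
    abort("Significant set is empty.", class = "envgxe_data_error")
  }
  G <- dosage_matrix(dosage)
  miss <- setdiff(significant, rownames(G))
  if (length(miss)) abort(paste0("Markers not in dosage table: ",
                                 paste(miss, collapse = ", ")),
                          class = "envgxe_data_error")
  M <- t(G[significant, nullfit$clones, drop = FALSE])  # n x k

  sw <- sqrt(nullfit$d + nullfit$delta)
  Xw <- nullfit$Xstar / sw
  yw <- nullfit$ystar / sw
  Mw <- (crossprod(nullfit$U, M)) / sw

  # order candidate markers by decreasing marginal association so that the
  # smaller-effect member of a collinear pair is the one dropped
  marg <- abs(apply(Mw, 2, function(g) {
    gt <- stats::lm.fit(Xw, g)$residuals
    yt <- stats::lm.fit(Xw, yw)$residuals
    if (sum(gt^2) < 1e-12) 0 else sum(gt * yt) / sum(gt^2)
  }))
  ord <- order(-marg)
  kept <- integer(0)
  cur <- Xw
  dropped <- character(0)
  for (j in ord) {
    cand <- cbind(cur, Mw[, j])
    if (qr(cand)$rank > qr(cur)$rank) {
      kept <- c(kept, j)
      cur <- cand
    } else {
      dropped <- c(dropped, colnames(M)[j])
    }
  }
  if (length(dropped)) {
    warn(paste0("Dropping collinear marker(s): ", paste(dropped, collapse = ", ")))
  }
  kept <- sort(kept)
  k <- length(kept)

  rss_of <- function(cols) {
    d <- cbind(Xw, Mw[, cols, drop = FALSE])
    sum(stats::lm.fit(d, yw)$residuals^2)
  }
  tss <- sum(stats::lm.fit(Xw, yw)$residuals^2)
  rss_full <- rss_of(kept)
  r2_full <- 1 - rss_full / tss
  pve <- vapply(seq_len(k), function(i) {
    r2_minus <- 1 - rss_of(kept[-i]) / tss
    d <- r2_full - r2_minus
    if (abs(d) < tol) 0 else 100 * d
  }, numeric(1))
  pve <- pmax(pve, 0)

  out <- tibble::tibble(
    Marker = colnames(M)[kept],
    pve = pve,
    order = rank(pve, ties.method = "first")
  )
  class(out) <- c("pve_report", class(out))
  attr(out, "cumulative") <- 100 * r2_full
  attr(out, "dropped") <- dropped
  out
}

#' Case-control response for a breeding program
#'
#' 1 for clones selected by `target_program`, 0 otherwise.  The linear
#' mixed-model scan of this binary response is a first-order approximation
#' to the corresponding generalized linear model.
#'
#' @param clone_programs Tibble `clone`, `program`.
#' @param target_program Program id.
#' @return Tibble `clone`, `value` with attribute `counts`.
#' @export
binary_response <- function(clone_programs, target_program) {
  if (!target_program %in% clone_programs$program) {
    abort(paste0("Unknown program `", target_program, "`."),
          class = "envgxe_config_error")
  }
  v <- as.numeric(clone_programs$program == target_program)
  if (all(v == 1) || all(v == 0)) {
    abort("Response is all-case or all-control.", class = "envgxe_data_error")
  }
  out <- tibble::tibble(clone = clone_programs$clone, value = v)
  attr(out, "counts") <- c(case = sum(v == 1), control = sum(v == 0))
  out
}
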