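test_that("MAF filter removes rare and monomorphic markers", {
  d <- tibble::tibble(
    Marker = c("m1", "m2", "m3"), Chrom = "chr01", Position = c(100L, 200L, 300L)
  )
  doses <- matrix(0L, 3, 100, dimnames = list(NULL, sprintf("C%03d", 1:100)))
  doses[2, 1] <- 2L            # one copy pair: f = 2/400 = 0.005
  doses[3, ] <- rep(c(1L, 3L), 50)
  d <- dplyr::bind_cols(d, tibble::as_tibble(doses))
  out <- maf_filter(d, 0.01)
  expect_equal(out$Marker, "m3")
  removed <- attr(out, "removed")
  expect_equal(removed$freq[removed$Marker == "m2"], 0.005)
  # threshold 0 drops only strict monomorphs
  out0 <- maf_filter(d, 0)
  expect_setequal(out0$Marker, c("m2", "m3"))
  expect_error(maf_filter(d[1, ], 0.01), class = "envgxe_data_error")
  expect_error(maf_filter(d, 0.6), class = "envgxe_config_error")
})

test_that("kinship matches hand-computed ZZt/c and is PSD", {
  d <- tibble::tibble(Marker = c("m1", "m2"), Chrom = "chr01",
                      Position = c(1L, 2L),
                      A = c(0L, 4L), B = c(2L, 2L), C = c(4L, 0L))
  K <- kinship(d)
  Z <- scale(t(matrix(c(0, 4, 2, 2, 4, 0), nrow = 2)), center = TRUE, scale = FALSE)
  KK <- Z %*% t(Z)
  expect_equal(unname(K), unname(KK / mean(diag(KK))), tolerance = 1e-12)
  expect_equal(mean(diag(K)), 1)
  # duplicate clones give identical rows; PSD on a simulated panel
  d2 <- dplyr::mutate(d, D = .data$A)
  K2 <- kinship(d2)
  expect_equal(unname(K2["A", ]), unname(K2["D", ]))
  Kp <- kinship(small_panel$dosage)
  expect_true(isSymmetric(Kp))
  expect_gte(min(eigen(Kp, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("PCA separates duplicate groups and explains bounded variance", {
  base <- simulate_genotypes(4, 200, default_sites, seed = 81)$dosage
  G <- dosage_matrix(base)
  grp1 <- G[, rep(1, 10)] + 0L
  grp2 <- G[, rep(3, 10)] + 0L
  colnames(grp1) <- sprintf("A%02d", 1:10)
  colnames(grp2) <- sprintf("B%02d", 1:10)
  panel <- dplyr::bind_cols(marker_map(base), tibble::as_tibble(cbind(grp1, grp2)))
  pc <- dosage_pca(panel, 3)
  pc1 <- pc$scores$PC1
  expect_true(max(pc1[1:10]) < min(pc1[11:20]) || min(pc1[1:10]) > max(pc1[11:20]))
  expect_lte(sum(pc$explained), 1 + 1e-12)
  expect_true(all(diff(pc$explained) <= 1e-12))
  # unstructured panel: no dominant leading component
  pcu <- dosage_pca(small_panel$dosage, 5)
  expect_lt(pcu$explained[1], 0.2)
  expect_error(dosage_pca(small_panel$dosage, 1e4), class = "envgxe_config_error")
})

test_that("null fit collapses to OLS when K is the identity", {
  set.seed(82)
  n <- 40
  clones <- sprintf("C%02d", 1:n)
  K <- diag(n); dimnames(K) <- list(clones, clones)
  y <- rnorm(n)
  resp <- tibble::tibble(clone = clones, value = y)
  nf <- fit_null(resp, K)
  G <- matrix(rbinom(50 * n, 4, 0.4), 50, n, dimnames = list(NULL, clones))
  d <- dplyr::bind_cols(marker_map(small_panel$dosage)[1:50, ], tibble::as_tibble(G))
  sc <- score_markers(d, resp, nf)
  p_ols <- apply(G, 1, function(g) {
    if (var(g) == 0) return(1)
    summary(lm(y ~ g))$coefficients["g", "Pr(>|t|)"]
  })
  expect_lt(max(abs(sc$p - p_ols)), 1e-8)
  expect_equal(sc$lod, -log10(sc$p))
  # degenerate responses refuse
  expect_error(fit_null(tibble::tibble(clone = clones, value = 1), K),
               class = "envgxe_data_error")
})

test_that("scan equals a dense-matrix GLS oracle on a small panel", {
  g <- simulate_genotypes(18, 120, default_sites, seed = 83)
  d <- maf_filter(g$dosage)
  K <- kinship(d)
  resp <- sim_polygenic(K, h2 = 0.5, seed = 84)
  nf <- fit_null(resp, K)
  sc <- score_markers(d, resp, nf)
  p_oracle <- gls_scan_oracle(dosage_matrix(d), resp$value, K, nf$delta)
  keep <- !sc$monomorphic
  expect_lt(max(abs(sc$p[keep] - p_oracle[keep])), 1e-6)
})

test_that("null-model REML recovers heritability", {
  K <- kinship(small_panel$dosage)
  h2 <- vapply(1:8, function(i) {
    resp <- sim_polygenic(K, h2 = 0.5, seed = 100 + i)
    fit_null(resp, K)$h2
  }, numeric(1))
  expect_equal(mean(h2), 0.5, tolerance = 0.2)
})

test_that("null p-values are uniform", {
  g <- simulate_genotypes(300, 500, default_sites, seed = 85)
  d <- maf_filter(g$dosage)
  K <- kinship(d)
  resp <- sim_polygenic(K, h2 = 0.5, seed = 86)
  nf <- fit_null(resp, K)
  sc <- score_markers(d, resp, nf)
  expect_gt(suppressWarnings(ks.test(sc$p, "punif"))$p.value, 0.01)
})

test_that("effective marker count respects independence and perfect LD", {
  g <- simulate_genotypes(400, 120, default_sites, seed = 87)
  d <- g$dosage
  thr <- meff_threshold(d, 0.05)
  expect_equal(thr$m_eff, nrow(d), tolerance = 0.1)
  expect_equal(thr$threshold, -log10(0.05 / thr$m_eff))
  # duplicating every marker leaves M_eff essentially unchanged
  dup <- d
  dup$Marker <- paste0(d$Marker, "_b")
  dup$Position <- d$Position + 1L
  both <- dplyr::arrange(dplyr::bind_rows(d, dup), .data$Chrom, .data$Position)
  thr2 <- meff_threshold(both, 0.05)
  expect_equal(thr2$m_eff, thr$m_eff, tolerance = 0.02)
  expect_error(meff_threshold(d, 1.5), class = "envgxe_config_error")
})

test_that("thresholding marks significance inclusively at the boundary", {
  g <- simulate_genotypes(30, 20, default_sites, seed = 88)
  K <- kinship(g$dosage)
  resp <- sim_polygenic(K, seed = 89)
  sc <- score_markers(g$dosage, resp, fit_null(resp, K))
  thr_at <- sc$lod[3]
  sc2 <- apply_threshold(sc, thr_at)
  expect_true(sc2$significant[3])
  expect_equal(sum(sc2$significant), sum(sc2$lod >= thr_at))
  expect_error(significant_markers(sc), class = "envgxe_config_error")
})

test_that("backward-elimination PVE recovers planted orthogonal effects", {
  set.seed(90)
  n <- 800
  clones <- sprintf("C%04d", 1:n)
  g1 <- rbinom(n, 4, 0.5); g2 <- rbinom(n, 4, 0.5)
  v <- var(g1) + var(g2)
  # each marker explains ~10% of the response variance
  b <- sqrt(0.1 / var(g1))
  y <- b * g1 + b * g2 + rnorm(n, 0, sqrt(0.8))
  y <- y / sd(y)
  G <- rbind(m1 = g1, m2 = g2, m3 = rbinom(n, 4, 0.5))
  d <- dplyr::bind_cols(
    tibble::tibble(Marker = rownames(G), Chrom = "chr01", Position = c(1L, 2e6L, 4e6L)),
    tibble::as_tibble(matrix(G, 3, dimnames = list(NULL, clones)))
  )
  K <- diag(n); dimnames(K) <- list(clones, clones)
  resp <- tibble::tibble(clone = clones, value = y)
  nf <- fit_null(resp, K)
  pv <- pve_backward_elimination(resp, c("m1", "m2"), d, nf)
  expect_equal(sort(pv$pve), sort(c(10, 10)), tolerance = 0.25)
  expect_equal(attr(pv, "cumulative"), 20, tolerance = 0.15)
  # saturation: a single marker carrying nearly all signal
  y2 <- 0.3 * g1 + rnorm(n, 0, 1e-4)
  resp2 <- tibble::tibble(clone = clones, value = y2)
  pv2 <- pve_backward_elimination(resp2, "m1", d, fit_null(resp2, K))
  expect_gt(attr(pv2, "cumulative"), 99)
  # collinear duplicate is dropped with a warning
  d3 <- d; d3$Marker[3] <- "m1_dup"
  d3[3, clones] <- d3[1, clones]
  expect_warning(
    pv3 <- pve_backward_elimination(resp, c("m1", "m1_dup"), d3, nf),
    "collinear")
  expect_equal(nrow(pv3), 1)
})

test_that("case-control responses are symmetric in label choice", {
  cp <- tibble::tibble(clone = sprintf("C%03d", 1:60),
                       program = rep(c("WI", "MN"), c(20, 40)))
  r1 <- binary_response(cp, "WI")
  expect_equal(unname(attr(r1, "counts")), c(20, 40))
  expect_error(binary_response(cp, "XX"), class = "envgxe_config_error")
  expect_error(binary_response(tibble::tibble(clone = "a", program = "WI"), "WI"),
               class = "envgxe_data_error")
  # scanning the complement flips effects but keeps p-values
  panel <- simulate_genotypes(60, 40, default_sites, seed = 91)$dosage
  G <- dosage_matrix(panel)
  colnames(G) <- cp$clone
  d <- dplyr::bind_cols(marker_map(panel), tibble::as_tibble(G))
  K <- kinship(d)
  r2 <- binary_response(cp, "MN")
  s1 <- score_markers(d, r1, fit_null(r1, K))
  s2 <- score_markers(d, r2, fit_null(r2, K))
  expect_equal(abs(s1$effect), abs(s2$effect), tolerance = 1e-8)
  expect_equal(s1$p, s2$p, tolerance = 1e-8)
})
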