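# Shared fixtures and independent oracles, built in code at test time.

default_sites <- simulate_programs(10, seed = 1)

# Small genotyped panel reused across files (no planted QTL).
small_panel <- simulate_genotypes(120, 240, default_sites, seed = 42)

# Polygenic response with heritability h2 on kinship K.
sim_polygenic <- function(K, h2 = 0.5, seed = 1) {
  set.seed(seed)
  n <- nrow(K)
  L <- chol(K + diag(1e-6, n))
  u <- drop(crossprod(L, rnorm(n)))
  e <- rnorm(n, 0, sd(u) * sqrt((1 - h2) / h2))
  tibble::tibble(clone = rownames(K), value = u + e)
}

# Dense-matrix GLS oracle for the marker scan: explicit inverse of
# V = K + delta * I, matching the scan's t-test construction.
gls_scan_oracle <- function(G, y, K, delta) {
  n <- length(y)
  Vi <- solve(K + diag(delta, n))
  vapply(seq_len(nrow(G)), function(j) {
    X <- cbind(1, G[j, ])
    XtVX <- t(X) %*% Vi %*% X
    b <- solve(XtVX, t(X) %*% Vi %*% y)
    r <- y - X %*% b
    rss <- drop(t(r) %*% Vi %*% r)
    df <- n - 2  # intercept + marker
    sigma2 <- rss / df
    se <- sqrt(sigma2 * solve(XtVX)[2, 2])
    2 * pt(-abs(b[2] / se), df)
  }, numeric(1))
}

# Dense REML log-likelihood for the yield variance decomposition, used as
# an independent oracle on tiny instances.
reml_loglik_dense <- function(y, X, Zlist, vc) {
  n <- length(y)
  V <- diag(vc[["e"]], n)
  for (nm in names(Zlist)) V <- V + vc[[nm]] * tcrossprod(Zlist[[nm]])
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  b <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  as.numeric(
    -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
              t(r) %*% Vi %*% r + (n - ncol(X)) * log(2 * pi))
  )
}

# Random-effect incidence matrices for the g/gY/gL/gYL model.
yield_incidence <- function(records) {
  mk <- function(f) {
    f <- factor(f)
    Z <- matrix(0, length(f), nlevels(f))
    Z[cbind(seq_along(f), as.integer(f))] <- 1
    Z
  }
  list(
    g = mk(records$clone),
    gY = mk(paste(records$clone, records$year)),
    gL = mk(paste(records$clone, records$location)),
    gYL = mk(paste(records$clone, records$location, records$year))
  )
}
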