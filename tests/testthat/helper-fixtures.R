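# Shared fixture builders. Regions are cached per test run: the geography is
# deterministic in its config, so reuse is safe.

tiny_region <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_geography(region_config(
        n_districts = 2, n_neighbourhoods = 4, n_tracts = 40,
        n_roadside_monitors = 4, n_grid_points = 16, n_mothers = 120,
        region_extent = 10000, covariate_count = 2, seed = 11))
    cache
  }
})

desk_region <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_geography(region_config(scale = "desk", seed = 3))
    cache
  }
})

# independent logistic ML oracle: Newton-Raphson on the written log-likelihood
logistic_newton_oracle <- function(x, y, tol = 1e-12, maxit = 100) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    grad <- drop(t(X) %*% (y - p))
    H <- t(X) %*% (X * (p * (1 - p)))
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(H)))
  list(slope = unname(beta[2]), se = unname(se[2]))
}

# independent universal-kriging oracle via the GLS "dual" form:
# beta_gls = (F' C^-1 F)^-1 F' C^-1 y;  pred = f0' b + c0' C^-1 (y - F b)
uk_gls_oracle <- function(mp, mv, mX, vgm, tp, tX) {
  conv <- if (is.null(vgm$convention)) "practical" else vgm$convention
  k <- if (conv == "practical") 3 else 1
  dist2 <- function(a, b) {
    out <- matrix(0, nrow(a), nrow(b))
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
      out[i, j] <- sqrt(sum((a[i, ] - b[j, ])^2))
    out
  }
  C <- vgm$partial_sill * exp(-k * dist2(mp, mp) / vgm$range_m)
  diag(C) <- vgm$partial_sill + vgm$nugget
  c0 <- vgm$partial_sill * exp(-k * dist2(mp, tp) / vgm$range_m)
  Fm <- cbind(1, mX); F0 <- cbind(1, tX)
  Ci <- solve(C)
  b <- solve(t(Fm) %*% Ci %*% Fm, t(Fm) %*% Ci %*% mv)
  drop(F0 %*% b) + drop(t(c0) %*% Ci %*% (mv - drop(Fm %*% b)))
}
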