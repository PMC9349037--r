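test_that("the Matheron estimator matches brute-force pair arithmetic", {
  # three points in a single bin, values 0/2/4:
  # ((0-2)^2 + (0-4)^2 + (2-4)^2) / (2*3) = 4
  pts <- rbind(c(0, 0), c(10, 0), c(5, 8))
  emp <- empirical_variogram(pts, c(0, 2, 4), n_bins = 1, max_distance = 20)
  expect_equal(emp$semivariance, 4)
  expect_equal(emp$pair_count, 3L)
  # constant field: exactly zero everywhere
  emp0 <- empirical_variogram(pts, c(5, 5, 5), n_bins = 1, max_distance = 20)
  expect_equal(emp0$semivariance, 0)
  # pair counts are exhaustive within the truncation
  set.seed(1)
  p2 <- cbind(runif(40, 0, 100), runif(40, 0, 100))
  empl <- empirical_variogram(p2, rnorm(40), n_bins = 6, max_distance = 200)
  expect_equal(sum(empl$pair_count), 40 * 39 / 2)
  expect_error(empirical_variogram(pts, c(0, 2, 4), max_distance = 1),
               "no point pairs")
})

test_that("an i.i.d. field gives a flat variogram near the sample variance", {
  set.seed(10)
  pts <- cbind(runif(400, 0, 1000), runif(400, 0, 1000))
  v <- rnorm(400, 0, 3)
  emp <- empirical_variogram(pts, v, n_bins = 6)
  expect_true(all(abs(emp$semivariance - var(v)) < 0.25 * var(v)))
  fit <- fit_variogram(emp)
  expect_lt(fit$partial_sill, 0.3 * var(v))
  expect_equal(fit$nugget + fit$partial_sill, var(v), tolerance = 0.15)
})

test_that("WLS fitting recovers exact model curves to within 1%", {
  h <- seq(200, 8000, length.out = 10)
  for (truth in list(c(1.0, 30.94, 5885), c(6.86, 3.60, 1004),
                     c(5, 10, 3000))) {
    gam <- truth[1] + truth[2] * (1 - exp(-3 * h / truth[3]))
    emp <- structure(data.frame(bin_centre = h, semivariance = gam,
                                pair_count = rep(50L, 10)),
                     class = c("empirical_variogram", "data.frame"))
    fit <- fit_variogram(emp)
    expect_equal(fit$nugget, truth[1], tolerance = 0.01)
    expect_equal(fit$partial_sill, truth[2], tolerance = 0.01)
    expect_equal(fit$range_m, truth[3], tolerance = 0.01)
    expect_false(fit$fallback)
  }
})

test_that("LUR is ordinary least squares with sane diagnostics", {
  set.seed(3)
  X <- matrix(rnorm(37 * 5), 37, 5)
  beta <- c(2, -1, 0.5, 0, 1.5)
  y <- 50 + drop(X %*% beta)
  pts <- cbind(runif(37), runif(37))
  lur <- fit_lur(pts, y, X)
  expect_equal(unname(lur$coefficients), beta, tolerance = 1e-10)
  expect_equal(lur$intercept, 50, tolerance = 1e-10)
  expect_lt(lur$residual_variance, 1e-18)
  # hand-solvable 4-point, 1-covariate system via the normal equations
  x1 <- c(0, 1, 2, 3); y4 <- c(1, 3, 4, 7)
  lur4 <- fit_lur(cbind(0:3, 0), y4, matrix(x1))
  D <- cbind(1, x1)
  expect_equal(unname(c(lur4$intercept, lur4$coefficients)),
               unname(drop(solve(t(D) %*% D, t(D) %*% y4))), tolerance = 1e-12)
  expect_equal(lur4$residual_variance,
               sum((y4 - D %*% solve(t(D) %*% D, t(D) %*% y4))^2) / 2,
               tolerance = 1e-12)
  # collinear columns are named in the error
  expect_error(fit_lur(pts, y, cbind(X, X[, 1])), "collinear")
})

test_that("universal kriging matches an independent GLS-form oracle", {
  set.seed(8)
  mp <- cbind(runif(5, 0, 5000), runif(5, 0, 5000))
  mX <- matrix(rnorm(10), 5, 2)
  mv <- 50 + mX[, 1] * 2 - mX[, 2] + rnorm(5)
  vgm <- list(nugget = 1.2, partial_sill = 6, range_m = 2500,
              convention = "practical")
  tp <- cbind(c(1000, 4200), c(3000, 800))
  tX <- matrix(rnorm(4), 2, 2)
  kr <- krige_universal(mp, mv, mX, vgm, tp, tX)
  oracle <- uk_gls_oracle(mp, mv, mX, vgm, tp, tX)
  expect_equal(kr$prediction, oracle, tolerance = 1e-8)
  # unbiasedness constraint: weights sum to one per target
  expect_equal(unname(colSums(kr$weights)), c(1, 1), tolerance = 1e-10)
  expect_true(all(kr$variance >= 0))
})

test_that("kriging is an exact interpolator with zero nugget", {
  set.seed(12)
  mp <- cbind(runif(6, 0, 4000), runif(6, 0, 4000))
  mX <- matrix(rnorm(6), 6, 1)
  mv <- rnorm(6, 50, 3)
  vgm <- list(nugget = 0, partial_sill = 8, range_m = 2000)
  kr <- krige_universal(mp, mv, mX, vgm, mp, mX)
  expect_equal(kr$prediction, mv, tolerance = 1e-8)
  expect_equal(unname(kr$variance), rep(0, 6), tolerance = 1e-8)
  # kriging variance grows along a transect away from the network
  tp <- cbind(seq(0, 20000, by = 2000), 0)
  tX <- matrix(0, nrow(tp), 1)
  kv <- krige_universal(mp, mv, mX, vgm, tp, tX)$variance
  expect_gt(kv[11], kv[6])
  expect_gt(max(kv), 0.9 * 8)
})

test_that("kriging collapses to the drift regression when spatial variance vanishes", {
  set.seed(15)
  mp <- cbind(runif(12, 0, 5000), runif(12, 0, 5000))
  mX <- matrix(rnorm(24), 12, 2)
  mv <- 48 + drop(mX %*% c(1.5, -2)) + rnorm(12, 0, 0.5)
  tp <- cbind(runif(4, 0, 5000), runif(4, 0, 5000))
  tX <- matrix(rnorm(8), 4, 2)
  vgm0 <- list(nugget = 2, partial_sill = 1e-12, range_m = 2000)
  kr <- krige_universal(mp, mv, mX, vgm0, tp, tX)
  lur <- fit_lur(mp, mv, mX)
  expect_equal(kr$prediction, predict(lur, tX), tolerance = 1e-6)
})

test_that("monitor variogram estimation detrends before fitting when asked", {
  region <- desk_region()
  prm <- scenario_table()[["ES7"]]
  field <- simulate_true_exposure(region, seed = 44, params = prm)
  pts <- region$points
  mi <- pts$role %in% c("monitor_background", "monitor_roadside")
  mp <- cbind(pts$x[mi], pts$y[mi])
  raw <- estimate_monitor_variogram(mp, field$values[mi], detrend = FALSE)
  det <- estimate_monitor_variogram(mp, field$values[mi],
                                    region$covariates[mi, ], detrend = TRUE)
  # the drift inflates the apparent sill; detrending removes it
  expect_lt(det$nugget + det$partial_sill, raw$nugget + raw$partial_sill)
  expect_error(estimate_monitor_variogram(mp, field$values[mi], detrend = TRUE),
               "covariates required")
})
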