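test_that("point-set sizes match the configuration, including full scale", {
  region <- build_geography(region_config(scale = "full", seed = 2))
  counts <- table(region$points$role)
  expect_equal(unname(counts[["mother_home"]]), 46007)
  expect_equal(unname(counts[["monitor_background"]]) +
                 unname(counts[["monitor_roadside"]]), 37)
  expect_equal(unname(counts[["district_office"]]), 25)
  expect_equal(unname(counts[["neighbourhood_centre"]]), 422)
  expect_equal(unname(counts[["tract_centroid"]]), 16230)
  expect_equal(unname(counts[["grid_centroid"]]), 610)
})

test_that("geography is deterministic in the seed and varies across seeds", {
  cfg <- region_config(n_districts = 2, n_neighbourhoods = 4, n_tracts = 30,
                       n_roadside_monitors = 1, n_grid_points = 9,
                       n_mothers = 50, region_extent = 5000, seed = 99)
  a <- build_geography(cfg)
  b <- build_geography(cfg)
  expect_identical(a$points, b$points)
  expect_identical(a$covariates, b$covariates)
  cfg2 <- cfg; cfg2$seed <- 100L
  c <- build_geography(cfg2)
  expect_false(isTRUE(all.equal(a$points$x, c$points$x)))
})

test_that("district and neighbourhood membership is a consistent nesting", {
  region <- tiny_region()
  pts <- region$points
  expect_true(all(pts$x >= 0 & pts$x <= region$config$region_extent))
  expect_true(all(pts$y >= 0 & pts$y <= region$config$region_extent))
  expect_false(anyNA(pts$district))
  # tract centroids: neighbourhood's district equals the point's district
  tr <- pts[pts$role %in% c("tract_centroid", "neighbourhood_centre"), ]
  expect_equal(region$neighbourhood_district[tr$neighbourhood], tr$district)
  # one background monitor and one office per district
  for (role in c("monitor_background", "district_office"))
    expect_equal(sort(pts$district[pts$role == role]),
                 seq_len(region$config$n_districts))
  # mothers sit exactly on tract-centroid coordinates
  mo <- pts[pts$role == "mother_home", ]
  backing <- pts[match(region$mother_tract, pts$id), ]
  expect_equal(mo$x, backing$x)
  expect_equal(mo$y, backing$y)
  expect_equal(mo$district, backing$district)
})

test_that("mother sampling follows birth weights", {
  region <- tiny_region()
  cfg <- region$config
  # degenerate weights: all mass on one neighbourhood per district
  r2 <- region
  w <- r2$birth_weights
  keep_nb <- tapply(w$neighbourhood, w$district, min)
  w$weight <- ifelse(w$neighbourhood %in% keep_nb, 1, 0)
  r2$birth_weights <- w
  homes <- sample_mother_homes(r2, c(30L, 30L))
  expect_true(all(homes$points$neighbourhood %in% keep_nb))
  # exhaustive case: demand equals centroid count, without replacement
  tr <- region$points[region$points$role == "tract_centroid", ]
  demand <- as.integer(table(factor(tr$district, seq_len(cfg$n_districts))))
  all_homes <- sample_mother_homes(region, demand, replace = FALSE)
  expect_equal(sort(all_homes$tract_id), sort(tr$id))
  # infeasible without replacement
  expect_error(sample_mother_homes(region, demand + 1L, replace = FALSE),
               "without replacement")
  # equal weights: per-neighbourhood counts track tract counts (multinomial)
  r3 <- region
  r3$birth_weights$weight <- rep(1, nrow(r3$birth_weights))
  n_draw <- 4000L
  homes3 <- sample_mother_homes(r3, c(n_draw, n_draw))
  counts <- table(factor(homes3$points$neighbourhood,
                         seq_len(cfg$n_neighbourhoods)))
  tr_counts <- table(factor(tr$neighbourhood, seq_len(cfg$n_neighbourhoods)))
  expected <- n_draw * tr_counts / rep(tapply(tr_counts, region$neighbourhood_district, sum),
                                       times = table(region$neighbourhood_district))
  z <- (as.numeric(counts) - as.numeric(expected)) /
    sqrt(as.numeric(expected) * (1 - as.numeric(expected) / n_draw))
  expect_true(all(abs(z) < 4))
})

test_that("covariates are standardized, consistent, and spatially structured", {
  region <- desk_region()
  pts <- region$points
  X <- region$covariates
  tr <- pts$role == "tract_centroid"
  expect_equal(unname(colMeans(X[tr, ])), rep(0, ncol(X)), tolerance = 1e-6)
  expect_equal(unname(apply(X[tr, ], 2, sd)), rep(1, ncol(X)), tolerance = 1e-6)
  # a mother and her backing tract centroid share the identical covariate row
  mo_i <- which(pts$role == "mother_home")
  backing_i <- match(region$mother_tract, pts$id)
  expect_equal(X[mo_i[1:50], ], X[backing_i[1:50], ])
  # re-evaluating the surfaces at stored coordinates reproduces the matrix
  X2 <- eval_covariates(region$covariate_surface, pts$x[1:20], pts$y[1:20])
  expect_equal(unname(X2), unname(X[1:20, ]), tolerance = 1e-12)
  # Moran-type statistic on a 100-tract subsample, brute force: positive
  # autocorrelation at short lags
  sub <- which(tr)[seq_len(100)]
  d <- as.matrix(dist(cbind(pts$x[sub], pts$y[sub])))
  W <- (d > 0 & d < 2500) * 1
  for (j in seq_len(ncol(X))) {
    z <- X[sub, j] - mean(X[sub, j])
    moran <- (length(z) / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
    expect_gt(moran, 0)
  }
})

test_that("region export round-trips through CSV and GeoJSON", {
  region <- tiny_region()
  csv <- tempfile(fileext = ".csv")
  write_region_csv(region, csv)
  back <- read_region_csv(csv)
  expect_equal(back$x, region$points$x)
  expect_equal(back$role, region$points$role)
  gj <- tempfile(fileext = ".geojson")
  write_region_geojson(region, gj, roles = c("monitor_background", "district_office"))
  back2 <- read_region_geojson(gj)
  mon <- region_points(region, "monitor_background")
  expect_equal(back2$x[back2$role == "monitor_background"], mon$x)
  expect_equal(back2$district[back2$role == "monitor_background"], mon$district)
})

test_that("infeasible configurations are rejected", {
  expect_error(region_config(n_districts = 5, n_background_monitors = 4),
               "one urban-background monitor per district")
  expect_error(region_config(n_districts = 0), "positive")
  expect_error(region_config(n_neighbourhoods = 3, n_districts = 5),
               "at least one neighbourhood")
  # zero birth weight with positive demand
  region <- tiny_region()
  r2 <- region
  r2$birth_weights$weight <- ifelse(r2$birth_weights$district == 1, 0,
                                    r2$birth_weights$weight)
  expect_error(sample_mother_homes(r2, c(10L, 10L)), "zero total birth weight")
})
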