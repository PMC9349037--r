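test_that("nearest-monitor assignment matches exhaustive search and tie rule", {
  set.seed(4)
  mothers <- cbind(runif(10, 0, 100), runif(10, 0, 100))
  monitors <- cbind(c(10, 90, 50, 30), c(10, 90, 10, 70))
  vals <- c(40, 50, 60, 70)
  nm <- assign_nearest_monitor(mothers, monitors, vals)
  for (i in 1:10) {
    d <- apply(monitors, 1, function(m) sqrt(sum((mothers[i, ] - m)^2)))
    expect_equal(nm$values[i], vals[which.min(d)])
  }
  # single monitor: everyone gets its value
  one <- assign_nearest_monitor(mothers, monitors[1, , drop = FALSE], 42)
  expect_equal(one$values, rep(42, 10))
  # exact tie: the lower monitor index wins
  tie <- assign_nearest_monitor(rbind(c(50, 50)),
                                rbind(c(40, 50), c(60, 50)), c(1, 2))
  expect_equal(tie$values, 1)
})

test_that("IDWA reproduces hand-computed inverse-square weights", {
  # distances 100/200/400 with values 40/50/60
  mother <- rbind(c(0, 0))
  monitors <- rbind(c(100, 0), c(0, 200), c(-400, 0))
  w <- 1 / c(100, 200, 400)^2
  expected <- sum(w * c(40, 50, 60)) / sum(w)
  idwa <- assign_idwa(mother, monitors, c(40, 50, 60))
  expect_equal(idwa$values, expected, tolerance = 1e-12)
  # equidistant monitors: simple average
  sym <- assign_idwa(rbind(c(0, 0)),
                     rbind(c(50, 0), c(-50, 0), c(0, 50), c(0, -50)),
                     c(1, 2, 3, 6))
  expect_equal(sym$values, 3)
  # coincident mother-monitor: that monitor's value exactly
  co <- assign_idwa(rbind(c(100, 0)), monitors, c(40, 50, 60))
  expect_equal(co$values, 40)
})

test_that("area averaging is a per-district monitor mean", {
  # two monitors in one district average; single-monitor district passes through
  aa <- assign_area_average(mother_districts = c(1, 1, 2, 2, 2),
                            monitor_districts = c(1, 1, 2),
                            monitor_values = c(40, 60, 55))
  expect_equal(aa$values, c(50, 50, 55, 55, 55))
  # brute-force group-by oracle on a larger example
  set.seed(5)
  md <- sample(1:4, 200, replace = TRUE)
  mond <- rep(1:4, each = 3)
  mv <- rnorm(12, 50, 5)
  aa2 <- assign_area_average(md, mond, mv)
  for (d in 1:4)
    expect_equal(unique(aa2$values[md == d]),
                 mean(mv[mond == d]), tolerance = 1e-12)
  expect_error(assign_area_average(c(1, 2), c(1), c(50)),
               "no background monitor")
})

test_that("district aggregation of point predictions averages and broadcasts", {
  # hand example: predictions (48, 52, 53) in one district -> 51
  agg <- aggregate_district_mean(c(48, 52, 53, 60), c(1, 1, 1, 2),
                                 c(1, 2, 1), method = "UKCA")
  expect_equal(agg$values, c(51, 60, 51))
  # single aggregation point reduces to the pass-through office behaviour
  one <- aggregate_district_mean(c(47, 55), c(1, 2), c(2, 1, 1), "UKNA")
  ukd <- assign_uk_point(c(47, 55), mother_districts = c(2, 1, 1),
                         office_districts = c(1, 2), method = "UKD")
  expect_equal(one$values, ukd$values)
  expect_error(aggregate_district_mean(c(1), c(1), c(1, 2), "UKGA"),
               "no aggregation points")
  expect_error(assign_uk_point(c(1), mother_districts = c(1, 2),
                               office_districts = c(1), method = "UKD"),
               "missing office prediction")
})

test_that("full assignment set honours the address-condition contracts", {
  region <- desk_region()
  field <- simulate_true_exposure(region, seed = 60,
                                  params = scenario_table()[["ES8"]])
  asg <- assign_all_methods(region, field)
  expect_setequal(names(asg), method_table()$code)
  pts <- region_points(region, "mother_home")
  n_m <- nrow(pts)
  for (a in asg) expect_length(a$values, n_m)
  # district-condition methods are exactly constant within district
  for (code in c("AA", "UKD", "UKNA", "UKCA", "UKGA")) {
    per_d <- tapply(asg[[code]]$values, pts$district,
                    function(v) diff(range(v)))
    expect_equal(as.numeric(per_d), rep(0, region$config$n_districts))
  }
  # measurement-based methods stay inside the monitor value range
  bg <- field_values(field, region, "monitor_background")
  for (code in c("NM", "IDWA", "AA")) {
    expect_gte(min(asg[[code]]$values), min(bg))
    expect_lte(max(asg[[code]]$values), max(bg))
  }
  # UKD equals the kriging prediction at the office coordinates
  off <- region_points(region, "district_office")
  vgm <- attr(asg, "variogram")
  mi <- region$points$role %in% c("monitor_background", "monitor_roadside")
  kr <- krige_universal(cbind(region$points$x[mi], region$points$y[mi]),
                        field$values[mi], region$covariates[mi, ], vgm,
                        cbind(off$x, off$y),
                        region$covariates[region$points$role == "district_office", ])
  expect_equal(as.numeric(tapply(asg$UKD$values, pts$district, unique)[as.character(off$district)]),
               kr$prediction, tolerance = 1e-10)
})

test_that("model-based predictions track the truth under a dominant mean structure", {
  region <- desk_region()
  cors <- matrix(NA_real_, 5, 4,
                 dimnames = list(NULL, c("UK", "LUR", "NM", "IDWA")))
  for (r in 1:5) {
    field <- simulate_true_exposure(region, seed = 700 + r,
                                    params = scenario_table()[["ES8"]])
    asg <- assign_all_methods(region, field,
                              methods = c("NM", "IDWA", "LUR", "UK"))
    te <- asg$TE$values
    for (m in colnames(cors)) cors[r, m] <- cor(te, asg[[m]]$values)
  }
  m <- colMeans(cors)
  expect_gt(m["UK"], m["NM"])
  expect_gt(m["UK"], m["IDWA"])
  expect_gt(m["LUR"], m["NM"])
})
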