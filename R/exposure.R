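#' Exponential spatial correlation
#'
#' `convention = "practical"` reads the range parameter as the practical range
#' (correlation has decayed to exp(-3) ~ 0.05 at that distance), the dominant
#' reporting convention in air-pollution geostatistics:
#' rho(h) = exp(-3 h / range). `convention = "parameter"` uses the raw
#' exponential parameterization rho(h) = exp(-h / range).
#'
#' @param h distances, metres (vector or matrix).
#' @param range_m range parameter, metres.
#' @param convention `"practical"` (default) or `"parameter"`.
#' @return Correlations in (0, 1], same shape as `h`.
#' @export
exp_correlation <- function(h, range_m, convention = c("practical", "parameter")) {
  convention <- match.arg(convention)
  k <- if (convention == "practical") 3 else 1
  exp(-k * h / range_m)
}

euclid_dist <- function(a, b = a) {
  # plain pairwise Euclidean distances between rows of two coordinate matrices
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Covariance matrix of the exposure field
#'
#' Builds the covariance matrix implied by an exponential variogram model:
#' `partial_sill * rho(h)` between distinct points and `nugget + partial_sill`
#' on the diagonal. The nugget is point-level (measurement / micro-scale)
#' noise, so two coincident but distinct points have off-diagonal covariance
#' equal to the partial sill only.
#'
#' @param points two-column matrix (or data frame) of planar coordinates in
#'   metres.
#' @param params a `scenario_params` (or any list with `nugget`,
#'   `partial_sill`, `range_m`).
#' @param convention range convention, see [exp_correlation()].
#' @return A symmetric positive semi-definite matrix.
#' @export
#' @examples
#' p <- cbind(c(0, 1000), c(0, 0))
#' build_covariance(p, scenario_table()[["ES1"]])
build_covariance <- function(points, params,
                             convention = c("practical", "parameter")) {
  convention <- match.arg(convention)
  pts <- as.matrix(points)
  if (!all(is.finite(pts))) stop("non-finite coordinates")
  h <- euclid_dist(pts)
  C <- params$partial_sill * exp_correlation(h, params$range_m, convention)
  diag(C) <- params$nugget + params$partial_sill
  C
}

#' Precompute the simulation machinery for one scenario on one region
#'
#' The study region is fixed over all replicates, so the expensive pieces of
#' the Gaussian-random-field simulation are computed once per scenario and
#' reused: the Cholesky factor of the no-nugget covariance over the unique
#' coordinates (mothers share their tract centroid's spatially-correlated
#' component), and the drift mean calibrated to the scenario's covariate
#' variance share.
#'
#' Mean calibration: the scenario stores a target share `s` of total variance
#' for the covariate term. With empirical covariance `S` of the covariates over
#' mothers, the coefficient vector `b` (equal loadings with alternating signs)
#' is rescaled so `b' S b = s / (1 - s) * (nugget + partial_sill)`, making the
#' realised share of total variance equal to `s`.
#'
#' @param region a `study_region`.
#' @param params a `scenario_params`.
#' @param convention range convention, see [exp_correlation()].
#' @param jitter relative diagonal jitter added before factorization.
#' @return An object of class `exposure_model` holding the mean vector over
#'   all points, the Cholesky factor over unique coordinates, the map from
#'   points to unique coordinates, and the calibrated `mean_coefficients`.
#' @export
exposure_model <- function(region, params,
                           convention = c("practical", "parameter"),
                           jitter = 1e-8) {
  convention <- match.arg(convention)
  pts <- region$points
  n <- nrow(pts)

  # unique spatial support: mothers sit on tract centroids
  is_mother <- pts$role == "mother_home"
  uidx <- which(!is_mother)
  map <- integer(n)
  map[uidx] <- seq_along(uidx)
  map[is_mother] <- match(region$mother_tract, pts$id[uidx])
  if (anyNA(map)) stop("mother homes must reference tract centroids of the region")

  coords <- cbind(pts$x[uidx], pts$y[uidx])
  Lchol <- NULL
  if (params$partial_sill > 0) {
    C <- params$partial_sill *
      exp_correlation(euclid_dist(coords), params$range_m, convention)
    diag(C) <- diag(C) + jitter * params$partial_sill
    Lchol <- tryCatch(t(chol(C)), error = function(e)
      stop("covariance factorization failed for ", params$scenario_id,
           " over ", nrow(coords), " unique points: ", conditionMessage(e)))
  }

  b <- calibrate_mean_coefficients(region, params)
  mean_vec <- params$overall_mean + drop(region$covariates %*% b)

  structure(list(region = region, params = params, convention = convention,
                 mean = mean_vec, mean_coefficients = b,
                 chol_lower = Lchol, unique_map = map,
                 n_unique = length(uidx)),
            class = "exposure_model")
}

# Equal-magnitude alternating-sign loadings rescaled so the covariate term's
# variance over mothers hits the scenario's target share of total variance.
calibrate_mean_coefficients <- function(region, params) {
  p <- region$config$covariate_count
  b <- rep(c(1, -1), length.out = p)
  s <- params$mean_share
  if (s <= 0) return(numeric(p))
  target_var <- s / (1 - s) * (params$nugget + params$partial_sill)
  X <- region$covariates[region$points$role == "mother_home", , drop = FALSE]
  v0 <- drop(stats::var(drop(X %*% b)))
  if (v0 <= 0) stop("covariates carry no variance over mothers")
  b * sqrt(target_var / v0)
}

#' Simulate one true-exposure field
#'
#' Draws one realization of true annual-average PM10 at every location of the
#' region: drift mean + spatially-correlated Gaussian component (one joint
#' draw over the unique coordinates, shared by all point sets and by mothers
#' at the same tract centroid) + independent nugget noise per location
#' (including per mother).
#'
#' @param model an [exposure_model()]; alternatively a `study_region`, in which
#'   case `params` must be given and the model is built on the fly.
#' @param seed integer seed for this replicate.
#' @param params a `scenario_params`, only when `model` is a region.
#' @param replicate integer replicate index stored on the result.
#' @return An object of class `exposure_field`: list with `values` (one per
#'   region point, ug/m3), `scenario_id`, `replicate`, `seed`.
#' @export
#' @examples
#' region <- build_geography(region_config(scale = "desk", n_tracts = 50,
#'                                         n_mothers = 100, seed = 1))
#' es8 <- scenario_table()[["ES8"]]
#' field <- simulate_true_exposure(region, seed = 11, params = es8)
#' summary(field$values)
simulate_true_exposure <- function(model, seed, params = NULL, replicate = NA_integer_) {
  if (inherits(model, "study_region")) {
    if (is.null(params)) stop("params required when passing a study_region")
    model <- exposure_model(model, params)
  }
  stopifnot(inherits(model, "exposure_model"))
  prm <- model$params
  n <- length(model$mean)
  vals <- with_seed(seed, {
    spat <- if (is.null(model$chol_lower)) numeric(model$n_unique)
    else drop(model$chol_lower %*% stats::rnorm(model$n_unique))
    nug <- if (prm$nugget > 0) stats::rnorm(n, 0, sqrt(prm$nugget)) else numeric(n)
    model$mean + spat[model$unique_map] + nug
  })
  structure(list(values = vals, scenario_id = prm$scenario_id,
                 replicate = replicate, seed = seed),
            class = "exposure_field")
}

#' Field values for one point set
#'
#' @param field an `exposure_field`.
#' @param region the `study_region` the field was simulated on.
#' @param role a point-set role.
#' @return Numeric vector of concentrations at those points.
#' @export
field_values <- function(field, region, role) {
  field$values[region$points$role == role]
}

#' Write an exposure field to CSV
#'
#' @param field an `exposure_field`.
#' @param region the backing `study_region`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_exposure_csv <- function(field, region, path) {
  out <- data.frame(location_id = region$points$id, role = region$points$role,
                    x = region$points$x, y = region$points$y,
                    value = field$values, scenario = field$scenario_id,
                    replicate = field$replicate)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
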