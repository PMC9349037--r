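#' Region configuration
#'
#' Describes the synthetic study region: a square extent tessellated into
#' districts, districts subdivided into neighbourhoods, census-tract centroids
#' scattered within neighbourhoods, plus the monitoring network, district
#' offices, a regular prediction grid, and the cohort of mothers placed at
#' tract centroids.
#'
#' The full-scale default mirrors a Seoul-like metropolitan area: 25 districts,
#' 422 neighbourhoods, 16,230 census tracts, 46,007 mothers, 25 urban-background
#' plus 12 roadside monitors, 25 district offices and 610 centroids of a 1-km
#' grid on a 25 km x 25 km extent. `region_config(scale = "desk")` gives a
#' reduced configuration suitable for interactive work and testing.
#'
#' @param n_districts number of districts; one urban-background monitor and one
#'   district office are placed in each.
#' @param n_neighbourhoods number of neighbourhoods, nested within districts.
#' @param n_tracts number of census-tract centroids, nested within
#'   neighbourhoods.
#' @param n_background_monitors number of urban-background monitors; must equal
#'   `n_districts` (one per district).
#' @param n_roadside_monitors number of roadside monitors, placed uniformly
#'   over the region.
#' @param n_grid_points number of points of a regular lattice over the extent.
#' @param n_mothers total number of mothers; homes are sampled from tract
#'   centroids with birth-count weights.
#' @param region_extent side length of the square study region, metres.
#' @param covariate_count number of synthetic geographic covariates.
#' @param seed integer seed fixing the geography (placement, covariate
#'   surfaces, birth weights, mother homes).
#' @param scale `"full"` or `"desk"`: preset counts used for any argument not
#'   supplied explicitly.
#' @return An object of class `region_config` (a named list).
#' @export
#' @examples
#' cfg <- region_config(scale = "desk", seed = 7)
#' cfg$n_districts
region_config <- function(n_districts = NULL,
                          n_neighbourhoods = NULL,
                          n_tracts = NULL,
                          n_background_monitors = NULL,
                          n_roadside_monitors = NULL,
                          n_grid_points = NULL,
                          n_mothers = NULL,
                          region_extent = 25000,
                          covariate_count = 5,
                          seed = 1L,
                          scale = c("desk", "full")) {
  scale <- match.arg(scale)
  preset <- if (scale == "full") {
    list(n_districts = 25L, n_neighbourhoods = 422L, n_tracts = 16230L,
         n_roadside_monitors = 12L, n_grid_points = 610L, n_mothers = 46007L)
  } else {
    list(n_districts = 5L, n_neighbourhoods = 20L, n_tracts = 800L,
         n_roadside_monitors = 3L, n_grid_points = 100L, n_mothers = 2000L)
  }
  cfg <- list(
    n_districts = as.integer(n_districts %||% preset$n_districts),
    n_neighbourhoods = as.integer(n_neighbourhoods %||% preset$n_neighbourhoods),
    n_tracts = as.integer(n_tracts %||% preset$n_tracts),
    n_roadside_monitors = as.integer(n_roadside_monitors %||% preset$n_roadside_monitors),
    n_grid_points = as.integer(n_grid_points %||% preset$n_grid_points),
    n_mothers = as.integer(n_mothers %||% preset$n_mothers),
    region_extent = as.numeric(region_extent),
    covariate_count = as.integer(covariate_count),
    seed = as.integer(seed)
  )
  cfg$n_background_monitors <-
    as.integer(n_background_monitors %||% cfg$n_districts)
  if (cfg$n_background_monitors != cfg$n_districts)
    stop("one urban-background monitor per district is required: ",
         "n_background_monitors must equal n_districts")
  counts <- c("n_districts", "n_neighbourhoods", "n_tracts",
              "n_background_monitors", "n_roadside_monitors",
              "n_grid_points", "n_mothers", "covariate_count")
  for (nm in counts)
    if (is.na(cfg[[nm]]) || cfg[[nm]] <= 0L)
      stop("configuration count '", nm, "' must be a positive integer")
  if (!is.finite(cfg$region_extent) || cfg$region_extent <= 0)
    stop("region_extent must be positive")
  if (cfg$n_neighbourhoods < cfg$n_districts)
    stop("need at least one neighbourhood per district")
  if (cfg$n_tracts < cfg$n_neighbourhoods)
    stop("need at least one tract centroid per neighbourhood")
  class(cfg) <- "region_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.region_config <- function(x, ...) {
  cat("Region configuration (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  extent: %.1f km square\n", x$region_extent / 1000))
  cat(sprintf("  districts %d | neighbourhoods %d | tracts %d\n",
              x$n_districts, x$n_neighbourhoods, x$n_tracts))
  cat(sprintf("  monitors: %d background + %d roadside | offices %d | grid %d\n",
              x$n_background_monitors, x$n_roadside_monitors,
              x$n_districts, x$n_grid_points))
  cat(sprintf("  mothers: %d | covariates: %d\n", x$n_mothers, x$covariate_count))
  invisible(x)
}

# Partition n items into k groups as evenly as possible (first groups get the
# remainder). Deterministic.
even_split <- function(n, k) {
  base <- n %/% k
  rem <- n %% k
  base + c(rep(1L, rem), rep(0L, k - rem))
}

# Tessellate the square [0, L]^2 into exactly n near-square rectangles:
# horizontal bands, each band split into vertical strips.
tessellate_square <- function(n, L) {
  nr <- max(1L, round(sqrt(n)))
  per_band <- even_split(n, nr)
  ybreaks <- seq(0, L, length.out = nr + 1L)
  out <- vector("list", n)
  id <- 0L
  for (b in seq_len(nr)) {
    nc <- per_band[b]
    xbreaks <- seq(0, L, length.out = nc + 1L)
    for (cidx in seq_len(nc)) {
      id <- id + 1L
      out[[id]] <- c(xmin = xbreaks[cidx], xmax = xbreaks[cidx + 1L],
                     ymin = ybreaks[b], ymax = ybreaks[b + 1L])
    }
  }
  do.call(rbind, out)
}

# Subdivide one rectangle into n near-square cells (same banding scheme).
tessellate_rect <- function(n, rect) {
  w <- rect["xmax"] - rect["xmin"]
  h <- rect["ymax"] - rect["ymin"]
  # choose band count from aspect ratio so cells stay near-square
  nr <- max(1L, min(n, round(sqrt(n * h / max(w, 1e-12)))))
  per_band <- even_split(n, nr)
  ybreaks <- seq(rect["ymin"], rect["ymax"], length.out = nr + 1L)
  out <- vector("list", n)
  id <- 0L
  for (b in seq_len(nr)) {
    nc <- per_band[b]
    xbreaks <- seq(rect["xmin"], rect["xmax"], length.out = nc + 1L)
    for (cidx in seq_len(nc)) {
      id <- id + 1L
      out[[id]] <- c(xmin = xbreaks[cidx], xmax = xbreaks[cidx + 1L],
                     ymin = ybreaks[b], ymax = ybreaks[b + 1L])
    }
  }
  do.call(rbind, out)
}

runif_rect <- function(n, rect) {
  cbind(x = stats::runif(n, rect["xmin"], rect["xmax"]),
        y = stats::runif(n, rect["ymin"], rect["ymax"]))
}

#' Build a synthetic study region
#'
#' Constructs the full spatial frame used by the simulation: districts
#' tessellating the square extent, neighbourhoods nested in districts, tract
#' centroids scattered within neighbourhoods, one urban-background monitor and
#' one district office per district, roadside monitors placed uniformly, a
#' regular prediction lattice, synthetic birth-count weights per neighbourhood,
#' mothers' homes sampled from tract centroids with those weights (fixed across
#' all replicates), and smooth standardized geographic covariates evaluated
#' consistently at every location.
#'
#' @param config a [region_config()].
#' @return An object of class `study_region`: a list with elements
#'   `config`, `points` (data frame: `id`, `role`, `x`, `y`, `district`,
#'   `neighbourhood`), `covariates` (matrix, one row per point),
#'   `covariate_names`, `birth_weights` (data frame per neighbourhood),
#'   `mother_tract` (tract point id backing each mother), and the rectangles of
#'   the district/neighbourhood tessellation.
#' @details Point roles are `monitor_background`, `monitor_roadside`,
#'   `district_office`, `neighbourhood_centre`, `tract_centroid`,
#'   `grid_centroid`, `mother_home`. The build is deterministic for a fixed
#'   `config` (including `seed`).
#' @export
#' @examples
#' region <- build_geography(region_config(scale = "desk", seed = 42))
#' table(region$points$role)
build_geography <- function(config) {
  stopifnot(inherits(config, "region_config"))
  L <- config$region_extent
  with_seed(config$seed, {
    dist_rects <- tessellate_square(config$n_districts, L)
    nb_per_district <- even_split(config$n_neighbourhoods, config$n_districts)
    nb_rects <- vector("list", config$n_districts)
    nb_district <- integer(0)
    for (d in seq_len(config$n_districts)) {
      nb_rects[[d]] <- tessellate_rect(nb_per_district[d], dist_rects[d, ])
      nb_district <- c(nb_district, rep(d, nb_per_district[d]))
    }
    nb_rects <- do.call(rbind, nb_rects)

    tracts_per_nb <- even_split(config$n_tracts, config$n_neighbourhoods)
    tract_xy <- matrix(NA_real_, config$n_tracts, 2)
    tract_nb <- integer(config$n_tracts)
    pos <- 0L
    for (nb in seq_len(config$n_neighbourhoods)) {
      k <- tracts_per_nb[nb]
      tract_xy[pos + seq_len(k), ] <- runif_rect(k, nb_rects[nb, ])
      tract_nb[pos + seq_len(k)] <- nb
      pos <- pos + k
    }
    tract_district <- nb_district[tract_nb]

    bg_xy <- t(vapply(seq_len(config$n_districts),
                      function(d) drop(runif_rect(1L, dist_rects[d, ])),
                      numeric(2)))
    office_xy <- t(vapply(seq_len(config$n_districts),
                          function(d) drop(runif_rect(1L, dist_rects[d, ])),
                          numeric(2)))
    road_xy <- cbind(stats::runif(config$n_roadside_monitors, 0, L),
                     stats::runif(config$n_roadside_monitors, 0, L))

    g <- ceiling(sqrt(config$n_grid_points))
    step <- L / g
    gx <- rep(seq(step / 2, by = step, length.out = g), times = g)
    gy <- rep(seq(step / 2, by = step, length.out = g), each = g)
    grid_xy <- cbind(gx, gy)[seq_len(config$n_grid_points), , drop = FALSE]

    # neighbourhood community centres at neighbourhood rectangle centres
    nbc_xy <- cbind((nb_rects[, "xmin"] + nb_rects[, "xmax"]) / 2,
                    (nb_rects[, "ymin"] + nb_rects[, "ymax"]) / 2)

    # synthetic birth-count weights per neighbourhood (gamma-distributed:
    # right-skewed like real district birth counts, strictly positive)
    birth_w <- stats::rgamma(config$n_neighbourhoods, shape = 2, rate = 1)
    birth_weights <- data.frame(neighbourhood = seq_len(config$n_neighbourhoods),
                                district = nb_district, weight = birth_w)

    locate_district <- function(xy) {
      d <- integer(nrow(xy))
      for (i in seq_len(nrow(xy))) {
        hit <- which(xy[i, 1] >= dist_rects[, "xmin"] &
                       xy[i, 1] <= dist_rects[, "xmax"] &
                       xy[i, 2] >= dist_rects[, "ymin"] &
                       xy[i, 2] <= dist_rects[, "ymax"])
        d[i] <- hit[1L]
      }
      d
    }

    pts <- rbind(
      data.frame(role = "monitor_background", x = bg_xy[, 1], y = bg_xy[, 2],
                 district = seq_len(config$n_districts), neighbourhood = NA_integer_),
      data.frame(role = "monitor_roadside", x = road_xy[, 1], y = road_xy[, 2],
                 district = locate_district(road_xy), neighbourhood = NA_integer_),
      data.frame(role = "district_office", x = office_xy[, 1], y = office_xy[, 2],
                 district = seq_len(config$n_districts), neighbourhood = NA_integer_),
      data.frame(role = "neighbourhood_centre", x = nbc_xy[, 1], y = nbc_xy[, 2],
                 district = nb_district, neighbourhood = seq_len(config$n_neighbourhoods)),
      data.frame(role = "tract_centroid", x = tract_xy[, 1], y = tract_xy[, 2],
                 district = tract_district, neighbourhood = tract_nb),
      data.frame(role = "grid_centroid", x = grid_xy[, 1], y = grid_xy[, 2],
                 district = locate_district(grid_xy), neighbourhood = NA_integer_)
    )
    pts$id <- seq_len(nrow(pts))
    pts <- pts[, c("id", "role", "x", "y", "district", "neighbourhood")]

    region <- structure(
      list(config = config, points = pts, birth_weights = birth_weights,
           district_rects = dist_rects, neighbourhood_rects = nb_rects,
           neighbourhood_district = nb_district),
      class = "study_region")

    # mothers: fixed over the whole simulation, per-district demand
    # apportioned by total neighbourhood birth weight
    dw <- tapply(birth_weights$weight, birth_weights$district, sum)
    demand <- apportion(config$n_mothers, as.numeric(dw))
    mothers <- sample_mother_homes(region, demand)
    region$points <- rbind(pts, mothers$points)
    region$points$id <- seq_len(nrow(region$points))
    region$mother_tract <- mothers$tract_id

    cov <- generate_covariates(region)
    region$covariates <- cov$values
    region$covariate_names <- cov$covariate_names
    region$covariate_surface <- cov$surface
    region
  })
}

# Largest-remainder apportionment of n among weights (deterministic ties by
# index order).
apportion <- function(n, w) {
  if (any(w < 0) || sum(w) <= 0) stop("weights must be non-negative with positive sum")
  q <- n * w / sum(w)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(q - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Run expr with a temporary RNG state seeded by `seed`; restores the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample mothers' home locations
#'
#' Draws each district's mothers from that district's tract centroids, with
#' sampling probability proportional to the birth-count weight of the
#' centroid's neighbourhood. Sampling is with replacement by default (several
#' mothers may share a centroid). The draw is seeded from the region seed so
#' repeated calls return the identical set of homes: homes are fixed over the
#' whole simulation.
#'
#' @param region a `study_region` (mother rows not required).
#' @param per_district_counts integer vector of mothers per district.
#' @param replace sample tract centroids with replacement (default `TRUE`).
#' @return A list with `points` (data frame of `mother_home` rows) and
#'   `tract_id` (the backing tract centroid id for each mother).
#' @export
sample_mother_homes <- function(region, per_district_counts, replace = TRUE) {
  cfg <- region$config
  if (length(per_district_counts) != cfg$n_districts)
    stop("per_district_counts must have one entry per district")
  tr <- region$points[region$points$role == "tract_centroid", ]
  bw <- region$birth_weights
  wt_by_nb <- bw$weight[match(tr$neighbourhood, bw$neighbourhood)]
  out <- vector("list", cfg$n_districts)
  with_seed(cfg$seed + 1000003L, {
    for (d in seq_len(cfg$n_districts)) {
      nd <- per_district_counts[d]
      if (nd == 0L) next
      idx <- which(tr$district == d)
      w <- wt_by_nb[idx]
      if (sum(w) <= 0)
        stop("district ", d, " has positive mother demand but zero total birth weight")
      if (!replace && nd > length(idx))
        stop("district ", d, ": ", nd, " mothers requested but only ",
             length(idx), " tract centroids available without replacement")
      pick <- if (!replace && nd == length(idx)) idx
      else idx[sample.int(length(idx), nd, replace = replace, prob = w)]
      out[[d]] <- pick
    }
  })
  pick <- unlist(out)
  homes <- data.frame(id = NA_integer_, role = "mother_home",
                      x = tr$x[pick], y = tr$y[pick],
                      district = tr$district[pick],
                      neighbourhood = tr$neighbourhood[pick])
  list(points = homes[, c("id", "role", "x", "y", "district", "neighbourhood")],
       tract_id = tr$id[pick])
}

# Smooth random surface: superposed Gaussian radial-basis bumps. Two bandwidth
# regimes give broad structure plus fine-scale texture; the surface is a
# deterministic function of coordinates, so coincident points in different
# point sets get identical covariate values.
make_bump_surface <- function(extent, n_broad = 40L, n_fine = 60L) {
  n <- n_broad + n_fine
  list(cx = stats::runif(n, 0, extent),
       cy = stats::runif(n, 0, extent),
       bw = c(stats::runif(n_broad, 0.10, 0.30),
              stats::runif(n_fine, 0.02, 0.06)) * extent,
       amp = c(stats::rnorm(n_broad, 0, 1), stats::rnorm(n_fine, 0, 0.3)))
}

eval_bump_surface <- function(surf, x, y) {
  v <- numeric(length(x))
  for (k in seq_along(surf$cx)) {
    d2 <- (x - surf$cx[k])^2 + (y - surf$cy[k])^2
    v <- v + surf$amp[k] * exp(-d2 / (2 * surf$bw[k]^2))
  }
  v
}

#' Generate geographic covariates
#'
#' Synthesises `covariate_count` spatially smooth covariate surfaces (stand-ins
#' for land-use variables such as road density or impervious surface) and
#' evaluates them at every point of the region. Each column is standardized to
#' mean 0 and variance 1 over the tract centroids; being a deterministic
#' function of coordinates, a mother and a monitor at the same location get
#' identical covariate values.
#'
#' @param region a `study_region` with its point sets built.
#' @return A list with `values` (matrix, rows aligned with `region$points`),
#'   `covariate_names`, and `surface` (the bump parameters plus
#'   standardization constants, reusable via [eval_covariates()]).
#' @export
generate_covariates <- function(region) {
  cfg <- region$config
  surfaces <- with_seed(cfg$seed + 2000003L, {
    lapply(seq_len(cfg$covariate_count),
           function(j) make_bump_surface(cfg$region_extent))
  })
  pts <- region$points
  raw <- vapply(surfaces, function(s) eval_bump_surface(s, pts$x, pts$y),
                numeric(nrow(pts)))
  tr <- pts$role == "tract_centroid"
  ctr <- colMeans(raw[tr, , drop = FALSE])
  scl <- apply(raw[tr, , drop = FALSE], 2, stats::sd)
  if (any(scl <= 0)) stop("degenerate covariate surface (zero variance)")
  values <- sweep(sweep(raw, 2, ctr), 2, scl, "/")
  names <- paste0("gcov", seq_len(cfg$covariate_count))
  colnames(values) <- names
  list(values = values, covariate_names = names,
       surface = list(surfaces = surfaces, centre = ctr, scale = scl,
                      names = names))
}

#' Evaluate covariate surfaces at arbitrary coordinates
#'
#' Uses the standardization constants fixed at the region's tract centroids, so
#' values are consistent with `region$covariates`.
#'
#' @param surface the `surface` element produced by [generate_covariates()]
#'   (stored on the region as `covariate_surface`).
#' @param x,y coordinate vectors in metres.
#' @return A matrix with one standardized covariate per column.
#' @export
eval_covariates <- function(surface, x, y) {
  raw <- vapply(surface$surfaces, function(s) eval_bump_surface(s, x, y),
                numeric(length(x)))
  if (length(x) == 1L) raw <- matrix(raw, nrow = 1L)
  values <- sweep(sweep(raw, 2, surface$centre), 2, surface$scale, "/")
  colnames(values) <- surface$names
  values
}

#' @export
print.study_region <- function(x, ...) {
  cat("Synthetic study region\n")
  print(x$config)
  invisible(x)
}

#' Extract one point set from a region
#'
#' @param region a `study_region`.
#' @param role one of the point-set roles (e.g. `"mother_home"`,
#'   `"monitor_background"`).
#' @param covariates if `TRUE`, attach the covariate columns.
#' @return A data frame of the requested points.
#' @export
region_points <- function(region, role, covariates = FALSE) {
  keep <- region$points$role == role
  out <- region$points[keep, , drop = FALSE]
  if (covariates)
    out <- cbind(out, as.data.frame(region$covariates[keep, , drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' Write region point sets to CSV
#'
#' Flat export with columns `id`, `role`, `x`, `y`, `district`,
#' `neighbourhood`, plus covariate columns.
#'
#' @param region a `study_region`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_region_csv <- function(region, path) {
  out <- cbind(region$points, as.data.frame(region$covariates))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read region point sets from CSV
#'
#' @param path a file written by [write_region_csv()].
#' @return A data frame of points (with covariate columns if present).
#' @export
read_region_csv <- function(path) {
  utils::read.csv(path)
}

#' Write region point sets as GeoJSON
#'
#' Each point becomes a Point feature with `role`, `district` and
#' `neighbourhood` properties. Coordinates are the planar metre coordinates of
#' the synthetic region (no geodetic projection is implied).
#'
#' @param region a `study_region`.
#' @param path output file path.
#' @param roles which roles to export (default all).
#' @return `path`, invisibly.
#' @export
write_region_geojson <- function(region, path, roles = unique(region$points$role)) {
  pts <- region$points[region$points$role %in% roles, ]
  features <- lapply(seq_len(nrow(pts)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(pts$x[i], pts$y[i])),
         properties = list(id = pts$id[i], role = pts$role[i],
                           district = pts$district[i],
                           neighbourhood = pts$neighbourhood[i]))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read point sets from GeoJSON
#'
#' @param path a file written by [write_region_geojson()].
#' @return A data frame with `id`, `role`, `x`, `y`, `district`,
#'   `neighbourhood`.
#' @export
read_region_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  rows <- lapply(gj$features, function(f) {
    data.frame(id = f$properties$id %||% NA_integer_,
               role = f$properties$role,
               x = as.numeric(f$geometry$coordinates[[1]]),
               y = as.numeric(f$geometry$coordinates[[2]]),
               district = f$properties$district %||% NA_integer_,
               neighbourhood = f$properties$neighbourhood %||% NA_integer_)
  })
  do.call(rbind, rows)
}
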