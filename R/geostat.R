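#' Empirical semivariogram (Matheron estimator)
#'
#' For each distance bin, half the average squared difference over all point
#' pairs whose separation falls in the bin; pairs beyond `max_distance` are
#' excluded.
#'
#' @param points two-column coordinate matrix (metres).
#' @param values observations at the points.
#' @param n_bins number of equal-width distance bins (ignored when
#'   `boundaries` is given).
#' @param max_distance truncation distance; defaults to half the maximum
#'   inter-point distance.
#' @param boundaries optional increasing vector of bin edges starting above 0
#'   (an implicit first edge at 0 is prepended); use geometric spacing to
#'   resolve short-range structure from clustered designs.
#' @return An object of class `empirical_variogram`: data frame with
#'   `bin_centre`, `semivariance`, `pair_count`.
#' @export
#' @examples
#' p <- cbind(runif(30, 0, 1000), runif(30, 0, 1000))
#' empirical_variogram(p, rnorm(30), n_bins = 5)
empirical_variogram <- function(points, values, n_bins = 8, max_distance = NULL,
                                boundaries = NULL) {
  pts <- as.matrix(points)
  stopifnot(nrow(pts) >= 2, length(values) == nrow(pts))
  h <- euclid_dist(pts)
  iu <- which(upper.tri(h))
  d <- h[iu]
  g <- 0.5 * (outer(values, values, "-")^2)[iu]
  if (!is.null(boundaries)) {
    stopifnot(all(diff(boundaries) > 0), boundaries[1] > 0)
    breaks <- c(0, boundaries)
    max_distance <- max(boundaries)
  } else {
    max_distance <- max_distance %||% (max(d) / 2)
    breaks <- seq(0, max_distance, length.out = n_bins + 1L)
  }
  n_bins <- length(breaks) - 1L
  keep <- d <= max_distance & d > 0
  if (!any(keep)) stop("no point pairs within max_distance")
  d <- d[keep]; g <- g[keep]
  bin <- pmin(pmax(findInterval(d, breaks, rightmost.closed = TRUE), 1L), n_bins)
  fbin <- factor(bin, levels = seq_len(n_bins))
  sv <- tapply(g, fbin, mean)
  cnt <- tapply(g, fbin, length)
  # represent each bin by its mean pair distance, not the midpoint: pair
  # distances are not centred within a bin and the midpoint biases the fit
  ctr <- tapply(d, fbin, mean)
  out <- data.frame(bin_centre = as.numeric(ctr),
                    semivariance = as.numeric(sv),
                    pair_count = ifelse(is.na(cnt), 0L, as.integer(cnt)))
  out <- out[out$pair_count > 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("empirical_variogram", "data.frame")
  out
}

# exponential variogram model gamma(h) = nugget + psill * (1 - rho(h))
variogram_curve <- function(h, nugget, psill, range_m,
                            convention = "practical") {
  nugget + psill * (1 - exp_correlation(h, range_m, convention))
}

#' Fit an exponential variogram model
#'
#' Weighted least squares with Cressie weights: minimises
#' `sum_j N_j * (gamma_hat_j / gamma_model_j - 1)^2` over (nugget, partial
#' sill, range). A deterministic multi-start grid (default 5 x 5 x 5 over the
#' parameter box) feeds a bounded quasi-Newton refinement; the best refined
#' start wins. If every start fails, moment estimates are returned (first-bin
#' semivariance as nugget, sample sill split, half the maximum bin distance as
#' range) with `fallback = TRUE` flagged on the result.
#'
#' @param emp an [empirical_variogram()].
#' @param bounds list with `range` = c(min, max) metres; defaults to
#'   (a tenth of the smallest bin centre, 4x the largest bin centre).
#' @param convention range convention, see [exp_correlation()].
#' @param n_starts starts per parameter for the multi-start grid.
#' @param weights `"cressie"` (pair count over squared model value; the
#'   default, suited to roughly balanced bins such as equal-width bins over a
#'   monitoring network) or `"npairs_h2"` (pair count over squared distance,
#'   as in gstat's default; preferable when pair counts are strongly
#'   unbalanced across bins, e.g. geometric bins over a nested sampling
#'   design, where count-dominated long bins would otherwise swamp the
#'   short-range information).
#' @return An object of class `variogram_model`: list with `family`
#'   (`"exponential"`), `nugget`, `partial_sill`, `range_m`, `convention`,
#'   `objective`, `fallback`.
#' @export
fit_variogram <- function(emp, bounds = NULL,
                          convention = c("practical", "parameter"),
                          n_starts = 5L,
                          weights = c("cressie", "npairs_h2")) {
  convention <- match.arg(convention)
  weights <- match.arg(weights)
  stopifnot(inherits(emp, "empirical_variogram"), nrow(emp) >= 3)
  ghat <- emp$semivariance
  hbin <- emp$bin_centre
  N <- emp$pair_count
  sill0 <- max(max(ghat), 1e-12)
  rng_bounds <- bounds$range %||% c(min(hbin) / 10, 4 * max(hbin))

  k <- if (convention == "practical") 3 else 1
  obj <- if (weights == "cressie") function(th) {
    gm <- th[1] + th[2] * (1 - exp(-k * hbin / th[3]))
    gm[gm < 1e-12] <- 1e-12
    sum(N * (ghat / gm - 1)^2)
  } else {
    w_h2 <- N / hbin^2
    function(th) {
      gm <- th[1] + th[2] * (1 - exp(-k * hbin / th[3]))
      sum(w_h2 * (ghat - gm)^2)
    }
  }
  lower <- c(0, 0, rng_bounds[1])
  upper <- c(4 * sill0, 4 * sill0, rng_bounds[2])

  grid1 <- seq(0, 1, length.out = n_starts)
  starts <- expand.grid(nug = grid1 * sill0,
                        psl = pmax(grid1, 0.05) * sill0,
                        rng = exp(seq(log(rng_bounds[1] * 2),
                                      log(rng_bounds[2] / 2),
                                      length.out = n_starts)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    warning("variogram WLS failed on all starts; using moment estimates")
    svar <- max(ghat)
    return(structure(list(family = "exponential", nugget = ghat[1],
                          partial_sill = max(svar - ghat[1], 0),
                          range_m = max(hbin) / 2, convention = convention,
                          objective = NA_real_, fallback = TRUE),
                     class = "variogram_model"))
  }
  structure(list(family = "exponential", nugget = best$par[1],
                 partial_sill = best$par[2], range_m = best$par[3],
                 convention = convention, objective = best$value,
                 fallback = FALSE),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("Exponential variogram: nugget %.3f, partial sill %.3f, range %.0f m%s\n",
              x$nugget, x$partial_sill, x$range_m,
              if (isTRUE(x$fallback)) " (moment fallback)" else ""))
  invisible(x)
}

#' Fit a land use regression model
#'
#' Ordinary least squares of monitor concentrations on the geographic
#' covariates (with intercept).
#'
#' @param monitor_points two-column coordinate matrix (unused by OLS; kept for
#'   interface symmetry with the kriging fitter).
#' @param monitor_values concentrations at the monitors.
#' @param monitor_covariates covariate matrix, one row per monitor.
#' @return An object of class `lur_model`: list with `intercept`,
#'   `coefficients`, `residual_variance`, `df_residual`.
#' @export
fit_lur <- function(monitor_points, monitor_values, monitor_covariates) {
  X <- cbind(`(Intercept)` = 1, as.matrix(monitor_covariates))
  n <- length(monitor_values)
  p <- ncol(X)
  if (n <= p) stop("need more monitors than covariates + 1")
  qrX <- qr(X)
  if (qrX$rank < p) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("rank-deficient design; collinear columns: ",
         paste(drop_cols, collapse = ", "))
  }
  beta <- qr.coef(qrX, monitor_values)
  res <- monitor_values - drop(X %*% beta)
  structure(list(intercept = unname(beta[1]), coefficients = beta[-1],
                 residual_variance = sum(res^2) / (n - p),
                 df_residual = n - p),
            class = "lur_model")
}

#' @export
print.lur_model <- function(x, ...) {
  cat(sprintf("LUR: intercept %.2f, %d covariates, residual variance %.3f\n",
              x$intercept, length(x$coefficients), x$residual_variance))
  invisible(x)
}

#' Predict from a land use regression model
#'
#' @param object a `lur_model`.
#' @param covariates covariate matrix at the prediction locations.
#' @param ... unused.
#' @return Predicted concentrations.
#' @export
predict.lur_model <- function(object, covariates, ...) {
  drop(as.matrix(covariates) %*% object$coefficients) + object$intercept
}

#' Universal kriging prediction
#'
#' Solves the universal-kriging system with covariance taken from an
#' exponential variogram model and drift `[1, covariates]`: for targets `s0`,
#' the weights satisfy
#' \deqn{\begin{pmatrix} C & F \\ F' & 0 \end{pmatrix}
#'       \begin{pmatrix} \lambda \\ \mu \end{pmatrix} =
#'       \begin{pmatrix} c_0 \\ f_0 \end{pmatrix}}
#' where `C` is the monitor-monitor covariance (`partial_sill * rho(h)` off the
#' diagonal, `partial_sill + nugget` on it), and `c0` uses the nugget-free
#' covariance (the predictor targets the underlying smooth surface; with zero
#' nugget it interpolates the data exactly). The kriging variance is
#' `partial_sill - lambda' c0 - mu' f0`, clamped at zero.
#'
#' @param monitor_points monitor coordinates (metres).
#' @param monitor_values concentrations at the monitors.
#' @param monitor_covariates covariate matrix at the monitors.
#' @param vgm a `variogram_model` (or any list with `nugget`, `partial_sill`,
#'   `range_m`, optionally `convention`).
#' @param target_points target coordinates.
#' @param target_covariates covariate matrix at the targets.
#' @param jitter relative diagonal jitter applied if the system is singular.
#' @return A list with `prediction` and `variance`, one per target.
#' @export
krige_universal <- function(monitor_points, monitor_values, monitor_covariates,
                            vgm, target_points, target_covariates,
                            jitter = 1e-10) {
  conv <- vgm$convention %||% "practical"
  mp <- as.matrix(monitor_points)
  tp <- as.matrix(target_points)
  n <- nrow(mp)
  Fm <- cbind(1, as.matrix(monitor_covariates))
  F0 <- cbind(1, as.matrix(target_covariates))
  p <- ncol(Fm)

  C <- vgm$partial_sill * exp_correlation(euclid_dist(mp), vgm$range_m, conv)
  diag(C) <- vgm$partial_sill + vgm$nugget
  c0 <- vgm$partial_sill * exp_correlation(euclid_dist(mp, tp), vgm$range_m, conv)

  K <- rbind(cbind(C, Fm), cbind(t(Fm), matrix(0, p, p)))
  rhs <- rbind(c0, t(F0))
  sol <- tryCatch(solve(K, rhs), error = function(e) {
    K2 <- K
    diag(K2)[seq_len(n)] <- diag(K2)[seq_len(n)] +
      jitter * max(vgm$partial_sill + vgm$nugget, 1)
    tryCatch(solve(K2, rhs), error = function(e2)
      stop("singular universal-kriging system: ", conditionMessage(e2)))
  })
  lambda <- sol[seq_len(n), , drop = FALSE]
  mu <- sol[n + seq_len(p), , drop = FALSE]
  pred <- drop(crossprod(lambda, monitor_values))
  kv <- vgm$partial_sill - colSums(lambda * c0) - colSums(mu * t(F0))
  list(prediction = pred, variance = pmax(kv, 0), weights = lambda)
}

#' Estimate a variogram model from monitor data
#'
#' Convenience wrapper for the per-replicate prediction step: optionally
#' detrends the monitor values by OLS on the covariates (standard universal
#' kriging practice when the field has a covariate-driven mean), computes the
#' empirical variogram of the (residual) values, and fits the exponential
#' model by weighted least squares.
#'
#' @param monitor_points monitor coordinates.
#' @param monitor_values concentrations at the monitors.
#' @param monitor_covariates covariate matrix at the monitors (needed when
#'   `detrend = TRUE`).
#' @param detrend remove an OLS covariate trend before variogram estimation.
#' @param n_bins,max_distance passed to [empirical_variogram()].
#' @param ... passed to [fit_variogram()].
#' @return A `variogram_model`.
#' @export
estimate_monitor_variogram <- function(monitor_points, monitor_values,
                                       monitor_covariates = NULL,
                                       detrend = FALSE, n_bins = 8,
                                       max_distance = NULL, ...) {
  v <- monitor_values
  if (detrend) {
    if (is.null(monitor_covariates)) stop("covariates required to detrend")
    lur <- fit_lur(monitor_points, monitor_values, monitor_covariates)
    v <- monitor_values - predict(lur, monitor_covariates)
  }
  emp <- empirical_variogram(monitor_points, v, n_bins = n_bins,
                             max_distance = max_distance)
  fit_variogram(emp, ...)
}
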