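#' Fit the logistic health-effect model
#'
#' Maximum-likelihood logistic regression of the binary low-birth-weight
#' status on assigned exposure (intercept + slope), with Wald 95% confidence
#' interval and two-sided p-value for the slope.
#'
#' @param exposure assigned exposure per mother, ug/m3.
#' @param outcomes 0/1 status per mother (an `outcome_vector` or a plain
#'   vector).
#' @param conf_level confidence level of the Wald interval.
#' @return An object of class `health_fit`: list with `slope` (log-odds per
#'   ug/m3), `se`, `ci_low`, `ci_high`, `p_value`, `rr` (`= exp(slope)`),
#'   `converged`, `n`.
#' @export
fit_health_model <- function(exposure, outcomes, conf_level = 0.95) {
  y <- if (inherits(outcomes, "outcome_vector")) outcomes$status else outcomes
  stopifnot(length(exposure) == length(y), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  if (stats::sd(exposure) == 0) stop("exposure is constant; slope not identifiable")
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, exposure), y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12, maxit = 50)))
  beta <- fit$coefficients[2]
  # Wald covariance from the weighted least-squares normal equations
  W <- fit$weights
  X <- cbind(1, exposure)
  XtWX <- crossprod(X * sqrt(W))
  vc <- tryCatch(solve(XtWX), error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(vc[2, 2])
  converged <- isTRUE(fit$converged) && is.finite(beta) && is.finite(se) && se > 0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(slope = unname(beta), se = unname(se),
                 ci_low = unname(beta - z * se), ci_high = unname(beta + z * se),
                 p_value = unname(2 * stats::pnorm(-abs(beta / se))),
                 rr = unname(exp(beta)), converged = converged,
                 n = length(y)),
            class = "health_fit")
}

#' @export
print.health_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (n = %d): slope %.5f (SE %.5f), RR %.4f, 95%% CI [%.5f, %.5f], p = %.3g%s\n",
              x$n, x$slope, x$se, x$rr, x$ci_low, x$ci_high, x$p_value,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Operating characteristics of replicated health-effect fits
#'
#' Aggregates a list of per-replicate logistic fits into the standard
#' Monte-Carlo performance measures, all on the log-odds (slope) scale:
#' bias = mean(slope) - true_beta; RMSE = sqrt(mean((slope - true_beta)^2));
#' ASE = mean(se); CP = fraction of 95% CIs containing true_beta;
#' mean RR = mean(exp(slope)). For display, bias, RMSE and ASE are also
#' reported multiplied by `scale_factor` (100 by default, matching the usual
#' presentation of effects of this magnitude). Non-converged fits are excluded
#' and counted.
#'
#' @param fits list of `health_fit`s.
#' @param true_beta the generating log-odds slope.
#' @param scale_factor display multiplier for bias/RMSE/ASE.
#' @return A one-row data frame of class `perf_summary`: `mean_rr`, `bias`,
#'   `rmse`, `ase`, `cp`, `bias100`, `rmse100`, `ase100`, `n_replicates`,
#'   `n_excluded`.
#' @export
summarize_performance <- function(fits, true_beta, scale_factor = 100) {
  if (!length(fits)) stop("no fits to summarize")
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) stop("no converged fits to summarize")
  excluded <- sum(!ok)
  fits <- fits[ok]
  slope <- vapply(fits, `[[`, numeric(1), "slope")
  se <- vapply(fits, `[[`, numeric(1), "se")
  lo <- vapply(fits, `[[`, numeric(1), "ci_low")
  hi <- vapply(fits, `[[`, numeric(1), "ci_high")
  bias <- mean(slope) - true_beta
  rmse <- sqrt(mean((slope - true_beta)^2))
  out <- data.frame(mean_rr = mean(exp(slope)), bias = bias, rmse = rmse,
                    ase = mean(se),
                    cp = mean(lo <= true_beta & true_beta <= hi),
                    bias100 = scale_factor * bias, rmse100 = scale_factor * rmse,
                    ase100 = scale_factor * mean(se),
                    n_replicates = length(fits), n_excluded = excluded)
  class(out) <- c("perf_summary", "data.frame")
  out
}

#' True positive rate of a prediction method
#'
#' Ratio of the number of replicates with a significantly positive slope
#' (two-sided p < `alpha` and slope > 0) using the predicted exposure to the
#' number using the true exposure.
#'
#' @param fits_predicted list of `health_fit`s from predicted exposure.
#' @param fits_true list of `health_fit`s from true exposure, same replicates.
#' @param alpha significance level.
#' @return The rate; `NA` with attribute `undefined = TRUE` when no replicate
#'   is significant under true exposure.
#' @export
compute_tpr <- function(fits_predicted, fits_true, alpha = 0.05) {
  stopifnot(length(fits_predicted) == length(fits_true))
  sig_pos <- function(f) isTRUE(f$converged) && f$slope > 0 && f$p_value < alpha
  num <- sum(vapply(fits_predicted, sig_pos, logical(1)))
  den <- sum(vapply(fits_true, sig_pos, logical(1)))
  if (den == 0) return(structure(NA_real_, undefined = TRUE))
  num / den
}
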