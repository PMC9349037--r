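#' Health model parameters
#'
#' The binary low-birth-weight (LBW) outcome follows an inverse-logit
#' (logistic) model in true PM10 exposure:
#' `P(LBW) = plogis(alpha + beta * x)` with `beta = log(true_rr)` per ug/m3.
#' The intercept `alpha` is not a free parameter; it is calibrated per
#' replicate by [calibrate_intercept()] so the cohort-average LBW probability
#' equals `baseline_prevalence`.
#'
#' @param true_rr true relative risk per 1 ug/m3 of PM10 (default 1.0033).
#' @param baseline_prevalence target LBW proportion in the cohort
#'   (default 0.05).
#' @return An object of class `health_params` with `true_rr`, `true_beta`
#'   (`= log(true_rr)`), `baseline_prevalence`.
#' @export
health_params <- function(true_rr = 1.0033, baseline_prevalence = 0.05) {
  if (true_rr <= 0) stop("true_rr must be positive")
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1)
    stop("baseline_prevalence must be in (0, 1)")
  structure(list(true_rr = true_rr, true_beta = log(true_rr),
                 baseline_prevalence = baseline_prevalence),
            class = "health_params")
}

#' Calibrate the logistic intercept to the target prevalence
#'
#' Finds the intercept `alpha` such that the mean of
#' `plogis(alpha + true_beta * x)` over the supplied exposures equals the
#' baseline prevalence. The mean is strictly increasing in `alpha`, so a
#' bracketed monotone root find converges to the stated tolerance.
#'
#' @param true_exposure exposures of the cohort, ug/m3.
#' @param params a [health_params()].
#' @param tol absolute tolerance on the achieved mean probability.
#' @return The intercept (log-odds scale).
#' @export
#' @examples
#' hp <- health_params()
#' a <- calibrate_intercept(rnorm(1000, 52, 5), hp)
calibrate_intercept <- function(true_exposure, params, tol = 1e-10) {
  stopifnot(all(is.finite(true_exposure)))
  p0 <- params$baseline_prevalence
  b <- params$true_beta
  if (b == 0) return(stats::qlogis(p0))
  f <- function(a) mean(stats::plogis(a + b * true_exposure)) - p0
  span <- abs(b) * max(abs(true_exposure)) + 1
  lo <- stats::qlogis(p0) - span
  hi <- stats::qlogis(p0) + span
  if (f(lo) > 0 || f(hi) < 0) stop("no intercept root in bracket")
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' Generate low-birth-weight outcomes
#'
#' Independent Bernoulli draws with `p_i = plogis(alpha + true_beta * x_i)`.
#'
#' @param true_exposure mothers' true exposures, ug/m3.
#' @param params a [health_params()].
#' @param seed integer seed for this replicate.
#' @param intercept optional pre-calibrated intercept; computed by
#'   [calibrate_intercept()] when missing.
#' @param replicate replicate index stored on the result.
#' @return An object of class `outcome_vector`: list with `status` (0/1 per
#'   mother), `intercept`, `replicate`, `seed`.
#' @export
generate_outcomes <- function(true_exposure, params, seed,
                              intercept = NULL, replicate = NA_integer_) {
  a <- intercept %||% calibrate_intercept(true_exposure, params)
  p <- stats::plogis(a + params$true_beta * true_exposure)
  status <- with_seed(seed, stats::rbinom(length(p), 1L, p))
  structure(list(status = status, intercept = a,
                 replicate = replicate, seed = seed),
            class = "outcome_vector")
}

#' Write outcomes to CSV
#'
#' @param outcomes an `outcome_vector`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_outcomes_csv <- function(outcomes, path) {
  out <- data.frame(mother_id = seq_along(outcomes$status),
                    status = outcomes$status, replicate = outcomes$replicate)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
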