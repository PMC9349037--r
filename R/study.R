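#' Study configuration
#'
#' Bundles everything one Monte-Carlo experiment needs: the region
#' configuration, the environmental scenarios and prediction methods to run,
#' the number of replicates, the health-model parameters and the master seed.
#'
#' @param region a [region_config()] (or a pre-built `study_region`).
#' @param scenarios character vector of scenario ids (subset of ES1-ES8) or a
#'   list of `scenario_params`.
#' @param methods subset of the method codes in [method_table()].
#' @param n_replicates replicates per scenario.
#' @param master_seed master seed; per-(scenario, replicate) seeds are derived
#'   by a fixed counter scheme, so results are independent of execution order.
#' @param health a [health_params()].
#' @param detrend_variogram detrend monitor values before per-replicate
#'   variogram estimation (see [estimate_monitor_variogram()]).
#' @param convention variogram range convention, see [exp_correlation()].
#' @return An object of class `study_config`.
#' @export
study_config <- function(region = region_config(),
                         scenarios = names(scenario_table()),
                         methods = method_table()$code,
                         n_replicates = 1000L,
                         master_seed = 1L,
                         health = health_params(),
                         detrend_variogram = TRUE,
                         convention = c("practical", "parameter")) {
  convention <- match.arg(convention)
  if (is.character(scenarios)) {
    tab <- scenario_table()
    bad <- setdiff(scenarios, names(tab))
    if (length(bad)) stop("unknown scenario(s): ", paste(bad, collapse = ", "))
    scenarios <- tab[scenarios]
  }
  bad <- setdiff(setdiff(methods, "TE"), method_table()$code)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  structure(list(region = region, scenarios = scenarios, methods = methods,
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed), health = health,
                 detrend_variogram = detrend_variogram,
                 convention = convention),
            class = "study_config")
}

#' Per-replicate seed derivation
#'
#' Deterministic counter-based split of the master seed: replicate seeds
#' depend only on (master seed, scenario index, replicate index), never on
#' execution order, so sequential and scenario-parallel runs agree.
#'
#' @param master_seed master seed.
#' @param scenario_index 1-based scenario position.
#' @param replicate 1-based replicate index.
#' @return An integer seed (below 2^31).
#' @export
replicate_seed <- function(master_seed, scenario_index, replicate) {
  as.integer((as.numeric(master_seed) * 97003 + scenario_index * 1500007 +
                replicate * 131) %% 2147483629)
}

#' Run one simulation replicate
#'
#' One full pass of the pipeline for one scenario: simulate the true-exposure
#' field, generate low-birth-weight outcomes from the mothers' true exposures,
#' compute every requested exposure assignment, and fit the logistic
#' health-effect model per method.
#'
#' @param model an [exposure_model()] (region + scenario, factorization
#'   cached); alternatively a `study_region` with `params` supplied.
#' @param health a [health_params()].
#' @param seed the replicate seed (see [replicate_seed()]).
#' @param methods method codes to evaluate.
#' @param params `scenario_params` when `model` is a region.
#' @param detrend_variogram see [assign_all_methods()].
#' @param replicate replicate index recorded on the results.
#' @return A list with `fits` (named list of `health_fit` per method, `TE`
#'   included), `assignments`, `variogram` (the per-replicate monitor fit, if
#'   kriging ran), `seed`.
#' @export
run_replicate <- function(model, health, seed, methods = method_table()$code,
                          params = NULL, detrend_variogram = TRUE,
                          replicate = NA_integer_) {
  if (inherits(model, "study_region"))
    model <- exposure_model(model, params)
  region <- model$region
  field <- simulate_true_exposure(model, seed = seed, replicate = replicate)
  te <- field_values(field, region, "mother_home")
  outcomes <- generate_outcomes(te, health, seed = seed + 1L,
                                replicate = replicate)
  assignments <- assign_all_methods(region, field, methods = methods,
                                    detrend_variogram = detrend_variogram)
  fits <- lapply(assignments, function(a) {
    tryCatch(fit_health_model(a$values, outcomes), error = function(e)
      # degenerate assignment (e.g. constant exposure): a non-converged
      # placeholder that summaries exclude and count
      structure(list(slope = NA_real_, se = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_, p_value = NA_real_, rr = NA_real_,
                     converged = FALSE, n = length(a$values),
                     error = conditionMessage(e)),
                class = "health_fit"))
  })
  list(fits = fits, assignments = assignments,
       variogram = attr(assignments, "variogram"), seed = seed,
       replicate = replicate)
}

fits_to_rows <- function(fits, scenario_id, replicate, seed) {
  do.call(rbind, lapply(names(fits), function(m) {
    f <- fits[[m]]
    data.frame(scenario = scenario_id, replicate = replicate, seed = seed,
               method = m, slope = f$slope, se = f$se, ci_low = f$ci_low,
               ci_high = f$ci_high, p_value = f$p_value, rr = f$rr,
               converged = f$converged)
  }))
}

rows_to_fits <- function(rows) {
  lapply(seq_len(nrow(rows)), function(i)
    structure(list(slope = rows$slope[i], se = rows$se[i],
                   ci_low = rows$ci_low[i], ci_high = rows$ci_high[i],
                   p_value = rows$p_value[i], rr = rows$rr[i],
                   converged = rows$converged[i], n = NA_integer_),
              class = "health_fit"))
}

#' Run the full Monte-Carlo study
#'
#' Executes the factorial experiment scenario-by-scenario: the study region is
#' built once (mothers' homes fixed over the whole simulation), the Gaussian
#' random field machinery is factorized once per scenario, and each replicate
#' runs exposure generation, outcome generation, all exposure assignments and
#' the logistic fits. Per-method x scenario operating characteristics are then
#' aggregated with [summarize_performance()] and [compute_tpr()].
#'
#' @param config a [study_config()].
#' @param checkpoint_dir optional directory: per-replicate fit rows are
#'   appended to `fits_<scenario>.csv` as they complete, and a rerun resumes
#'   from whatever is already there (identical results to an uninterrupted
#'   run, since seeds are per-replicate).
#' @param verbose print progress lines.
#' @return An object of class `addr_study`: list with `summary` (data frame,
#'   one row per method x scenario: mean RR, bias/rmse/ase x100, CP, TPR),
#'   `fits` (data frame of per-replicate fit rows), `manifest`, `config`,
#'   `region`.
#' @export
#' @examples
#' \donttest{
#' cfg <- study_config(region_config(scale = "desk", n_tracts = 100,
#'                                   n_mothers = 300, seed = 1),
#'                     scenarios = "ES8", methods = c("TE", "AA"),
#'                     n_replicates = 20, master_seed = 9)
#' st <- run_study(cfg)
#' st$summary
#' }
run_study <- function(config, checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  t0 <- Sys.time()
  region <- if (inherits(config$region, "study_region")) config$region
  else build_geography(config$region)
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE)

  all_rows <- list()
  warnings <- list()
  scen_names <- vapply(config$scenarios, `[[`, character(1), "scenario_id")
  for (si in seq_along(config$scenarios)) {
    prm <- config$scenarios[[si]]
    # seed on the scenario's global identity, not its position in this run,
    # so a subset run reproduces the same replicates
    si_seed <- match(prm$scenario_id, names(scenario_table()))
    if (is.na(si_seed)) si_seed <- 100L + si
    model <- exposure_model(region, prm, convention = config$convention)
    ckpt <- if (!is.null(checkpoint_dir))
      file.path(checkpoint_dir, paste0("fits_", prm$scenario_id, ".csv"))
    done <- NULL
    if (!is.null(ckpt) && file.exists(ckpt)) {
      done <- utils::read.csv(ckpt)
      done <- done[done$replicate <= config$n_replicates, , drop = FALSE]
    }
    done_reps <- unique(done$replicate)
    rows <- if (!is.null(done) && nrow(done)) list(done) else list()
    n_fallback <- 0L
    for (r in seq_len(config$n_replicates)) {
      if (r %in% done_reps) next
      seed <- replicate_seed(config$master_seed, si_seed, r)
      rep_out <- run_replicate(model, config$health, seed,
                               methods = config$methods,
                               detrend_variogram = config$detrend_variogram,
                               replicate = r)
      if (!is.null(rep_out$variogram) && isTRUE(rep_out$variogram$fallback))
        n_fallback <- n_fallback + 1L
      rr <- fits_to_rows(rep_out$fits, prm$scenario_id, r, seed)
      rows[[length(rows) + 1L]] <- rr
      if (!is.null(ckpt))
        utils::write.table(rr, ckpt, sep = ",", row.names = FALSE,
                           col.names = !file.exists(ckpt), append = file.exists(ckpt))
      if (verbose && r %% 100 == 0)
        message(sprintf("%s: replicate %d/%d", prm$scenario_id, r,
                        config$n_replicates))
    }
    scen_rows <- do.call(rbind, rows)
    scen_rows <- scen_rows[order(scen_rows$replicate), , drop = FALSE]
    all_rows[[si]] <- scen_rows
    warnings[[prm$scenario_id]] <-
      list(variogram_fallbacks = n_fallback,
           non_converged = sum(!scen_rows$converged))
  }
  fits <- do.call(rbind, all_rows)
  rownames(fits) <- NULL

  summary_tab <- summarize_study_fits(fits, config$health$true_beta)
  manifest <- list(
    package_version = as.character(utils::packageVersion("addrsim")),
    master_seed = config$master_seed,
    n_replicates = config$n_replicates,
    scenarios = scen_names, methods = config$methods,
    region_seed = region$config$seed,
    region_counts = region$config[grep("^n_", names(region$config))],
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    warnings = warnings)
  structure(list(summary = summary_tab, fits = fits, manifest = manifest,
                 config = config, region = region),
            class = "addr_study")
}

#' Recompute the summary table from per-replicate fit rows
#'
#' @param fits data frame of fit rows (as in `addr_study$fits` or a
#'   checkpoint CSV).
#' @param true_beta generating log-odds slope.
#' @return Data frame, one row per method x scenario, with operating
#'   characteristics and TPR (relative to the TE fits of the same scenario).
#' @export
summarize_study_fits <- function(fits, true_beta) {
  out <- list()
  cond <- stats::setNames(method_table()$address_condition, method_table()$code)
  for (sc in unique(fits$scenario)) {
    sub <- fits[fits$scenario == sc, , drop = FALSE]
    te_fits <- rows_to_fits(sub[sub$method == "TE", , drop = FALSE])
    for (m in unique(sub$method)) {
      mf <- rows_to_fits(sub[sub$method == m, , drop = FALSE])
      s <- summarize_performance(mf, true_beta)
      tpr <- if (length(te_fits)) compute_tpr(mf, te_fits) else NA_real_
      out[[length(out) + 1L]] <- cbind(
        data.frame(scenario = sc, method = m,
                   address_condition = unname(cond[m])), s,
        data.frame(tpr = as.numeric(tpr)))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.addr_study <- function(x, digits = 4, ...) {
  cat("Monte-Carlo address-availability study\n")
  cat(sprintf("  scenarios: %s | replicates: %d | mothers: %d\n",
              paste(x$manifest$scenarios, collapse = ", "),
              x$manifest$n_replicates,
              sum(x$region$points$role == "mother_home")))
  tab <- x$summary[, c("scenario", "method", "address_condition", "mean_rr",
                       "bias100", "rmse100", "ase100", "cp", "tpr")]
  print(format(tab, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.addr_study <- function(object, ...) object$summary

#' Plot method-wise bias of a study
#'
#' Barplot of bias x100 per method, one panel per scenario; complete-address
#' methods in grey, district-level methods in red.
#'
#' @param x an `addr_study`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.addr_study <- function(x, ...) {
  tab <- x$summary
  scens <- unique(tab$scenario)
  oldpar <- graphics::par(mfrow = c(1, length(scens)))
  on.exit(graphics::par(oldpar))
  for (sc in scens) {
    sub <- tab[tab$scenario == sc, ]
    cols <- ifelse(sub$address_condition == "district", "firebrick",
                   ifelse(sub$address_condition == "truth", "steelblue", "grey60"))
    graphics::barplot(sub$bias100, names.arg = sub$method, col = cols,
                      main = sc, ylab = "bias x 100 (log-odds)", las = 2, ...)
    graphics::abline(h = 0)
  }
  invisible(x)
}

#' Write the study summary table to CSV
#'
#' One row per method x scenario with the Table-2-style columns: mean RR,
#' bias x100, RMSE x100, ASE x100, CP and TPR.
#'
#' @param study an `addr_study`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(study, path) {
  tab <- study$summary[, c("scenario", "method", "address_condition",
                           "mean_rr", "bias100", "rmse100", "ase100", "cp",
                           "tpr", "n_replicates", "n_excluded")]
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write the run manifest as JSON
#'
#' @param study an `addr_study`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_manifest_json <- function(study, path) {
  jsonlite::write_json(study$manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a study configuration from a YAML file
#'
#' The file may contain `region` (fields of [region_config()]), `scenarios`,
#' `methods`, `n_replicates`, `master_seed`, and `health`
#' (`true_rr`, `baseline_prevalence`).
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files")
  y <- yaml::read_yaml(path)
  region <- do.call(region_config, y$region %||% list())
  health <- do.call(health_params, y$health %||% list())
  study_config(region = region,
               scenarios = y$scenarios %||% names(scenario_table()),
               methods = y$methods %||% method_table()$code,
               n_replicates = y$n_replicates %||% 1000L,
               master_seed = y$master_seed %||% 1L,
               health = health,
               detrend_variogram = y$detrend_variogram %||% TRUE)
}
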