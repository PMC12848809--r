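#' Simulate the synthetic trial arms of a configuration
#'
#' For each strategy and endpoint, draws an arm from the configured ground
#' truth, computes the KM estimate with its risk table, emulates figure
#' digitization, and (when `out_dir` is given) writes the
#' `{strategy}_{endpoint}_curve.csv` / `_risk.csv` pairs. Per-arm seeds are
#' derived deterministically from the scenario seed, so reruns are
#' byte-identical.
#'
#' @param config a `cea_config` (see [default_config()]).
#' @param out_dir optional output directory for the CSV pairs.
#' @return named list (per strategy) of lists with elements `PFS` and `OS`:
#'   each a list with the `truth`, the raw `records`, the exact `km` curve
#'   and the `digitized` curve.
#' @export
cea_simulate <- function(config, out_dir = NULL) {
  syn <- config$synthetic
  if (is.null(syn)) stop("configuration has no synthetic block", call. = FALSE)
  if (syn$n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  out <- list()
  strategies <- names(config$strategies)
  for (si in seq_along(strategies)) {
    s <- strategies[si]
    block <- config$strategies[[s]]$synthetic
    arms <- list()
    for (ei in 1:2) {
      endpoint <- c("PFS", "OS")[ei]
      med <- if (endpoint == "PFS") block$pfs_median else block$os_median
      arm_seed <- syn$seed + 100L * si + ei
      truth <- trial_arm_truth(syn$family,
                               params = c(rate = log(2) / med),
                               n_patients = syn$n_patients,
                               max_follow_up = block$follow_up,
                               seed = arm_seed,
                               dropout_rate = syn$dropout_rate)
      records <- simulate_arm(truth)
      km <- km_estimate(records,
                        risk_times = seq(0, block$follow_up, by = syn$risk_every),
                        endpoint = endpoint, strategy_id = s)
      dig <- emit_digitized(km, n_points = syn$digitize$n_points,
                            jitter_sd = syn$digitize$jitter_sd,
                            seed = arm_seed + 5000L)
      if (!is.null(out_dir)) write_digitized_curve(dig, out_dir)
      arms[[endpoint]] <- list(truth = truth, records = records,
                               km = km, digitized = dig)
    }
    out[[s]] <- arms
  }
  invisible(out)
}

#' Reconstruct and fit all survival curves of a scenario
#'
#' Runs the Guyot reconstruction on each digitized curve, fits the five
#' parametric families to the pseudo-IPD and selects the extrapolation
#' model per the configured policy.
#'
#' @param curves per-strategy list of digitized curves, as produced by
#'   [cea_simulate()] (the `digitized` elements) or assembled from
#'   [read_digitized_curve()].
#' @param config a `cea_config`.
#' @return per-strategy list with, per endpoint, the reconstruction report
#'   (QC fields filled), all five fits, and the selected fit.
#' @export
fit_scenario <- function(curves, config) {
  lapply(curves, function(arms) {
    lapply(arms, function(a) {
      dig <- if (inherits(a, "digitized_curve")) a else a$digitized
      use_tot <- isTRUE(config$guyot$use_total_events) && !is.null(dig$total_events)
      rec <- reconstruct_ipd(dig, use_total_events = use_tot)
      rec <- validate_reconstruction(dig, rec)
      fits <- lapply(surv_families(), function(f) fit_parametric(rec$ipd, f))
      names(fits) <- surv_families()
      list(reconstruction = rec, fits = fits,
           selected = select_best(fits, config$selection_policy))
    })
  })
}

#' Assemble the model context
#'
#' Binds selected survival fits, configuration parameters and cohort traces
#' into the object the economic layer evaluates. The traces depend only on
#' the survival fits and the time settings, so they are computed once here
#' and reused across one-way and probabilistic sensitivity runs (which vary
#' costs and utilities only).
#'
#' @param fitted result of [fit_scenario()] (or any per-strategy list with
#'   `selected` fits per endpoint).
#' @param config a `cea_config`.
#' @return list with `config`, `settings`, `strategies` (list of
#'   [strategy_spec()]), `traces`, `base_params`.
#' @export
build_context <- function(fitted, config) {
  params <- econ_param_base(config)
  settings <- settings_from_params(config, params)
  strategies <- lapply(names(config$strategies), function(s) {
    spec_from_params(config, s, params,
                     pfs_fit = fitted[[s]]$PFS$selected,
                     os_fit = fitted[[s]]$OS$selected)
  })
  names(strategies) <- names(config$strategies)
  traces <- lapply(strategies, run_cohort, settings = settings)
  list(config = config, settings = settings, strategies = strategies,
       traces = traces, base_params = params)
}

settings_from_params <- function(config, params) {
  model_settings(cycle_len = config$settings$cycle_len,
                 horizon_cycles = config$settings$horizon_cycles,
                 annual_discount_rate = params[["discount_rate"]],
                 utility_pf = params[["utility_pf"]],
                 utility_pd = params[["utility_pd"]],
                 wtp_per_qaly = wtp_threshold(config),
                 half_cycle_correction = config$settings$half_cycle_correction)
}

spec_from_params <- function(config, name, params, pfs_fit, os_fit) {
  strategy_spec(
    name = name,
    drug_cost_per_cycle = params[[paste0("cost_drug_", name)]],
    chemo_cost_per_cycle = params[["cost_pemetrexed"]] + params[["cost_carboplatin"]],
    maintenance_cost_per_cycle = params[["cost_pemetrexed"]],
    admin_cost_per_cycle = params[["cost_admin"]],
    ae_profile = config$strategies[[name]]$ae_profile,
    ae_unit_costs = c(neutropenia = params[["cost_ae_neutropenia"]],
                      leukopenia = params[["cost_ae_leukopenia"]],
                      thrombocytopenia = params[["cost_ae_thrombocytopenia"]],
                      anemia = params[["cost_ae_anemia"]]),
    second_line_cost_per_cycle = params[["cost_second_line"]],
    pfs_fit = pfs_fit, os_fit = os_fit,
    max_treatment_cycles = config$settings$max_treatment_cycles,
    chemo_cycles = config$settings$chemo_cycles)
}

#' Evaluate all strategies under (possibly overridden) parameters
#'
#' Rebuilds the strategy specifications and settings from the base
#' parameters with `overrides` applied, then accumulates costs and QALYs
#' over the cached cohort traces. Overriding the discount rate or utilities
#' re-prices the same traces; survival fits are part of the context.
#'
#' @param context from [build_context()].
#' @param overrides named numeric vector, names among [econ_param_names()].
#' @return data.frame with columns `strategy`, `cost`, `qalys`.
#' @export
evaluate_strategies <- function(context, overrides = NULL) {
  params <- context$base_params
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), names(params))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    params[names(overrides)] <- overrides
  }
  settings <- settings_from_params(context$config, params)
  rows <- lapply(names(context$strategies), function(s) {
    spec <- spec_from_params(context$config, s, params,
                             pfs_fit = context$strategies[[s]]$pfs_fit,
                             os_fit = context$strategies[[s]]$os_fit)
    r <- accumulate_econ(context$traces[[s]], spec, settings)
    data.frame(strategy = s, cost = r$total_cost, qalys = r$total_qalys)
  })
  do.call(rbind, rows)
}

#' Run the full analysis
#'
#' Executes reconstruction, fitting, the cohort model, the incremental
#' analysis, the tornado and the PSA for a configuration, writing the
#' artifact set (fit summaries, traces, `results.csv`, `cea_table.csv`,
#' `tornado.csv`, `psa_samples.csv`, `ceac.csv` and a run manifest) when
#' `out_dir` is given.
#'
#' @param config a `cea_config`.
#' @param out_dir optional artifact directory.
#' @param curves optional per-strategy curve list (defaults to simulating
#'   the configured synthetic scenario).
#' @param psa_n optional override of the configured PSA iteration count.
#' @return list with `fitted`, `context`, `results`, `cea_table`,
#'   `decision`, `tornado`, `psa`, `ceac`.
#' @export
cea_run <- function(config, out_dir = NULL, curves = NULL, psa_n = NULL) {
  if (is.null(curves)) curves <- cea_simulate(config, out_dir = NULL)
  fitted <- fit_scenario(curves, config)
  context <- build_context(fitted, config)
  results <- lapply(names(context$strategies), function(s)
    accumulate_econ(context$traces[[s]], context$strategies[[s]], context$settings))
  names(results) <- names(context$strategies)
  table <- icer_table(results)
  decision <- check_wtp_decision(table, wtp_threshold(config))
  tornado <- one_way_sa(context, config_oneway_specs(config),
                        comparator = config$comparator)
  n_iter <- if (is.null(psa_n)) config$psa$n_iterations else psa_n
  psa <- run_psa(context, config_dist_specs(config),
                 n_iterations = n_iter, seed = config$psa$seed)
  ceac_tab <- ceac(psa)
  out <- list(fitted = fitted, context = context, results = results,
              cea_table = table, decision = decision, tornado = tornado,
              psa = psa, ceac = ceac_tab)
  if (!is.null(out_dir)) write_artifacts(out, config, out_dir)
  out
}

write_artifacts <- function(run, config, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  selected <- list()
  for (s in names(run$fitted)) {
    for (e in names(run$fitted[[s]])) {
      node <- run$fitted[[s]][[e]]
      fits_json <- lapply(node$fits, function(f) list(
        family = f$family, params = as.list(f$params),
        log_likelihood = f$log_likelihood, aic = f$aic, bic = f$bic,
        n_obs = f$n_obs, converged = f$converged))
      jsonlite::write_json(
        list(strategy = s, endpoint = e, selected = node$selected$family,
             reconstruction = list(rmse_survival = node$reconstruction$rmse_survival,
                                   max_abs_dev = node$reconstruction$max_abs_dev,
                                   events = node$reconstruction$events_reconstructed),
             fits = fits_json),
        file.path(out_dir, sprintf("fits_%s_%s.json", s, e)),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      selected[[paste(s, e, sep = "_")]] <- node$selected$family
    }
    tr <- run$context$traces[[s]]
    utils::write.csv(data.frame(cycle = 0:(nrow(tr) - 1L),
                                pf = tr[, "pf"], pd = tr[, "pd"],
                                dead = tr[, "dead"]),
                     file.path(out_dir, sprintf("trace_%s.csv", s)),
                     row.names = FALSE)
  }
  res_df <- do.call(rbind, lapply(run$results, function(r)
    data.frame(strategy = r$strategy, total_cost = r$total_cost,
               total_qalys = r$total_qalys, t(r$cost_breakdown))))
  utils::write.csv(res_df, file.path(out_dir, "results.csv"), row.names = FALSE)
  tab <- run$cea_table
  tab$decision_at_wtp <- ifelse(tab$strategy == run$decision, "preferred", "")
  utils::write.csv(tab, file.path(out_dir, "cea_table.csv"), row.names = FALSE)
  utils::write.csv(run$tornado, file.path(out_dir, "tornado.csv"), row.names = FALSE)
  psa_df <- data.frame(iteration = seq_len(run$psa$n_iterations))
  for (s in run$psa$strategies) {
    psa_df[[paste0("cost_", s)]] <- run$psa$cost[, s]
    psa_df[[paste0("qalys_", s)]] <- run$psa$qalys[, s]
  }
  utils::write.csv(psa_df, file.path(out_dir, "psa_samples.csv"), row.names = FALSE)
  utils::write.csv(run$ceac, file.path(out_dir, "ceac.csv"), row.names = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pd1cea")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    synthetic_seed = config$synthetic$seed,
    psa_seed = config$psa$seed,
    selected_families = selected,
    decision = run$decision,
    wtp_per_qaly = wtp_threshold(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Scenario diagnostics
#'
#' Reconstruction fidelity per curve, fit convergence, and trace
#' conservation checks for a completed run.
#'
#' @param run a [cea_run()] result.
#' @param max_abs_dev_tol reconstruction tolerance on the KM scale.
#' @return data.frame of checks with columns `check`, `target`, `value`,
#'   `pass`; attribute `ok` is TRUE when all checks pass.
#' @export
cea_validate <- function(run, max_abs_dev_tol = 0.02) {
  rows <- list()
  add <- function(check, target, value, pass)
    rows[[length(rows) + 1L]] <<- data.frame(check = check, target = target,
                                             value = value, pass = pass)
  for (s in names(run$fitted)) {
    for (e in names(run$fitted[[s]])) {
      node <- run$fitted[[s]][[e]]
      add("reconstruction_max_abs_dev", paste(s, e),
          node$reconstruction$max_abs_dev,
          node$reconstruction$max_abs_dev <= max_abs_dev_tol)
      add("selected_fit_converged", paste(s, e),
          as.numeric(node$selected$converged), isTRUE(node$selected$converged))
    }
    tr <- run$context$traces[[s]]
    add("trace_rows_sum_to_1", s, max(abs(rowSums(tr) - 1)),
        max(abs(rowSums(tr) - 1)) <= 1e-12)
    add("trace_dead_monotone", s, min(diff(tr[, "dead"])),
        all(diff(tr[, "dead"]) >= -1e-15))
  }
  out <- do.call(rbind, rows)
  attr(out, "ok") <- all(out$pass)
  out
}
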