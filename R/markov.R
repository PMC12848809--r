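#' Model time constants
#'
#' One model cycle is 3 weeks. With 1 month = 365.25/12 days this is
#' 21/(365.25/12) = 0.68994 months, i.e. 21/365.25 years; QALY accrual and
#' discounting use the same conversion so time units stay consistent.
#'
#' @export
cycle_length_months <- function() 21 / (365.25 / 12)

#' Global settings of the cohort model
#'
#' @param cycle_len cycle length in months.
#' @param horizon_cycles number of cycles; the default 522 spans 30 years,
#'   operationalizing a lifetime horizon (residual alive occupancy is
#'   negligible under the fitted models).
#' @param annual_discount_rate discounting for both costs and QALYs
#'   (default 5\% per year).
#' @param utility_pf,utility_pd health-state utilities (progression-free
#'   0.804, progressive disease 0.321).
#' @param wtp_per_qaly willingness-to-pay threshold, CNY/QALY (3x the 2024
#'   Chinese per-capita GDP of 95,749 CNY).
#' @param half_cycle_correction average adjacent occupancies when accruing
#'   (off by default: discrete, TreeAge-style accrual).
#' @export
model_settings <- function(cycle_len = cycle_length_months(),
                           horizon_cycles = 522L,
                           annual_discount_rate = 0.05,
                           utility_pf = 0.804, utility_pd = 0.321,
                           wtp_per_qaly = 3 * 95749,
                           half_cycle_correction = FALSE) {
  stopifnot(cycle_len > 0, horizon_cycles >= 1,
            annual_discount_rate >= 0,
            utility_pf >= 0, utility_pf <= 1,
            utility_pd >= 0, utility_pd <= 1,
            wtp_per_qaly >= 0)
  structure(list(cycle_len = cycle_len,
                 horizon_cycles = as.integer(horizon_cycles),
                 annual_discount_rate = annual_discount_rate,
                 utility_pf = utility_pf, utility_pd = utility_pd,
                 wtp_per_qaly = wtp_per_qaly,
                 half_cycle_correction = isTRUE(half_cycle_correction)),
            class = "model_settings")
}

#' Economic and clinical profile of one treatment strategy
#'
#' Per-cycle costs in CNY. The PD-1 agent (`drug_cost_per_cycle`) and
#' administration cost accrue for every progression-free cycle (the PD-1
#' agent up to `max_treatment_cycles`); platinum doublet chemotherapy
#' (`chemo_cost_per_cycle`, pemetrexed + carboplatin) for the first
#' `chemo_cycles` induction cycles, after which pemetrexed maintenance
#' (`maintenance_cost_per_cycle`) continues until progression. Progressive
#' disease accrues `second_line_cost_per_cycle` (docetaxel). Grade >= 3
#' adverse-event management is charged once at model entry via
#' [weighted_ae_cost()].
#'
#' @param name strategy identifier (unique within an analysis).
#' @param drug_cost_per_cycle PD-1 inhibitor cost per cycle.
#' @param chemo_cost_per_cycle induction chemotherapy cost per cycle.
#' @param maintenance_cost_per_cycle post-induction maintenance cost.
#' @param admin_cost_per_cycle administration/visit cost per cycle.
#' @param ae_profile named incidences of grade >= 3 adverse events.
#' @param ae_unit_costs named per-episode management costs; must cover every
#'   name in `ae_profile`.
#' @param second_line_cost_per_cycle post-progression therapy cost.
#' @param pfs_fit,os_fit converged [fit_parametric()] results.
#' @param max_treatment_cycles PD-1 treatment cap (default `Inf`: treat
#'   until progression).
#' @param chemo_cycles induction length (default 4 cycles).
#' @export
strategy_spec <- function(name, drug_cost_per_cycle, chemo_cost_per_cycle,
                          maintenance_cost_per_cycle, admin_cost_per_cycle,
                          ae_profile, ae_unit_costs,
                          second_line_cost_per_cycle,
                          pfs_fit = NULL, os_fit = NULL,
                          max_treatment_cycles = Inf, chemo_cycles = 4L) {
  costs <- c(drug_cost_per_cycle, chemo_cost_per_cycle,
             maintenance_cost_per_cycle, admin_cost_per_cycle,
             second_line_cost_per_cycle, unlist(ae_unit_costs))
  stopifnot(all(costs >= 0), all(ae_profile >= 0), all(ae_profile <= 1),
            max_treatment_cycles >= 1, chemo_cycles >= 0)
  structure(list(name = name,
                 drug_cost_per_cycle = drug_cost_per_cycle,
                 chemo_cost_per_cycle = chemo_cost_per_cycle,
                 maintenance_cost_per_cycle = maintenance_cost_per_cycle,
                 admin_cost_per_cycle = admin_cost_per_cycle,
                 ae_profile = unlist(ae_profile),
                 ae_unit_costs = unlist(ae_unit_costs),
                 second_line_cost_per_cycle = second_line_cost_per_cycle,
                 pfs_fit = pfs_fit, os_fit = os_fit,
                 max_treatment_cycles = max_treatment_cycles,
                 chemo_cycles = as.integer(chemo_cycles)),
            class = "strategy_spec")
}

#' Incidence-weighted adverse-event management cost
#'
#' Sum over adverse events of incidence x unit management cost; applied
#' once per patient at model entry (trial-reported incidences are
#' whole-treatment cumulative rates, so per-cycle application would
#' multiply-count).
#'
#' @param spec a [strategy_spec()].
#' @return cost in CNY.
#' @export
weighted_ae_cost <- function(spec) {
  stopifnot(inherits(spec, "strategy_spec"))
  missing <- setdiff(names(spec$ae_profile), names(spec$ae_unit_costs))
  if (length(missing))
    stop("no unit cost for adverse event(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(spec$ae_profile) == 0L) return(0)
  sum(spec$ae_profile * spec$ae_unit_costs[names(spec$ae_profile)])
}

#' Per-cycle discount factor
#'
#' `(1 + r)^(-k * cycle_len_years)` with `cycle_len_years` derived from the
#' settings' cycle length (21/365.25 years for the default 3-week cycle).
#'
#' @param settings a [model_settings()].
#' @param cycle_index cycle number(s), 0-based; vectorized.
#' @export
discount_factor <- function(settings, cycle_index) {
  stopifnot(inherits(settings, "model_settings"), all(cycle_index >= 0))
  years <- cycle_index * settings$cycle_len / 12
  (1 + settings$annual_discount_rate)^(-years)
}

#' Run the three-state cohort model
#'
#' Propagates the occupancy vector (progression-free, progressive disease,
#' dead) from (1, 0, 0) over `horizon_cycles` cycles using
#' [cycle_transition_probs()] per cycle. Death is absorbing and backward
#' transitions are not permitted. Row sums are checked to 1e-12 and dead
#' occupancy must be non-decreasing.
#'
#' @param spec a [strategy_spec()] with converged fits.
#' @param settings a [model_settings()].
#' @return a `cohort_trace`: numeric matrix with `horizon_cycles + 1` rows
#'   and columns `pf`, `pd`, `dead`; attribute `cycle_len`.
#' @export
run_cohort <- function(spec, settings) {
  stopifnot(inherits(spec, "strategy_spec"), inherits(settings, "model_settings"))
  H <- settings$horizon_cycles
  tp <- transition_grid(spec$pfs_fit, spec$os_fit, H, settings$cycle_len)
  trace <- matrix(0, nrow = H + 1L, ncol = 3,
                  dimnames = list(NULL, c("pf", "pd", "dead")))
  trace[1, ] <- c(1, 0, 0)
  for (k in seq_len(H)) {
    pf <- trace[k, 1]; pd <- trace[k, 2]; dead <- trace[k, 3]
    p_pd <- tp$p_pf_to_pd[k]; p_pfd <- tp$p_pf_to_death[k]; q_os <- tp$p_pd_to_death[k]
    if (p_pd + p_pfd > 1 + 1e-9)
      stop("probability coherence violation at cycle ", k - 1L, call. = FALSE)
    trace[k + 1L, 1] <- pf * (1 - p_pd - p_pfd)
    trace[k + 1L, 2] <- pd * (1 - q_os) + pf * p_pd
    trace[k + 1L, 3] <- dead + pf * p_pfd + pd * q_os
  }
  bad <- which(abs(rowSums(trace) - 1) > 1e-12)
  if (length(bad))
    stop("occupancy rows do not sum to 1 at cycle ", bad[1] - 1L, call. = FALSE)
  if (any(diff(trace[, "dead"]) < -1e-15))
    stop("dead occupancy decreased", call. = FALSE)
  structure(trace, cycle_len = settings$cycle_len, class = c("cohort_trace", "matrix"))
}

#' Accumulate discounted costs and QALYs over a trace
#'
#' Discrete accrual: occupancy at the start of cycle k earns that cycle's
#' costs and utilities, discounted by [discount_factor()] (with the optional
#' half-cycle correction, the average of adjacent occupancies is used
#' instead). Progression-free cycles accrue PD-1 drug (up to the treatment
#' cap), chemotherapy (induction then maintenance) and administration
#' costs plus `utility_pf`; progressive-disease cycles accrue second-line
#' therapy plus `utility_pd`; the weighted adverse-event cost enters once at
#' cycle 0.
#'
#' @param trace a [run_cohort()] result.
#' @param spec the matching [strategy_spec()].
#' @param settings a [model_settings()].
#' @return an `econ_result`: list with `strategy`, `total_cost`,
#'   `total_qalys`, `cost_breakdown` (drug, chemo, admin, second_line,
#'   adverse_events) and undiscounted life-years `life_years`.
#' @export
accumulate_econ <- function(trace, spec, settings) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(spec, "strategy_spec"),
            inherits(settings, "model_settings"))
  H <- nrow(trace) - 1L
  k <- 0:(H - 1L)
  pf <- trace[k + 1L, "pf"]; pd <- trace[k + 1L, "pd"]
  if (settings$half_cycle_correction) {
    pf <- (pf + trace[k + 2L, "pf"]) / 2
    pd <- (pd + trace[k + 2L, "pd"]) / 2
  }
  df <- discount_factor(settings, k)
  cyc_years <- settings$cycle_len / 12
  on_drug <- k < spec$max_treatment_cycles
  chemo_per_cycle <- ifelse(k < spec$chemo_cycles,
                            spec$chemo_cost_per_cycle,
                            spec$maintenance_cost_per_cycle)
  breakdown <- c(
    drug = sum(df * pf * spec$drug_cost_per_cycle * on_drug),
    chemo = sum(df * pf * chemo_per_cycle),
    admin = sum(df * pf * spec$admin_cost_per_cycle),
    second_line = sum(df * pd * spec$second_line_cost_per_cycle),
    adverse_events = weighted_ae_cost(spec))
  qalys <- sum(df * (pf * settings$utility_pf + pd * settings$utility_pd)) * cyc_years
  structure(list(strategy = spec$name,
                 total_cost = sum(breakdown),
                 total_qalys = qalys,
                 cost_breakdown = breakdown,
                 life_years = sum(pf + pd) * cyc_years),
            class = "econ_result")
}

#' @export
print.econ_result <- function(x, ...) {
  cat(sprintf("<econ_result> %s: cost %.0f CNY, %.3f QALYs (%.3f LY undiscounted)\n",
              x$strategy, x$total_cost, x$total_qalys, x$life_years))
  invisible(x)
}
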