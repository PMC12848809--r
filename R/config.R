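#' Default analysis configuration
#'
#' All numeric inputs of the packaged replication in one structured list:
#' per-cycle treatment costs (CNY) with plausible ranges, grade >= 3
#' adverse-event incidences per strategy, health-state utilities, discount
#' rate, willingness-to-pay threshold, and the synthetic-trial scenario that
#' stands in for digitized trial curves.
#'
#' The synthetic scenario uses exponential event times calibrated to the
#' source trials: PFS medians 8.9 (sintilimab), 9.7 (toripalimab) and 11.0
#' months (camrelizumab); OS median 27.1 months for camrelizumab (reported
#' reached, follow-up 30 months) and latent OS medians 23 and 21 months for
#' sintilimab and toripalimab, whose reported medians were not reached —
#' both arms are administratively censored at 18 months, before the latent
#' median, and the latent values are in line with subsequently reported
#' mature estimates from those trials. Arms of 5,000 patients keep KM
#' sampling noise from obscuring the designed survival structure; trial-
#' scale arms are exercised in the validation suite.
#'
#' @param seed base seed for the synthetic scenario; per-arm/endpoint seeds
#'   are derived from it deterministically.
#' @return nested configuration list (class `cea_config`).
#' @export
default_config <- function(seed = 20260922L) {
  ae_unit_costs <- list(
    neutropenia = list(base = 818, low = 363, high = 2545),
    leukopenia = list(base = 818, low = 363, high = 2545),
    thrombocytopenia = list(base = 10707, low = 8818, high = 12597),
    anemia = list(base = 987, low = 759, high = 1138))
  cfg <- list(
    strategies = list(
      sintilimab = list(
        drug_cost = list(base = 3558, low = 2519, high = 3558),  # price cuts only
        ae_profile = list(neutropenia = 0.365, leukopenia = 0.147,
                          thrombocytopenia = 0.12, anemia = 0.15),
        synthetic = list(pfs_median = 8.9, os_median = 23.0, follow_up = 18)),
      toripalimab = list(
        drug_cost = list(base = 3636, low = 2727, high = 3636),
        ae_profile = list(neutropenia = 0.555, leukopenia = 0.357,
                          thrombocytopenia = 0.172, anemia = 0.299),
        synthetic = list(pfs_median = 9.7, os_median = 21.0, follow_up = 18)),
      camrelizumab = list(
        drug_cost = list(base = 3558, low = 2519, high = 3558),
        ae_profile = list(neutropenia = 0.395, leukopenia = 0.20,
                          thrombocytopenia = 0.166, anemia = 0.20),
        synthetic = list(pfs_median = 11.0, os_median = 27.1, follow_up = 30))),
    costs = list(
      pemetrexed = list(base = 833, low = 625, high = 1041),
      carboplatin = list(base = 364, low = 273, high = 455),
      admin = list(base = 6348, low = 4761, high = 7935),
      second_line = list(base = 2792, low = 2094, high = 3490),
      ae_unit = ae_unit_costs),
    utilities = list(
      pf = list(base = 0.804, low = 0.536, high = 0.883),
      pd = list(base = 0.321, low = 0.05, high = 0.473)),
    settings = list(
      cycle_len = cycle_length_months(),
      horizon_cycles = 522L,
      discount_rate = list(base = 0.05, low = 0, high = 0.08),
      gdp_per_capita = 95749,          # 2024 Chinese per-capita GDP, CNY
      wtp_multiplier = 3,
      half_cycle_correction = FALSE,
      chemo_cycles = 4L,
      max_treatment_cycles = Inf),
    synthetic = list(
      family = "exponential",
      n_patients = 5000L,
      seed = as.integer(seed),
      dropout_rate = 0,
      risk_every = 3,
      digitize = list(n_points = 1000L, jitter_sd = 0.002)),
    selection_policy = "aic_then_bic",
    guyot = list(use_total_events = TRUE),
    psa = list(n_iterations = 10000L, seed = as.integer(seed) + 1L),
    comparator = c("camrelizumab", "sintilimab"))
  class(cfg) <- c("cea_config", "list")
  cfg
}

#' @rdname default_config
#' @param config a `cea_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.character(cfg$settings$max_treatment_cycles))  # ".inf" round trip
    cfg$settings$max_treatment_cycles <- Inf
  class(cfg) <- c("cea_config", "list")
  cfg
}

#' Willingness-to-pay threshold implied by a configuration
#'
#' `wtp_multiplier` x per-capita GDP (3 x 95,749 = 287,247 CNY/QALY by
#' default).
#'
#' @param config a `cea_config`.
#' @export
wtp_threshold <- function(config) {
  config$settings$wtp_multiplier * config$settings$gdp_per_capita
}

#' Tunable scalar parameters of the economic model
#'
#' These names key the one-way sensitivity analysis, the PSA and
#' [evaluate_strategies()] overrides.
#'
#' @export
econ_param_names <- function() {
  c("cost_drug_sintilimab", "cost_drug_toripalimab", "cost_drug_camrelizumab",
    "cost_pemetrexed", "cost_carboplatin", "cost_admin", "cost_second_line",
    "cost_ae_neutropenia", "cost_ae_leukopenia", "cost_ae_thrombocytopenia",
    "cost_ae_anemia", "utility_pf", "utility_pd", "discount_rate")
}

#' @rdname econ_param_names
#' @param config a `cea_config`.
#' @return `econ_param_base()`: named vector of base-case values.
#' @export
econ_param_base <- function(config) {
  b <- function(x) x$base
  c(cost_drug_sintilimab = b(config$strategies$sintilimab$drug_cost),
    cost_drug_toripalimab = b(config$strategies$toripalimab$drug_cost),
    cost_drug_camrelizumab = b(config$strategies$camrelizumab$drug_cost),
    cost_pemetrexed = b(config$costs$pemetrexed),
    cost_carboplatin = b(config$costs$carboplatin),
    cost_admin = b(config$costs$admin),
    cost_second_line = b(config$costs$second_line),
    cost_ae_neutropenia = b(config$costs$ae_unit$neutropenia),
    cost_ae_leukopenia = b(config$costs$ae_unit$leukopenia),
    cost_ae_thrombocytopenia = b(config$costs$ae_unit$thrombocytopenia),
    cost_ae_anemia = b(config$costs$ae_unit$anemia),
    utility_pf = b(config$utilities$pf),
    utility_pd = b(config$utilities$pd),
    discount_rate = b(config$settings$discount_rate))
}

#' Distribution specifications for the probabilistic sensitivity analysis
#'
#' Gamma for costs, beta for utilities, fixed for the discount rate (no
#' distribution is assigned to it; it is varied in one-way analysis over
#' its 0-8\% range). Spreads are moment-matched to the published low/high
#' ranges read as 95\% intervals. PD-1 drug prices carry asymmetric ranges
#' (reductions only, reflecting reimbursement-list pricing).
#'
#' @param config a `cea_config`.
#' @return named list of [distribution_spec()]s.
#' @export
config_dist_specs <- function(config) {
  sp <- function(name, family, x)
    distribution_spec(name, family, base = x$base, low = x$low, high = x$high)
  specs <- list(
    sp("cost_drug_sintilimab", "gamma", config$strategies$sintilimab$drug_cost),
    sp("cost_drug_toripalimab", "gamma", config$strategies$toripalimab$drug_cost),
    sp("cost_drug_camrelizumab", "gamma", config$strategies$camrelizumab$drug_cost),
    sp("cost_pemetrexed", "gamma", config$costs$pemetrexed),
    sp("cost_carboplatin", "gamma", config$costs$carboplatin),
    sp("cost_admin", "gamma", config$costs$admin),
    sp("cost_second_line", "gamma", config$costs$second_line),
    sp("cost_ae_neutropenia", "gamma", config$costs$ae_unit$neutropenia),
    sp("cost_ae_leukopenia", "gamma", config$costs$ae_unit$leukopenia),
    sp("cost_ae_thrombocytopenia", "gamma", config$costs$ae_unit$thrombocytopenia),
    sp("cost_ae_anemia", "gamma", config$costs$ae_unit$anemia),
    sp("utility_pf", "beta", config$utilities$pf),
    sp("utility_pd", "beta", config$utilities$pd),
    sp("discount_rate", "fixed", config$settings$discount_rate))
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' One-way sensitivity ranges
#'
#' The tornado protocol mirrors the source analysis: the three PD-1 drug
#' prices vary over their asymmetric negotiated-price ranges (reductions
#' only), the discount rate over 0-8\%, and every other parameter by
#' +/-25\% around base (utilities clipped to \[0, 1\]). For chemotherapy,
#' administration and second-line costs the published ranges are exactly
#' +/-25\%, so the two conventions coincide there.
#'
#' @param config a `cea_config`.
#' @return named list of [distribution_spec()]s carrying the one-way ranges.
#' @export
config_oneway_specs <- function(config) {
  pm25 <- function(name, base, cap1 = FALSE) {
    hi <- if (cap1) min(base * 1.25, 1) else base * 1.25
    distribution_spec(name, "fixed", base = base, low = base * 0.75, high = hi)
  }
  tbl <- function(name, x)
    distribution_spec(name, "fixed", base = x$base, low = x$low, high = x$high)
  p <- econ_param_base(config)
  specs <- list(
    tbl("cost_drug_sintilimab", config$strategies$sintilimab$drug_cost),
    tbl("cost_drug_toripalimab", config$strategies$toripalimab$drug_cost),
    tbl("cost_drug_camrelizumab", config$strategies$camrelizumab$drug_cost),
    pm25("cost_pemetrexed", p[["cost_pemetrexed"]]),
    pm25("cost_carboplatin", p[["cost_carboplatin"]]),
    pm25("cost_admin", p[["cost_admin"]]),
    pm25("cost_second_line", p[["cost_second_line"]]),
    pm25("cost_ae_neutropenia", p[["cost_ae_neutropenia"]]),
    pm25("cost_ae_leukopenia", p[["cost_ae_leukopenia"]]),
    pm25("cost_ae_thrombocytopenia", p[["cost_ae_thrombocytopenia"]]),
    pm25("cost_ae_anemia", p[["cost_ae_anemia"]]),
    pm25("utility_pf", p[["utility_pf"]], cap1 = TRUE),
    pm25("utility_pd", p[["utility_pd"]], cap1 = TRUE),
    tbl("discount_rate", config$settings$discount_rate))
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}
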