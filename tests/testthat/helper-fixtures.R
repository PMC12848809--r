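# shared fixtures, built in code

exp_fit <- function(rate) parametric_fit_from_params("exponential", c(rate = rate))

# a minimal strategy spec with the camrelizumab AE profile
make_spec <- function(name = "arm", drug = 3558, pfs_rate = 0.08, os_rate = 0.03,
                      ae_profile = c(neutropenia = 0.395, leukopenia = 0.20,
                                     thrombocytopenia = 0.166, anemia = 0.20),
                      ...) {
  strategy_spec(name, drug_cost_per_cycle = drug, chemo_cost_per_cycle = 1197,
                maintenance_cost_per_cycle = 833, admin_cost_per_cycle = 6348,
                ae_profile = ae_profile,
                ae_unit_costs = c(neutropenia = 818, leukopenia = 818,
                                  thrombocytopenia = 10707, anemia = 987),
                second_line_cost_per_cycle = 2792,
                pfs_fit = exp_fit(pfs_rate), os_fit = exp_fit(os_rate), ...)
}

# a small two-strategy context driven by ground-truth fits (no data)
make_context <- function(horizon = 300L) {
  cfg <- default_config()
  cfg$settings$horizon_cycles <- horizon
  fitted <- lapply(names(cfg$strategies), function(s) {
    b <- cfg$strategies[[s]]$synthetic
    list(PFS = list(selected = exp_fit(log(2) / b$pfs_median)),
         OS = list(selected = exp_fit(log(2) / b$os_median)))
  })
  names(fitted) <- names(cfg$strategies)
  build_context(fitted, cfg)
}

# the packaged replication, computed once per test run on first use
packaged_run <- local({
  cache <- NULL
  function(psa_n = 10000L) {
    if (is.null(cache)) cache <<- cea_run(default_config(), psa_n = psa_n)
    cache
  }
})
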