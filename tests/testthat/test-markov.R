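test_that("weighted AE cost reproduces hand arithmetic from the cost table", {
  cam <- make_spec("camrelizumab")
  expect_equal(weighted_ae_cost(cam), 2461.47, tolerance = 1e-2)
  sin <- make_spec("sintilimab",
                   ae_profile = c(neutropenia = 0.365, leukopenia = 0.147,
                                  thrombocytopenia = 0.12, anemia = 0.15))
  expect_equal(weighted_ae_cost(sin), 1851.71, tolerance = 1e-2)
  none <- make_spec("clean", ae_profile = c(neutropenia = 0, leukopenia = 0,
                                            thrombocytopenia = 0, anemia = 0))
  expect_equal(weighted_ae_cost(none), 0)
  broken <- make_spec("broken")
  broken$ae_profile <- c(broken$ae_profile, rash = 0.1)
  expect_error(weighted_ae_cost(broken), "rash")
})

test_that("discounting follows the cycle-length-consistent convention", {
  s <- model_settings()
  expect_equal(discount_factor(s, 0), 1)
  expect_equal(discount_factor(model_settings(annual_discount_rate = 0), 40), 1)
  # ~1 year of 3-week cycles at 5%/year
  expect_equal(discount_factor(s, 17), 1.05^(-17 * 21 / 365.25), tolerance = 1e-12)
  expect_equal(discount_factor(s, 17), 0.95342, tolerance = 1e-4)
})

test_that("the cohort trace honors absorbing death and conservation", {
  # effectively no transitions: cohort frozen in PF
  frozen <- make_spec(pfs_rate = 1e-14, os_rate = 1e-14)
  s <- model_settings(horizon_cycles = 50)
  tr <- run_cohort(frozen, s)
  expect_equal(tr[nrow(tr), ], c(pf = 1, pd = 0, dead = 0), tolerance = 1e-10)

  # immediate absorption
  doomed <- make_spec(pfs_rate = 50, os_rate = 50)
  tr2 <- run_cohort(doomed, s)
  expect_equal(unname(tr2[2, "dead"]), 1, tolerance = 1e-10)
  expect_equal(unname(tr2[nrow(tr2), "dead"]), 1, tolerance = 1e-10)

  # memoryless chaining: PF occupancy equals S_PFS at cycle boundaries
  spec <- make_spec(pfs_rate = 0.08, os_rate = 0.03)
  s2 <- model_settings(horizon_cycles = 400)
  tr3 <- run_cohort(spec, s2)
  k <- 0:400
  expect_equal(unname(tr3[, "pf"]), exp(-0.08 * k * s2$cycle_len), tolerance = 1e-9)
  expect_true(all(abs(rowSums(tr3) - 1) <= 1e-12))
  expect_true(all(diff(tr3[, "dead"]) >= -1e-15))
})

test_that("QALY accrual matches the geometric-series closed form", {
  spec <- make_spec(pfs_rate = 0.1, os_rate = 0.1)
  spec$drug_cost_per_cycle <- 0; spec$chemo_cost_per_cycle <- 0
  spec$maintenance_cost_per_cycle <- 0; spec$admin_cost_per_cycle <- 0
  spec$second_line_cost_per_cycle <- 0
  spec$ae_profile[] <- 0
  s <- model_settings(horizon_cycles = 2000, annual_discount_rate = 0,
                      utility_pf = 1, utility_pd = 0)
  p <- 1 - exp(-0.1 * s$cycle_len)        # per-cycle PF exit probability
  res <- accumulate_econ(run_cohort(spec, s), spec, s)
  cyc_years <- s$cycle_len / 12
  expect_equal(res$total_qalys, cyc_years / p, tolerance = 1e-6)
  expect_equal(res$total_cost, 0)
})

test_that("single-cycle bookkeeping charges entry costs once", {
  spec <- make_spec(pfs_rate = 50, os_rate = 50)   # dead by cycle 1
  s <- model_settings(horizon_cycles = 1)
  res <- accumulate_econ(run_cohort(spec, s), spec, s)
  expect_equal(res$total_cost,
               spec$drug_cost_per_cycle + spec$chemo_cost_per_cycle +
                 spec$admin_cost_per_cycle + weighted_ae_cost(spec),
               tolerance = 1e-9)
  expect_equal(res$total_qalys, s$utility_pf * s$cycle_len / 12, tolerance = 1e-9)
  expect_equal(res$total_cost, sum(res$cost_breakdown))
})

test_that("costs scale linearly and leave QALYs untouched", {
  spec <- make_spec(pfs_rate = 0.07, os_rate = 0.03)
  s <- model_settings(horizon_cycles = 300)
  tr <- run_cohort(spec, s)
  base <- accumulate_econ(tr, spec, s)
  doubled <- spec
  for (f in c("drug_cost_per_cycle", "chemo_cost_per_cycle",
              "maintenance_cost_per_cycle", "admin_cost_per_cycle",
              "second_line_cost_per_cycle"))
    doubled[[f]] <- 2 * spec[[f]]
  doubled$ae_unit_costs <- 2 * spec$ae_unit_costs
  res2 <- accumulate_econ(tr, doubled, s)
  expect_equal(res2$total_cost, 2 * base$total_cost, tolerance = 1e-12)
  expect_equal(res2$total_qalys, base$total_qalys)
})

test_that("undiscounted life-years match the restricted mean survival", {
  s <- model_settings(horizon_cycles = 522)
  os_fits <- list(
    parametric_fit_from_params("exponential", c(rate = 0.03)),
    parametric_fit_from_params("weibull", c(shape = 1.2, scale = 30)),
    parametric_fit_from_params("lognormal", c(meanlog = 3.2, sdlog = 0.8)),
    parametric_fit_from_params("loglogistic", c(logloc = 3.2, logscale = 0.5)),
    parametric_fit_from_params("gompertz", c(shape = 0.01, rate = 0.025)))
  horizon_months <- 522 * s$cycle_len
  for (os in os_fits) {
    spec <- make_spec(pfs_rate = 0.08)
    spec$os_fit <- os
    res <- accumulate_econ(run_cohort(spec, s), spec, s)
    rmst <- stats::integrate(function(t) survival_at(os, t), 0, horizon_months,
                             subdivisions = 2000L, rel.tol = 1e-10)$value / 12
    expect_lt(abs(res$life_years - rmst), s$cycle_len / 12)
  }
})

test_that("discounting shrinks both costs and QALYs monotonically", {
  spec <- make_spec(pfs_rate = 0.07, os_rate = 0.03)
  vals <- lapply(c(0, 0.05, 0.08), function(r) {
    s <- model_settings(horizon_cycles = 400, annual_discount_rate = r)
    accumulate_econ(run_cohort(spec, s), spec, s)
  })
  costs <- vapply(vals, `[[`, 0, "total_cost")
  qalys <- vapply(vals, `[[`, 0, "total_qalys")
  expect_true(all(diff(costs) < 0))
  expect_true(all(diff(qalys) < 0))
})
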