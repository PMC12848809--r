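test_that("exponential MLE matches the closed form", {
  f <- fit_parametric(data.frame(time = c(1, 2, 3), event = c(1, 1, 1)), "exponential")
  expect_true(f$converged)
  expect_equal(unname(f$params[["rate"]]), 0.5, tolerance = 1e-6)
  expect_equal(f$log_likelihood, 3 * log(0.5) - 0.5 * 6, tolerance = 1e-6)
  expect_equal(f$aic, 2 - 2 * f$log_likelihood)
  expect_equal(f$bic, log(3) - 2 * f$log_likelihood)

  # censored-data closed form lambda-hat = events / total time, as an
  # independent oracle on a censored sample
  d <- data.frame(time = c(2, 5, 7, 4, 9), event = c(1, 0, 1, 1, 0))
  f2 <- fit_parametric(d, "exponential")
  expect_equal(unname(f2$params[["rate"]]), sum(d$event) / sum(d$time),
               tolerance = 1e-6)
})

test_that("the weibull family nests the exponential fit", {
  d <- simulate_arm(trial_arm_truth("exponential", c(rate = 0.2), 400,
                                    max_follow_up = 30, seed = 21))
  fe <- fit_parametric(d, "exponential")
  fw <- fit_parametric(d, "weibull")
  expect_gte(fw$log_likelihood, fe$log_likelihood - 1e-6)
  expect_equal(unname(fw$params[["shape"]]), 1, tolerance = 0.15)
})

test_that("large-sample exponential rates land in the Wald interval", {
  d <- simulate_arm(trial_arm_truth("exponential", c(rate = 0.1), 5000,
                                    max_follow_up = Inf, seed = 31))
  f <- fit_parametric(d, "exponential")
  expect_gte(unname(f$params[["rate"]]), 0.0972)
  expect_lte(unname(f$params[["rate"]]), 0.1028)
})

test_that("unfittable inputs are rejected", {
  expect_error(fit_parametric(data.frame(time = 1, event = 1), "exponential"),
               "at least 2")
  expect_error(fit_parametric(data.frame(time = c(1, 2), event = c(0, 0)),
                              "weibull"), "no events")
})

test_that("selection minimizes the chosen criterion with a BIC tie-break", {
  mk <- function(aic, bic) structure(list(family = "exponential", aic = aic,
                                          bic = bic, converged = TRUE),
                                     class = "parametric_fit")
  fits <- list(mk(100, 90), mk(98, 120), mk(105, 80))
  expect_equal(select_best(fits, "aic")$aic, 98)
  expect_equal(select_best(fits, "bic")$bic, 80)
  # near-tie on AIC resolved by BIC
  pair <- list(mk(100.0, 110), mk(101.0, 105))
  expect_equal(select_best(pair, "aic_then_bic")$bic, 105)
  # a clear AIC win is not overturned
  pair2 <- list(mk(100.0, 110), mk(103.0, 105))
  expect_equal(select_best(pair2, "aic_then_bic")$aic, 100)
  bad <- list(structure(list(aic = 1, bic = 1, converged = FALSE),
                        class = "parametric_fit"))
  expect_error(select_best(bad), "no converged fits")
})

test_that("fitted survival functions have the family closed forms", {
  fits <- list(
    parametric_fit_from_params("exponential", c(rate = 0.5)),
    parametric_fit_from_params("weibull", c(shape = 1.4, scale = 12)),
    parametric_fit_from_params("lognormal", c(meanlog = 2.2, sdlog = 0.7)),
    parametric_fit_from_params("loglogistic", c(logloc = 2.3, logscale = 0.4)),
    parametric_fit_from_params("gompertz", c(shape = 0.02, rate = 0.05)))
  t_grid <- seq(0, 60, by = 0.5)
  for (f in fits) {
    s <- survival_at(f, t_grid)
    expect_equal(s[1], 1)
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
  expect_equal(survival_at(parametric_fit_from_params("exponential",
                                                      c(rate = log(2) / 8.9)), 8.9), 0.5)
  # gompertz shape -> 0 limit is the exponential
  g <- parametric_fit_from_params("gompertz", c(shape = 1e-8, rate = 0.1))
  expect_lt(abs(survival_at(g, 10) - exp(-1)), 1e-6)
  expect_error(survival_at(fits[[1]], -1), "non-negative")
})

test_that("cycle transition probabilities follow the stated conversion", {
  pfs <- parametric_fit_from_params("exponential", c(rate = log(2) / 8.9))
  os <- parametric_fit_from_params("exponential", c(rate = 0.02))
  cl <- 21 / (365.25 / 12)
  tp <- cycle_transition_probs(pfs, os, 0, cl)
  q_pf <- 1 - exp(-log(2) / 8.9 * cl)
  expect_equal(tp$p_pf_to_pd + tp$p_pf_to_death, q_pf, tolerance = 1e-12)
  expect_equal(tp$p_pd_to_death, 1 - exp(-0.02 * cl), tolerance = 1e-12)

  # no-mortality limit: all PF exits progress
  os0 <- parametric_fit_from_params("exponential", c(rate = 1e-14))
  tp0 <- cycle_transition_probs(pfs, os0, 3, cl)
  expect_equal(tp0$p_pf_to_death, 0, tolerance = 1e-10)
  expect_equal(tp0$p_pf_to_pd, 1 - exp(-log(2) / 8.9 * cl), tolerance = 1e-10)

  # identical PFS and OS: min() saturates, nobody progresses
  tpe <- cycle_transition_probs(pfs, pfs, 2, cl)
  expect_equal(tpe$p_pf_to_pd, 0)
})

test_that("transition probabilities stay coherent over a 30-year horizon", {
  cl <- 21 / (365.25 / 12)
  fits <- list(
    exponential = parametric_fit_from_params("exponential", c(rate = 0.06)),
    weibull = parametric_fit_from_params("weibull", c(shape = 1.3, scale = 16)),
    lognormal = parametric_fit_from_params("lognormal", c(meanlog = 2.6, sdlog = 0.9)),
    loglogistic = parametric_fit_from_params("loglogistic", c(logloc = 2.6, logscale = 0.5)),
    gompertz = parametric_fit_from_params("gompertz", c(shape = 0.015, rate = 0.03)))
  os <- parametric_fit_from_params("exponential", c(rate = 0.025))
  for (f in fits) {
    tg <- pd1cea:::transition_grid(f, os, 522L, cl)
    expect_true(all(tg$p_pf_to_pd >= 0 & tg$p_pf_to_pd <= 1))
    expect_true(all(tg$p_pf_to_death >= 0 & tg$p_pf_to_death <= 1))
    expect_true(all(tg$p_pd_to_death >= 0 & tg$p_pd_to_death <= 1))
    expect_true(all(tg$p_pf_to_pd + tg$p_pf_to_death <= 1 + 1e-12))
    # chaining the conditional exit probabilities telescopes back to S(t)
    surv_chain <- cumprod(1 - tg$p_pf_to_pd - tg$p_pf_to_death)
    expect_equal(surv_chain, survival_at(f, (1:522) * cl), tolerance = 1e-9)
  }
})
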