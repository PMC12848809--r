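test_that("simulated exponential arms reproduce the target median", {
  truth <- trial_arm_truth("exponential", c(rate = log(2) / 8.9),
                           n_patients = 10000, max_follow_up = Inf, seed = 1)
  arm <- simulate_arm(truth)
  expect_equal(nrow(arm), 10000)
  expect_true(all(arm$event == 1))
  expect_gte(median(arm$time), 8.6)
  expect_lte(median(arm$time), 9.2)
})

test_that("follow-up and seeding behave as an observation scheme", {
  truth0 <- trial_arm_truth("weibull", c(shape = 1.2, scale = 10), 50,
                            max_follow_up = 0, seed = 3)
  arm0 <- simulate_arm(truth0)
  expect_true(all(arm0$time == 0) && all(arm0$event == 0))

  truth <- trial_arm_truth("lognormal", c(meanlog = 2, sdlog = 0.7), 200,
                           max_follow_up = 12, seed = 9)
  expect_identical(simulate_arm(truth), simulate_arm(truth))
  arm <- simulate_arm(truth)
  expect_true(all(arm$time <= 12))
  expect_true(all(arm$event[arm$time < 12] == 1))

  expect_error(trial_arm_truth("gamma", c(rate = 1), 10), "unknown survival family")
  expect_error(trial_arm_truth("weibull", c(shape = -1, scale = 2), 10), "positive")
})

test_that("km_estimate is the product-limit estimator with a risk table", {
  km <- km_estimate(data.frame(time = c(1, 2, 3), event = c(1, 1, 0)))
  expect_equal(km$coords$time, c(0, 1, 2, 3))
  expect_equal(km$coords$survival, c(1, 2/3, 1/3, 1/3), tolerance = 1e-12)
  expect_equal(km$total_events, 2L)

  censored <- km_estimate(data.frame(time = c(2, 4, 6), event = c(0, 0, 0)))
  expect_true(all(censored$coords$survival == 1))
  expect_equal(censored$total_events, 0L)

  single <- km_estimate(data.frame(time = 5, event = 1))
  expect_equal(single$coords$time, c(0, 5))
  expect_equal(single$coords$survival, c(1, 0))

  expect_error(km_estimate(data.frame(time = numeric(0), event = integer(0))))
})

test_that("risk tables count records still under observation", {
  for (seed in 1:5) {
    arm <- simulate_arm(trial_arm_truth("exponential", c(rate = 0.07), 400,
                                        max_follow_up = 20, seed = seed))
    km <- km_estimate(arm, risk_times = seq(0, 20, 4))
    expect_equal(km$risk_table$n_at_risk,
                 vapply(km$risk_table$time, function(t) sum(arm$time >= t), 0L))
  }
})

test_that("digitization thins losslessly and monotonizes under jitter", {
  km <- km_estimate(data.frame(time = c(1, 2, 3), event = c(1, 1, 0)))
  thin <- emit_digitized(km, n_points = 10, jitter_sd = 0)
  expect_true(all(thin$coords$survival %in% km$coords$survival))

  arm <- simulate_arm(trial_arm_truth("exponential", c(rate = log(2) / 8.9), 300,
                                      max_follow_up = 24, seed = 11))
  km2 <- km_estimate(arm)
  noisy <- emit_digitized(km2, n_points = 80, jitter_sd = 0.02, seed = 5)
  expect_true(all(diff(noisy$coords$survival) <= 0))
  expect_true(all(noisy$coords$survival >= 0 & noisy$coords$survival <= 1))
  expect_identical(noisy$risk_table, km2$risk_table)

  # 5-sigma measurement bound at jitter_sd = 0.01
  j <- emit_digitized(km2, n_points = 80, jitter_sd = 0.01, seed = 6)
  dev <- abs(j$coords$survival - curve_survival_at(km2, j$coords$time))
  expect_lte(max(dev), 0.05)

  expect_error(emit_digitized(km2, n_points = 80, jitter_sd = -0.1), "non-negative")
  expect_error(emit_digitized(km2, n_points = 1), ">= 2")
})

test_that("KM estimates converge to the generating survival function", {
  lam <- log(2) / 8.9
  arm <- simulate_arm(trial_arm_truth("exponential", c(rate = lam), 20000,
                                      max_follow_up = 36, seed = 2))
  km <- km_estimate(arm)
  grid <- seq(0, 36, by = 0.25)
  expect_lt(max(abs(curve_survival_at(km, grid) - exp(-lam * grid))), 0.02)
})

test_that("curve invariants are enforced at construction", {
  good_coords <- data.frame(time = c(0, 1, 2), survival = c(1, 0.8, 0.6))
  risk <- data.frame(time = c(0, 2), n_at_risk = c(10, 5))
  expect_s3_class(digitized_curve(good_coords, risk), "digitized_curve")
  expect_error(digitized_curve(data.frame(time = c(0, 1), survival = c(0.9, 0.8)),
                               risk), "begin at")
  expect_error(digitized_curve(data.frame(time = c(0, 1, 2), survival = c(1, 0.5, 0.7)),
                               risk), "non-increasing")
  expect_error(digitized_curve(good_coords,
                               data.frame(time = c(0, 2), n_at_risk = c(5, 10))),
               "non-increasing")
  expect_error(digitized_curve(good_coords,
                               data.frame(time = c(0, 9), n_at_risk = c(10, 2))),
               "within the coordinate time span")
})
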