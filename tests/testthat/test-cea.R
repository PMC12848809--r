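table3 <- data.frame(strategy = c("sintilimab", "toripalimab", "camrelizumab"),
                     cost = c(230813, 243082, 253056),
                     qalys = c(1.1, 1.1, 1.2))

test_that("dominance classification matches the three-strategy comparison", {
  tab <- icer_table(table3)
  expect_equal(tab$dominance, c("none", "strict", "none"))
  expect_equal(attr(tab, "reference"), "sintilimab")
  expect_equal(tab$on_frontier, c(TRUE, FALSE, TRUE))
  # frontier ICER on the printed (rounded) inputs; the published table used
  # unrounded QALYs, so its 164,983 is not recoverable from rounded values
  expect_equal(tab$frontier_icer[3], 22243 / 0.1, tolerance = 1e-9)
  expect_error(icer_table(table3[c(1, 1, 2), ]), "duplicate")
})

test_that("ties produce no dominance and undefined ICERs", {
  twins <- data.frame(strategy = c("a", "b"), cost = c(100, 100), qalys = c(1, 1))
  tab <- icer_table(twins)
  expect_true(all(tab$dominance == "none"))
  expect_true(all(is.na(tab$icer)))
})

test_that("extended dominance removes frontier kinks", {
  df <- data.frame(strategy = c("cheap", "kink", "best"),
                   cost = c(0, 150, 200),
                   qalys = c(0, 1, 2))
  # kink: ICER 150 vs cheap, but best costs 50 more for a full QALY (ICER 50)
  tab <- icer_table(df)
  expect_equal(tab$dominance[tab$strategy == "kink"], "extended")
  fi <- tab$frontier_icer[tab$on_frontier]
  expect_true(all(diff(fi[!is.na(fi)]) > 0) || sum(!is.na(fi)) <= 1)
})

test_that("the WTP decision walks the frontier correctly", {
  tab <- icer_table(table3)
  expect_equal(check_wtp_decision(tab, 0), "sintilimab")
  expect_equal(check_wtp_decision(tab, 287247), "camrelizumab")
  expect_equal(check_wtp_decision(tab, 1e12), "camrelizumab")
  expect_equal(check_wtp_decision(tab, 222429), "sintilimab")
  # a frontier step priced exactly at the published ICER is accepted at the
  # published threshold
  unrounded <- data.frame(strategy = c("sintilimab", "camrelizumab"),
                          cost = c(230813, 253056),
                          qalys = c(1.1, 1.1 + 22243 / 164983))
  tab2 <- icer_table(unrounded)
  expect_equal(tab2$frontier_icer[2], 164983, tolerance = 1e-6)
  expect_equal(check_wtp_decision(tab2, 287247), "camrelizumab")
})

test_that("moment matching reproduces the stated mean and spread", {
  set.seed(77)
  g <- parameterize_distribution(
    distribution_spec("cost_drug_camrelizumab", "gamma", 3558, 2519, 3558))
  x <- g(100000)
  expect_equal(mean(x), 3558, tolerance = 0.01)
  expect_equal(sd(x), (3558 - 2519) / (2 * 1.96), tolerance = 0.03)

  b <- parameterize_distribution(distribution_spec("utility_pf", "beta",
                                                   0.804, 0.536, 0.883))
  y <- b(100000)
  expect_true(all(y >= 0 & y <= 1))
  expect_equal(mean(y), 0.804, tolerance = 0.005 / 0.804)

  f <- parameterize_distribution(distribution_spec("discount_rate", "fixed", 0.05))
  expect_equal(f(10), rep(0.05, 10))
  expect_warning(z <- parameterize_distribution(
    distribution_spec("flat", "gamma", 5, 5, 5)), "fixed")
  expect_equal(z(3), rep(5, 3))
})

test_that("one-way sensitivity orders parameters by ICER width", {
  ctx <- make_context()
  specs <- list(
    distribution_spec("cost_drug_camrelizumab", "fixed", 3558, 2519, 3558),
    distribution_spec("utility_pf", "fixed", 0.804, 0.536, 0.883),
    distribution_spec("cost_carboplatin", "fixed", 364, 364, 364),
    distribution_spec("not_in_model", "fixed", 1, 0.5, 2))
  tor <- one_way_sa(ctx, specs)
  expect_equal(tor$width[tor$parameter == "cost_carboplatin"], 0)
  expect_true(tor$flagged[tor$parameter == "not_in_model"])
  expect_equal(tor$width[tor$parameter == "not_in_model"], 0)
  expect_true(all(diff(tor$width[!is.na(tor$width)]) <= 1e-9))
  # the intervention's drug price moves its own ICER monotonically downward
  cam <- tor[tor$parameter == "cost_drug_camrelizumab", ]
  expect_lt(cam$icer_low, cam$icer_base)
  expect_equal(cam$icer_high, cam$icer_base)
  # published PF-utility range stays narrower than the drug-price bar
  expect_lt(tor$width[tor$parameter == "utility_pf"],
            tor$width[tor$parameter == "cost_drug_camrelizumab"])
})

test_that("degenerate and reproducible PSA behave as stated", {
  ctx <- make_context()
  fixed <- lapply(econ_param_names(), function(p)
    distribution_spec(p, "fixed", ctx$base_params[[p]]))
  psa <- run_psa(ctx, fixed, n_iterations = 5, seed = 1)
  base <- evaluate_strategies(ctx)
  for (i in 1:5) {
    expect_equal(unname(psa$cost[i, base$strategy]), base$cost, tolerance = 1e-12)
    expect_equal(unname(psa$qalys[i, base$strategy]), base$qalys, tolerance = 1e-12)
  }
  specs <- config_dist_specs(ctx$config)
  expect_identical(run_psa(ctx, specs, 40, seed = 9), run_psa(ctx, specs, 40, seed = 9))
})

test_that("PSA means agree with the base case within Monte Carlo error", {
  ctx <- make_context()
  specs <- config_dist_specs(ctx$config)
  psa <- run_psa(ctx, specs, n_iterations = 2000, seed = 5)
  base <- evaluate_strategies(ctx)
  for (s in base$strategy) {
    se <- sd(psa$qalys[, s]) / sqrt(psa$n_iterations)
    expect_lt(abs(mean(psa$qalys[, s]) - base$qalys[base$strategy == s]), 3 * se)
  }
})

test_that("CEAC probabilities partition the iterations", {
  ctx <- make_context()
  specs <- config_dist_specs(ctx$config)
  psa <- run_psa(ctx, specs, n_iterations = 500, seed = 13)
  cc <- ceac(psa, wtp_grid = seq(0, 400000, 50000))
  expect_true(all(abs(rowSums(cc[, -1]) - 1) < 1e-9))
  expect_true(all(as.matrix(cc[, -1]) >= 0 & as.matrix(cc[, -1]) <= 1))
  # at WTP 0 the cheapest strategy per iteration wins
  cheapest <- apply(psa$cost, 1, function(x) names(x)[which.min(x)])
  expect_equal(unname(unlist(cc[cc$wtp == 0, -1]))[match("sintilimab", psa$strategies)],
               mean(cheapest == "sintilimab"), tolerance = 1e-9)
  expect_error(ceac(psa, numeric(0)), "empty")
})

test_that("rescaling the currency rescales ICERs and preserves decisions", {
  tab <- icer_table(table3)
  scaled <- table3
  scaled$cost <- scaled$cost * 7.2
  tab2 <- icer_table(scaled)
  expect_equal(tab2$icer, tab$icer * 7.2, tolerance = 1e-12)
  expect_equal(tab2$dominance, tab$dominance)
  for (w in c(0, 150000, 287247, 1e7))
    expect_equal(check_wtp_decision(tab2, w * 7.2), check_wtp_decision(tab, w))
})
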