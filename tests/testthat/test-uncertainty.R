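test_that("gamma moment matching is exact", {
  gm <- gamma_moments(100, 10)
  expect_equal(gm$shape, 100)
  expect_equal(gm$scale, 1)
  expect_error(gamma_moments(-1, 1), "mean")
  # one million draws match the specified moments within 1%
  pd <- param_distribution("g", "gamma", mean = 250, sd = 40)
  x <- draw_parameters(list(pd), n = 1e6, seed = 11)[, "g"]
  expect_lt(abs(mean(x) - 250) / 250, 0.01)
  expect_lt(abs(sd(x) - 40) / 40, 0.01)
})

test_that("parameter draws are reproducible, truncated and degenerate-safe", {
  reg <- list(
    param_distribution("a", "normal", 10, 2, lower = 0),
    param_distribution("b", "gamma", 5, 1),
    param_distribution("c", "normal", 7, 0)
  )
  d1 <- draw_parameters(reg, 100, seed = 3)
  d2 <- draw_parameters(reg, 100, seed = 3)
  expect_identical(d1, d2)
  expect_false(identical(d1, draw_parameters(reg, 100, seed = 4)))
  expect_equal(unname(d1[, "c"]), rep(7, 100))  # sd = 0 -> exact mean

  # the stream is keyed by name: shared parameters get identical draws in
  # different registries (common random numbers)
  solo <- draw_parameters(list(param_distribution("a", "normal", 10, 2,
                                                  lower = 0)), 100, seed = 3)
  expect_equal(unname(solo[, "a"]), unname(d1[, "a"]))

  tight <- list(param_distribution("t", "normal", 0.1, 1, lower = 0))
  expect_message(dt <- draw_parameters(tight, 1000, seed = 5), "truncated")
  expect_gt(attr(dt, "truncated")[["t"]], 0)
  expect_true(all(dt[, "t"] >= 0))

  expect_error(draw_parameters(list(), 10), "registry")
  expect_error(param_distribution("x", "gamma", -2, 1), "mean")
  expect_error(param_distribution("x", "normal", 0, -1), "sd")
})

test_that("effect-size draws centre on the specified mean", {
  reg <- intervention_registry()
  pd <- param_distribution("effect", "normal", 22.8,
                           spec_effect_sd(reg$mandatory_all), lower = 0)
  x <- draw_parameters(list(pd), 2000, seed = 9)[, "effect"]
  expect_lt(abs(mean(x) - 22.8), 3 * 2.28 / sqrt(2000))
})

test_that("PSA summaries are seed-stable percentile intervals", {
  # identity closure: outputs are the parameters themselves
  reg <- list(param_distribution("x", "normal", 50, 10),
              param_distribution("y", "gamma", 20, 5))
  closure <- function(p) c(out = unname(p[["x"]] + p[["y"]]))
  cfg <- psa_config(n_draws = 2000, seed = 21)
  p1 <- run_psa(closure, reg, cfg)
  p2 <- run_psa(closure, reg, cfg)
  expect_identical(p1$summary, p2$summary)
  expect_identical(p1$draws, p2$draws)

  # percentile interval = order statistics 50 and 1950 of the sorted draws
  x <- sort(p1$draws[, "out"])
  expect_equal(p1$summary$lower, x[50])
  expect_equal(p1$summary$upper, x[1950])

  # linear model: PSA mean within 3 Monte Carlo standard errors of the
  # all-means deterministic value
  det <- closure(c(x = 50, y = 20))
  mc_se <- sd(p1$draws[, "out"]) / sqrt(2000)
  expect_lt(abs(p1$summary$mean - det), 3 * mc_se)

  # degenerate registry: all sd zero collapses the interval
  reg0 <- list(param_distribution("x", "normal", 50, 0),
               param_distribution("y", "normal", 20, 0))
  p0 <- run_psa(closure, reg0, psa_config(50, 1))
  expect_equal(p0$summary$lower, p0$summary$upper)
  expect_equal(p0$summary$mean, 70)

  # failing draws are excluded and counted
  flaky <- function(p) {
    if (p[["x"]] > 50) stop("boom")
    c(out = unname(p[["x"]]))
  }
  pf <- run_psa(flaky, reg, psa_config(200, 8))
  expect_gt(pf$n_failed, 0)
  expect_equal(sum(is.na(pf$draws[, "out"])), pf$n_failed)
})

test_that("tornado ranks parameters by induced output range", {
  closure <- function(p) c(out = unname(2 * p[["big"]] + 0.1 * p[["small"]] +
                                          0 * p[["nil"]]))
  reg <- list(param_distribution("small", "normal", 5, 1),
              param_distribution("big", "normal", 5, 1),
              param_distribution("nil", "normal", 5, 0))
  tr <- tornado(closure, reg)
  expect_s3_class(tr, "tornado_result")
  expect_equal(tr$parameter, c("big", "small", "nil"))
  expect_equal(tr$range[3], 0)  # sd = 0 collapses to the deterministic point
  expect_equal(tr$range[1], 2 * diff(qnorm(c(0.025, 0.975), 5, 1)))
  single <- tornado(function(p) c(out = unname(p[["big"]])), reg[2])
  expect_equal(nrow(single), 1)
  expect_equal(attr(tr, "base"), 10.5)
})

test_that("scenario runner reproduces the structural scenario orderings", {
  b <- generate_baseline(1)
  reg <- intervention_registry()[c("counselling", "mandatory_3g",
                                   "mandatory_all")]
  sc <- run_scenarios(b, c("discount_0", "discount_6", "sunset_20y",
                           "costs_plus_50pct", "baseline"),
                      interventions = reg)
  expect_error(run_scenarios(b, "no_such_scenario"), "unknown scenario")

  # discounting order holds for every intervention
  expect_true(all(sc$discount_0$inc_qalys > sc$discount_6$inc_qalys))

  # a 20-year sunset strictly truncates mandatory interventions' benefits
  base <- sc$baseline
  sun <- sc$sunset_20y
  for (nm in c("mandatory_3g", "mandatory_all")) {
    expect_lt(sun$inc_qalys[sun$intervention == nm],
              base$inc_qalys[base$intervention == nm])
  }
  # counselling has no sunset applied
  expect_equal(sun$inc_qalys[sun$intervention == "counselling"],
               base$inc_qalys[base$intervention == "counselling"],
               tolerance = 1e-9)

  # +50% costs raise net cost by exactly half the discounted direct stream
  plus <- sc$costs_plus_50pct
  for (nm in names(reg)) {
    d_net <- plus$net_cost[plus$intervention == nm] -
      base$net_cost[base$intervention == nm]
    expect_equal(d_net, 0.5 * base$cost_direct[base$intervention == nm],
                 tolerance = 1e-9)
  }
})

test_that("alternative BP table and reduced case fatality run as scenarios", {
  b <- generate_baseline(1)
  reg <- intervention_registry()["mandatory_all"]
  sc <- run_scenarios(b, c("baseline", "he_macgregor_bp", "cfr_reduced",
                           "enforcement_costs_aus"), interventions = reg)
  expect_lt(sc$he_macgregor_bp$inc_qalys, sc$baseline$inc_qalys)
  expect_gt(sc$cfr_reduced$inc_qalys, 0)
  # enforcement costs add a recurring per-person charge to law-based options
  expect_gt(sc$enforcement_costs_aus$cost_direct, sc$baseline$cost_direct)
})
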