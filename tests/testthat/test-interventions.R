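test_that("sodium unit conversions match published figures", {
  expect_equal(round(mg_to_mmol(525), 1), 22.8)
  expect_equal(round(mg_to_mmol(296), 1), 12.9)
  expect_equal(mg_to_mmol(0), 0)
  expect_error(mg_to_mmol(-1), "non-negative")
  # mg -> mmol -> mg identity
  for (x in c(0, 100, 2300, 3544)) {
    expect_equal(mmol_to_mg(mg_to_mmol(x)), x, tolerance = 1e-12)
  }
})

test_that("sex scaling follows the intake ratios", {
  expect_equal(sex_scaled_reduction(22.8, "male"), 22.8 * 4013 / 3544)
  expect_equal(round(sex_scaled_reduction(22.8, "male"), 2), 25.82)
  expect_equal(round(sex_scaled_reduction(22.8, "female"), 2), 20.04)
  expect_equal(sex_scaled_reduction(0, "male"), 0)
  expect_equal(sex_scaled_reduction(0, "female"), 0)
  expect_error(sex_scaled_reduction(-1, "male"), "non-negative")
})

test_that("registry ships the eight named interventions", {
  reg <- intervention_registry()
  expect_setequal(names(reg), c("counselling", "endorsement_label",
                                "mandatory_3g", "mandatory_all",
                                "uk_package", "uk_media", "salt_tax",
                                "sinking_lid"))
  expect_true(all(vapply(reg, inherits, logical(1), "intervention_spec")))
  expect_equal(reg$mandatory_all$effect_mean, 22.8)
  expect_equal(reg$counselling$per_hour_effect, 7.6)
})

test_that("schedules reproduce the published ramps and targets", {
  reg <- intervention_registry()
  prof <- sodium_profile()

  uk <- build_schedule(reg$uk_package)
  expect_equal(schedule_reduction(uk, 7), 22.7)
  expect_equal(round(schedule_reduction(uk, 1), 1), 3.2)
  expect_equal(schedule_reduction(uk, 20), 22.7)  # persists for life

  expect_equal(schedule_reduction(build_schedule(reg$mandatory_all), 1), 22.8)
  expect_equal(schedule_reduction(build_schedule(reg$mandatory_3g), 1), 12.9)

  media <- build_schedule(reg$uk_media)
  expect_equal(round(schedule_reduction(media, 7), 1), 6.8)
  expect_equal(schedule_reduction(media, 7), 0.30 * 22.7)

  lid <- build_schedule(reg$sinking_lid)
  expect_equal(round(schedule_reduction(lid, 1), 1), 9.0)
  target_total <- (3544 - 2300) / 22.99
  expect_equal(schedule_reduction(lid, 6), target_total, tolerance = 1e-9)
  expect_equal(schedule_reduction(lid, 30), target_total, tolerance = 1e-9)

  # counselling: per-hour effect diluted over the adult population
  cns <- build_schedule(reg$counselling, total_adults = 2300000)
  expect_equal(schedule_reduction(cns, 1), 7.6 * 4600 / 2300000)
})

test_that("every schedule is nondecreasing and never exceeds baseline intake", {
  reg <- intervention_registry()
  prof <- sodium_profile()
  for (nm in names(reg)) {
    s <- build_schedule(reg[[nm]], prof)
    for (sex in c("male", "female")) {
      cum <- schedule_reduction(s, 1:s$horizon, sex)
      expect_true(all(diff(cum) >= -1e-12), info = nm)
      intake <- if (sex == "male") prof$intake_male else prof$intake_female
      expect_true(all(cum <= intake / prof$na_molar_mass + 1e-9), info = nm)
    }
  }
})

test_that("tax schedule solves the capped constant-proportional demand path", {
  prof <- sodium_profile()
  baseline <- prof$intake_mean / prof$na_molar_mass
  s <- solve_tax_schedule(baseline, 2300, -0.1, 0.20, 10)
  cum <- schedule_reduction(s, 1:10)
  expect_equal(round(cum[1], 1), 6.5)
  # intake path hits the target at the horizon within 0.1 mmol
  expect_equal(baseline - cum[10], 2300 / 22.99, tolerance = 0.1 / 100)
  # monotone decreasing yearly absolute reductions
  expect_true(all(diff(diff(c(0, cum))) < 0))
  # implied annual price increase p / |elasticity|
  p <- 1 - (2300 / 3544)^(1 / 10)
  expect_equal(s$annual_price_increase, p / 0.1)

  expect_error(solve_tax_schedule(baseline, 2300, -0.1, 0.01, 10),
               "infeasible")
  expect_error(solve_tax_schedule(baseline, 4000, -0.1, 0.2, 10),
               "target")
  expect_error(solve_tax_schedule(baseline, 2300, 0.1, 0.2, 10), "negative")
  # degenerate: target equal to baseline gives a zero schedule
  z <- solve_tax_schedule(baseline, 3544, -0.1, 0.2, 1)
  expect_equal(max(z$cum_mean), 0)
  # price-basis cap reading is infeasible at the default elasticity
  expect_error(solve_tax_schedule(baseline, 2300, -0.1, 0.20, 10,
                                  cap_basis = "price"), "infeasible")
})

test_that("required annual sinking-lid step matches the six-year target", {
  expect_equal(round(required_annual_step(3544, 2300, 6), 1), 9.0)
  expect_equal(round(required_annual_step(3544, 2300, 3), 1), 18.0)
  expect_equal(required_annual_step(3544, 3544, 4), 0)
  expect_error(required_annual_step(3544, 2300, 0), "years")
  expect_error(required_annual_step(2300, 3544, 6), "baseline")
})

test_that("cost streams separate one-off and recurring costs", {
  reg <- intervention_registry()
  expect_equal(intervention_cost_stream(reg$counselling, c(0, 1, 40)),
               rep(575000, 3))
  expect_equal(intervention_cost_stream(reg$mandatory_all, 0), 3680000)
  expect_equal(intervention_cost_stream(reg$mandatory_all, 5), 0)
  expect_equal(intervention_cost_stream(reg$endorsement_label, 30), 621000)
  expect_equal(intervention_cost_stream(reg$uk_package, c(0, 1)),
               c(12100000, 0))
  expect_error(intervention_cost_stream(reg$counselling, -1), "non-negative")
})

test_that("a sunset clause zeroes the reduction after the sunset year", {
  reg <- intervention_registry()
  spec <- reg$mandatory_all
  spec$sunset_year <- 20
  s <- build_schedule(spec)
  expect_equal(schedule_reduction(s, 20), 22.8)
  expect_equal(schedule_reduction(s, 21), 0)
  expect_equal(schedule_reduction(s, 40), 0)
})
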