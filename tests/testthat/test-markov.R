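zero_rates <- list(chd_incidence = 0, stroke_incidence = 0,
                   chd_case_fatality = 0, stroke_case_fatality = 0,
                   background_mortality = 0)

test_that("rate projection follows and then freezes the secular trend", {
  expect_equal(project_rate(0.01, -0.02, 2011, 2026), 0.01)
  expect_equal(project_rate(0.01, -0.02, 2013, 2026), 0.01 * 0.98^2)
  expect_equal(project_rate(0.01, -0.02, 2040, 2026), 0.01 * 0.98^15)
  expect_error(project_rate(0.01, -0.02, 2005, 2026), "base year")
})

test_that("single-cohort stepping matches hand calculations", {
  s0 <- cohort_state(age = 60, year = 2011)
  s1 <- step_cohort(s0, zero_rates)
  expect_equal(s1$occupancy, s0$occupancy)
  expect_equal(s1$age, 61)
  expect_equal(s1$year, 2012)

  forced <- modifyList(zero_rates, list(chd_incidence = 1))
  s2 <- step_cohort(s0, forced)
  expect_equal(unname(s2$occupancy[["chd_year1"]]), 1)

  # two-state toy: healthy/dead with mortality 0.1 over three years
  mort <- modifyList(zero_rates, list(background_mortality = 0.1))
  s <- s0
  expected <- c(0.9, 0.81, 0.729)
  for (k in 1:3) {
    s <- step_cohort(s, mort)
    expect_equal(unname(s$occupancy[["healthy"]]), expected[k],
                 tolerance = 1e-12)
  }

  expect_error(step_cohort(s0, zero_rates[-1]), "missing rates")
  expect_error(step_cohort(s0, modifyList(zero_rates,
                                          list(chd_incidence = 1.5))),
               "\\[0, 1\\]")
})

test_that("occupancy is conserved over ten thousand random steps", {
  set.seed(7)
  n <- 10000
  occ <- matrix(rexp(n * 6), n, 6)
  occ <- occ / rowSums(occ)
  colnames(occ) <- saltshift:::STATE_NAMES
  rates <- list(chd_incidence = runif(n, 0, 0.5),
                stroke_incidence = runif(n, 0, 0.5),
                chd_case_fatality = runif(n),
                stroke_case_fatality = runif(n),
                background_mortality = runif(n))
  res <- saltshift:::step_occupancy(occ, rates)
  expect_true(all(abs(rowSums(res$occupancy) - 1) < 1e-9))
  expect_true(all(res$occupancy >= 0))
  # dead is absorbing
  expect_true(all(res$occupancy[, "dead"] >= occ[, "dead"] - 1e-12))
})

test_that("annual QALY and cost accrual follow the state weights", {
  expect_equal(annual_qaly(cohort_state(healthy = 1), pyld = 0.288), 0.712)
  expect_equal(annual_qaly(cohort_state(healthy = 0, dead = 1)), 0)
  expect_equal(annual_qaly(cohort_state(healthy = 0, chd_later = 1),
                           pyld = 0.288), 1 - 0.288 - 0.081)
  # disability floor at zero
  expect_equal(annual_qaly(cohort_state(healthy = 0, stroke_later = 1),
                           pyld = 0.9), 0)
  expect_error(annual_qaly(cohort_state(), pyld = 1.2), "\\[0, 1\\]")

  costs <- list(healthy_annual = 2381, chd_first_year = 16258,
                chd_subsequent = 5395, stroke_first_year = 20553,
                stroke_subsequent = 5991)
  expect_equal(annual_cost(cohort_state(healthy = 1), costs),
               list(cvd = 0, non_cvd = 2381))
  expect_equal(annual_cost(cohort_state(healthy = 0, dead = 1), costs),
               list(cvd = 0, non_cvd = 0))
  expect_equal(annual_cost(cohort_state(healthy = 0, chd_year1 = 1), costs),
               list(cvd = 16258, non_cvd = 2381))
})

test_that("engine equals the path-enumeration oracle on small instances", {
  b <- flat_bundle()
  trend <- trend_spec(0, 0, c(non_maori = 0, maori = 0))
  traj <- run_cohort(b, NULL, trend = trend, econ = economic_spec(0))

  rates <- list(chd_incidence = 0.01, stroke_incidence = 0.005,
                chd_case_fatality = 0.08, stroke_case_fatality = 0.1,
                background_mortality = 0.02)
  p0 <- c(1 - 0.05 - 0.03, 0, 0.05, 0, 0.03, 0)
  occ <- oracle_enumerate(p0, rep(list(rates), 5))

  # three strata spot-checked against enumeration, five cycles each
  # (strata whose cohorts stay below the age horizon throughout)
  for (s_idx in c(1, 17, 30)) {
    for (t in 1:5) {
      expect_equal(traj$strata$alive[s_idx, t], 1 - occ[t, 6],
                   tolerance = 1e-9)
      qaly_exp <- occ[t, 1] * (1 - 0.2) +
        (occ[t, 2] + occ[t, 3]) * (1 - 0.2 - 0.081) +
        (occ[t, 4] + occ[t, 5]) * (1 - 0.2 - 0.226)
      expect_equal(traj$strata$qalys[s_idx, t], qaly_exp, tolerance = 1e-9)
    }
  }
  # population-weighted aggregate equals 52 identical strata
  expect_equal(traj$by_year$alive[3], 52 * 1000 * (1 - occ[3, 6]),
               tolerance = 1e-6)
})

test_that("a zero-effect schedule is identical to no intervention apart from its cost", {
  b <- flat_bundle()
  reg <- intervention_registry()
  spec <- reg$mandatory_all
  zero <- build_schedule(spec, effect_scale = 0)
  base <- run_cohort(b, NULL)
  with_zero <- run_cohort(b, zero, direct_cost = c(3680000, numeric(60)))
  expect_equal(with_zero$totals$qalys, base$totals$qalys, tolerance = 1e-12)
  expect_equal(with_zero$totals$cost_cvd, base$totals$cost_cvd,
               tolerance = 1e-12)
  expect_equal(with_zero$totals$cost_intervention, 3680000)
  expect_equal(base$totals$cost_intervention, 0)
})

test_that("totals are linear in population counts", {
  b <- generate_baseline(1)
  b2 <- b
  b2$population$count <- b$population$count * 2L
  b2$total_adults <- b$total_adults * 2
  t1 <- run_cohort(b)
  t2 <- run_cohort(b2)
  expect_equal(t2$totals$qalys, 2 * t1$totals$qalys, tolerance = 1e-9)
  expect_equal(t2$totals$cost_cvd, 2 * t1$totals$cost_cvd, tolerance = 1e-9)
  expect_equal(t2$totals$cost_non_cvd, 2 * t1$totals$cost_non_cvd,
               tolerance = 1e-9)
})

test_that("QALY gains shrink as the discount rate rises", {
  b <- generate_baseline(1)
  sched <- build_schedule(intervention_registry()$mandatory_all)
  gain <- vapply(c(0, 0.03, 0.06), function(r) {
    econ <- economic_spec(r)
    run_cohort(b, sched, econ = econ)$totals$qalys -
      run_cohort(b, NULL, econ = econ)$totals$qalys
  }, numeric(1))
  expect_true(gain[1] >= gain[2] && gain[2] >= gain[3])
  expect_true(all(gain > 0))
})

test_that("QALY gain is monotone in the effect size", {
  b <- generate_baseline(1)
  spec <- intervention_registry()$mandatory_all
  base <- run_cohort(b, NULL)$totals$qalys
  gains <- vapply(c(0.25, 0.5, 1, 1.5, 2), function(sc) {
    run_cohort(b, build_schedule(spec, effect_scale = sc))$totals$qalys - base
  }, numeric(1))
  expect_true(all(diff(gains) > 0))
})

test_that("discounted totals never exceed undiscounted totals", {
  traj <- run_cohort(generate_baseline(1))
  expect_lte(traj$totals$qalys, traj$totals$qalys_undiscounted)
  expect_lte(traj$totals$cost_cvd, traj$totals$cost_cvd_undiscounted)
  # essentially everyone is dead or past the age horizon by the final cycle
  # (the residue is the handful of youngest-cohort survivors at age 99)
  expect_lt(traj$by_year$alive[traj$meta$n_cycles] /
              sum(traj$strata$population), 0.01)
})

test_that("half-cycle correction is available and changes accrual smoothly", {
  b <- flat_bundle()
  full <- run_cohort(b)
  half <- run_cohort(b, half_cycle = TRUE)
  # start-of-cycle occupancy is larger, so averaged accrual is larger
  expect_gt(half$totals$qalys, full$totals$qalys)
  expect_lt((half$totals$qalys - full$totals$qalys) / full$totals$qalys, 0.05)
})
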