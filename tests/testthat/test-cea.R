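test_that("do-nothing back-calculation round-trips through re-application", {
  b <- generate_baseline(1)
  reg <- intervention_registry()
  cp <- reg[c("counselling", "endorsement_label")]
  dn <- backcalculate_do_nothing(b, cp)
  # inflation: do-nothing incidence must exceed observed
  expect_true(all(dn$epi$chd_incidence >= b$epi$chd_incidence))

  # re-apply the combined current-practice multiplier
  reapplied <- dn$epi
  age <- reapplied$age_band + 2.5
  for (i in seq_len(nrow(reapplied))) {
    for (d in c("chd", "stroke")) {
      m <- 1
      for (spec in cp) {
        full <- spec_full_effect(spec, total_adults = b$total_adults)
        delta <- sex_scaled_reduction(full, reapplied$sex[i])
        m <- m * incidence_multiplier(delta, age[i], d)
      }
      col <- paste0(d, "_incidence")
      reapplied[[col]][i] <- reapplied[[col]][i] * m
    }
  }
  expect_equal(reapplied$chd_incidence, b$epi$chd_incidence,
               tolerance = 1e-9)
  expect_equal(reapplied$stroke_incidence, b$epi$stroke_incidence,
               tolerance = 1e-9)

  # empty current practice leaves the bundle untouched
  expect_identical(backcalculate_do_nothing(b, list()), b)
  # magnitude: the combined label+counselling multiplier is a sub-percent
  # inflation of incidence
  infl <- dn$epi$chd_incidence / b$epi$chd_incidence
  expect_true(all(infl > 1 & infl < 1.02))
})

test_that("ICER computation handles dominance and degenerate cases", {
  expect_equal(compute_icer(-34e6, 7900)$label, "Dominant")
  expect_true(is.na(compute_icer(-34e6, 7900)$value))
  expect_equal(compute_icer(0, 0)$label, "undefined")
  expect_equal(compute_icer(5, 0)$label, "dominated/undefined")
  icer <- compute_icer(6900000, 200)
  expect_equal(icer$value, 34500)
  expect_equal(icer$label, "cost-effective")  # below the NZ$45,000 benchmark
  expect_equal(compute_icer(5e6, 100)$label, "not cost-effective")
  expect_error(compute_icer(1, -5), "non-negative")
})

test_that("per-adult cost components always sum to the net cost", {
  expect_equal(per_adult_costs(1.40, -509, 245)$net, -262.6)
  expect_equal(per_adult_costs(3.60, -1.00, 0.40)$net, 3.00)
  expect_equal(per_adult_costs(0, 0, 0)$net, 0)

  fit <- default_fit()
  res <- fit$results
  expect_equal(res$per_adult_net,
               res$per_adult_direct + res$per_adult_cvd + res$per_adult_non_cvd,
               tolerance = 1e-9)
  # per-adult decomposition is the population totals divided by adults
  expect_equal(res$per_adult_net * fit$settings$total_adults, res$net_cost,
               tolerance = 1e-6)

  traj <- fit$trajectories$mandatory_all
  pa <- decompose_per_adult(traj, fit$comparator, fit$settings$total_adults)
  i <- match("mandatory_all", res$intervention)
  expect_equal(pa$net, res$per_adult_net[i], tolerance = 1e-12)
  expect_error(decompose_per_adult(traj, fit$comparator, 0), "positive")
})

test_that("inequality report reproduces the generator's ethnic rate structure", {
  fit <- default_fit()
  rep0 <- inequality_report(fit$comparator)
  m5054 <- rep0[rep0$sex == "male" & rep0$age_band == 50, ]
  expect_gte(m5054$rate_ratio, 3)
  expect_lte(m5054$rate_ratio, 6)
  expect_equal(m5054$rate_difference, m5054$rate_maori - m5054$rate_non_maori)
  expect_equal(m5054$rate_ratio, m5054$rate_maori / m5054$rate_non_maori)

  # identical ethnic inputs give ratio 1 and difference 0
  b_eq <- generate_baseline(1)
  epi <- b_eq$epi
  key <- paste(epi$sex, epi$age_band)
  im <- which(epi$ethnicity == "maori")
  inm <- which(epi$ethnicity == "non_maori")[
    match(key[im], key[epi$ethnicity == "non_maori"])]
  for (cl in setdiff(names(epi), c("sex", "age_band", "ethnicity"))) {
    epi[[cl]][im] <- epi[[cl]][inm]
  }
  b_eq$epi <- epi
  # equalise the ethnicity-specific mortality trends as well
  eq_trend <- trend_spec(mortality_apc = c(non_maori = -0.0175,
                                           maori = -0.0175))
  rep_eq <- inequality_report(run_cohort(b_eq, trend = eq_trend))
  # cohorts already past the age horizon in 2021 are undefined entries
  defined <- !is.na(rep_eq$rate_ratio)
  expect_true(all(rep_eq$age_band[!defined] >= 90))
  expect_equal(rep_eq$rate_ratio[defined], rep(1, sum(defined)),
               tolerance = 1e-9)
  expect_equal(rep_eq$rate_difference[defined], rep(0, sum(defined)),
               tolerance = 1e-6)

  expect_error(inequality_report(fit$comparator, report_year = 2200),
               "horizon")
})

test_that("a mandatory intervention narrows absolute ethnic mortality gaps", {
  fit <- default_fit()
  rep_dn <- inequality_report(fit$comparator)
  rep_ma <- inequality_report(fit$comparator, fit$trajectories$mandatory_all)
  m_dn <- rep_dn[rep_dn$sex == "male" & rep_dn$age_band == 50, ]
  m_ma <- rep_ma[rep_ma$sex == "male" & rep_ma$age_band == 50, ]
  # absolute rate reduction larger for Maori (higher baseline rates)
  expect_gt(m_dn$rate_maori - m_ma$rate_maori,
            m_dn$rate_non_maori - m_ma$rate_non_maori)
  # so the rate difference narrows
  expect_lt(m_ma$rate_difference, m_dn$rate_difference)
  # per-person QALY gains positive for both ethnic groups
  expect_gt(m_ma$qaly_gain_maori, 0)
  expect_gt(m_ma$qaly_gain_non_maori, 0)
})

test_that("equity substitution expands Maori health gains", {
  b <- generate_baseline(1)
  reg <- intervention_registry()["mandatory_all"]
  fit_obs <- salt_cea(b, reg)
  fit_eq <- salt_cea(equity_substitution(b), reg)
  rep_obs <- inequality_report(fit_obs$comparator,
                               fit_obs$trajectories$mandatory_all)
  rep_eq <- inequality_report(fit_eq$comparator,
                              fit_eq$trajectories$mandatory_all)
  # lower competing mortality/morbidity expands Maori QALY gains everywhere
  expect_true(all(rep_eq$qaly_gain_maori >= rep_obs$qaly_gain_maori - 1e-12))
  expect_gt(sum(rep_eq$qaly_gain_maori), sum(rep_obs$qaly_gain_maori))
})

test_that("salt_cea methods expose the fitted results coherently", {
  fit <- default_fit()
  expect_s3_class(fit, "salt_cea")
  expect_equal(nrow(fit$results), 8)
  expect_output(print(fit), "Dominant")
  s <- summary(fit)
  expect_equal(s$qaly_order,
               fit$results$intervention[order(-fit$results$inc_qalys)])
  expect_output(print(s), "descending QALY gain")
  expect_identical(as.data.frame(fit), fit$results)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
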