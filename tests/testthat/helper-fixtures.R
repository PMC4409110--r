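# Shared fixtures and the independent path-enumeration oracle.

# A structurally valid bundle with identical rates in every stratum (flat
# age profile), so cohorts crossing band boundaries keep the same rates and
# hand calculations stay simple.
flat_bundle <- function(chd_inc = 0.01, stroke_inc = 0.005,
                        cf_chd = 0.08, cf_stroke = 0.1, bg = 0.02,
                        prev_chd = 0.05, prev_stroke = 0.03, pyld = 0.2,
                        healthy_annual = 2000, chd_first = 16000,
                        chd_sub = 5000, stroke_first = 20000,
                        stroke_sub = 6000, count = 1000) {
  st <- stratum_table()
  n <- nrow(st)
  epi <- cbind(st, data.frame(
    chd_incidence = rep(chd_inc, n), stroke_incidence = rep(stroke_inc, n),
    chd_case_fatality = rep(cf_chd, n),
    stroke_case_fatality = rep(cf_stroke, n),
    chd_prevalence = rep(prev_chd, n), stroke_prevalence = rep(prev_stroke, n),
    background_mortality = rep(bg, n), pyld = rep(pyld, n)
  ))
  costs <- cbind(st, data.frame(
    healthy_annual = rep(healthy_annual, n),
    chd_first_year = rep(chd_first, n), chd_subsequent = rep(chd_sub, n),
    stroke_first_year = rep(stroke_first, n),
    stroke_subsequent = rep(stroke_sub, n)
  ))
  population <- cbind(st, data.frame(count = rep(count, n)))
  structure(list(epi = epi, costs = costs, population = population,
                 base_year = 2011, total_adults = count * n),
            class = "baseline_bundle")
}

# Independent oracle: expected state occupancy by explicit enumeration of
# every state path, with per-cycle 6x6 transition matrices written out from
# first principles (incidence splits the healthy, death risks are summed
# and capped, tunnel states empty into the chronic states).
oracle_transition_matrix <- function(r) {
  ic <- r$chd_incidence; is_ <- r$stroke_incidence
  dc <- min(r$chd_case_fatality + r$background_mortality, 1)
  ds <- min(r$stroke_case_fatality + r$background_mortality, 1)
  P <- matrix(0, 6, 6)
  P[1, ] <- c((1 - ic - is_) * (1 - r$background_mortality), ic, 0, is_, 0,
              (1 - ic - is_) * r$background_mortality)
  P[2, ] <- c(0, 0, 1 - dc, 0, 0, dc)
  P[3, ] <- c(0, 0, 1 - dc, 0, 0, dc)
  P[4, ] <- c(0, 0, 0, 0, 1 - ds, ds)
  P[5, ] <- c(0, 0, 0, 0, 1 - ds, ds)
  P[6, 6] <- 1
  P
}

# Occupancy after each of `cycles` annual steps, by summing the probability
# of every individual path (6^cycles paths), never by matrix products.
oracle_enumerate <- function(p0, rates_by_cycle) {
  cycles <- length(rates_by_cycle)
  P <- lapply(rates_by_cycle, oracle_transition_matrix)
  occ <- matrix(0, cycles, 6)
  recurse <- function(state, t, prob) {
    if (prob == 0) return()
    if (t > 0) occ[t, state] <<- occ[t, state] + prob
    if (t == cycles) return()
    for (nxt in 1:6) recurse(nxt, t + 1, prob * P[[t + 1]][state, nxt])
  }
  for (s0 in 1:6) recurse(s0, 0, p0[s0])
  occ
}

expected_qaly_order <- c("sinking_lid", "salt_tax", "mandatory_all",
                         "uk_package", "mandatory_3g", "uk_media",
                         "endorsement_label", "counselling")

# Memoised default analysis shared by several test files.
default_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- salt_cea(generate_baseline(1))
    }
    cache
  }
})
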