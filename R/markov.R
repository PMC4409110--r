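# Markov cohort engine ---------------------------------------------------------
#
# Closed cohorts (one per stratum) run annually from the base year to death
# or age 100 through states {healthy, CHD, stroke, dead}, with first-year
# cost tunnels (chd_year1 -> chd_later, stroke_year1 -> stroke_later after
# one cycle; the tunnel is invisible to the QALY logic). Within a cycle,
# incidence is applied first; disease occupants then face case fatality plus
# background mortality (summed death risk capped at 1), and remaining
# healthy occupants face background mortality.

STATE_NAMES <- c("healthy", "chd_year1", "chd_later",
                 "stroke_year1", "stroke_later", "dead")

#' Secular trend specification
#'
#' Annual percentage changes applied to baseline rates from the base year up
#' to `trend_end_year`, after which rates are held constant: -2.0%/year for
#' CHD and stroke incidence and case fatality, and -1.75%/year (non-Maori) /
#' -2.25%/year (Maori) for background mortality.
#'
#' @param incidence_apc,case_fatality_apc Annual proportional change.
#' @param mortality_apc Named vector, one APC per ethnicity.
#' @param trend_end_year Year after which rates are held constant.
#' @param post_trend_apc APC after `trend_end_year` (default 0).
#' @return A list of class `trend_spec`.
#' @export
trend_spec <- function(incidence_apc = -0.02, case_fatality_apc = -0.02,
                       mortality_apc = c(non_maori = -0.0175,
                                         maori = -0.0225),
                       trend_end_year = 2026, post_trend_apc = 0) {
  stopifnot(all(ETHNICITIES %in% names(mortality_apc)))
  structure(list(incidence_apc = incidence_apc,
                 case_fatality_apc = case_fatality_apc,
                 mortality_apc = mortality_apc,
                 trend_end_year = trend_end_year,
                 post_trend_apc = post_trend_apc),
            class = "trend_spec")
}

#' Economic specification
#'
#' @param discount_rate Annual discount rate applied to both costs and QALYs
#'   (default 3\%; 0\% and 6\% in scenario analyses).
#' @param horizon_age Simulation stops when a cohort reaches this age.
#' @param currency_year Currency year of all costs.
#' @return A list of class `economic_spec`.
#' @export
economic_spec <- function(discount_rate = 0.03, horizon_age = 100,
                          currency_year = 2011) {
  if (discount_rate < 0) stop("discount rate must be non-negative")
  structure(list(discount_rate = discount_rate, horizon_age = horizon_age,
                 currency_year = currency_year),
            class = "economic_spec")
}

#' Project a baseline rate along its secular trend
#'
#' rate x (1 + apc)^(min(year, trend_end) - base_year): the trend runs to
#' `trend_end` and the rate is held constant thereafter.
#'
#' @param base_rate Rate at `base_year`.
#' @param apc Annual proportional change (e.g. -0.02).
#' @param year Calendar year(s) of interest (>= `base_year`).
#' @param trend_end Last year of the trend.
#' @param base_year Base calendar year.
#' @return Projected rate(s).
#' @export
#' @examples
#' project_rate(0.01, -0.02, 2013, 2026)  # 0.01 * 0.98^2
project_rate <- function(base_rate, apc, year, trend_end, base_year = 2011) {
  if (any(year < base_year)) stop("year must not precede the base year")
  base_rate * (1 + apc)^(pmin(year, trend_end) - base_year)
}

#' Construct a cohort state
#'
#' @param healthy,chd_year1,chd_later,stroke_year1,stroke_later,dead
#'   Occupancy fractions; must be non-negative and sum to 1 (tolerance 1e-9).
#' @param age Current age (years).
#' @param year Current calendar year.
#' @return A list of class `cohort_state`.
#' @export
cohort_state <- function(healthy = 1, chd_year1 = 0, chd_later = 0,
                         stroke_year1 = 0, stroke_later = 0, dead = 0,
                         age = 60, year = 2011) {
  occ <- c(healthy = healthy, chd_year1 = chd_year1, chd_later = chd_later,
           stroke_year1 = stroke_year1, stroke_later = stroke_later,
           dead = dead)
  if (any(occ < 0)) stop("occupancy fractions must be non-negative")
  if (abs(sum(occ) - 1) > 1e-9) stop("occupancy fractions must sum to 1")
  structure(list(occupancy = occ, age = age, year = year),
            class = "cohort_state")
}

# One annual transition on an occupancy matrix (rows = cohorts, cols =
# STATE_NAMES). `rates` is a list of equal-length vectors. Returns the new
# occupancy plus the CVD deaths generated during the cycle.
step_occupancy <- function(occ, rates) {
  ic <- rates$chd_incidence
  is_ <- rates$stroke_incidence
  cfc <- rates$chd_case_fatality
  cfs <- rates$stroke_case_fatality
  bg <- rates$background_mortality

  inc_sum <- ic + is_
  over <- inc_sum > 1
  if (any(over)) {
    ic[over] <- ic[over] / inc_sum[over]
    is_[over] <- is_[over] / inc_sum[over]
  }

  h <- occ[, 1L]; c1 <- occ[, 2L]; c2 <- occ[, 3L]
  s1 <- occ[, 4L]; s2 <- occ[, 5L]; d <- occ[, 6L]

  new_c1 <- h * ic
  new_s1 <- h * is_
  h_stay <- h * (1 - ic - is_)

  # Death risks within each state; competing risks within a cycle are summed
  # and capped at 1, with CVD deaths attributed in proportion to case
  # fatality's share of the total risk.
  denc <- cfc + bg
  dens <- cfs + bg
  dc <- pmin(denc, 1)
  ds <- pmin(dens, 1)
  # CVD deaths: pool * cf, rescaled when the summed risk is capped at 1
  # (a zero denominator implies cf = 0, so the product is already 0).
  cvd_deaths <- (c1 + c2) * cfc / pmax(denc, 1) +
    (s1 + s2) * cfs / pmax(dens, 1)

  chd_pool <- c1 + c2
  stroke_pool <- s1 + s2
  dead_new <- d + h_stay * bg + chd_pool * dc + stroke_pool * ds

  out <- occ
  out[, 1L] <- h_stay * (1 - bg)
  out[, 2L] <- new_c1
  out[, 3L] <- chd_pool * (1 - dc)
  out[, 4L] <- new_s1
  out[, 5L] <- stroke_pool * (1 - ds)
  out[, 6L] <- dead_new
  drift <- abs(rowSums(out) - 1)
  if (any(drift > 1e-6)) stop("occupancy sum drifted beyond 1e-6")
  list(occupancy = out, cvd_deaths = cvd_deaths)
}

#' Advance a cohort state by one annual cycle
#'
#' Healthy occupants split into incident CHD/stroke (first-year tunnel
#' states) or face background mortality; disease occupants face case
#' fatality plus background mortality and survivors move to (or stay in) the
#' later-years state; death is absorbing. Age and calendar year advance by
#' one.
#'
#' @param state A [cohort_state()].
#' @param rates Named list with `chd_incidence`, `stroke_incidence`,
#'   `chd_case_fatality`, `stroke_case_fatality`, `background_mortality`,
#'   all in \[0, 1\].
#' @return The advanced `cohort_state`.
#' @export
step_cohort <- function(state, rates) {
  req <- c("chd_incidence", "stroke_incidence", "chd_case_fatality",
           "stroke_case_fatality", "background_mortality")
  missing_r <- setdiff(req, names(rates))
  if (length(missing_r)) stop("missing rates: ", paste(missing_r, collapse = ", "))
  r <- lapply(rates[req], as.numeric)
  if (any(unlist(r) < 0) || any(unlist(r) > 1)) stop("rates must lie in [0, 1]")
  res <- step_occupancy(matrix(state$occupancy, nrow = 1), r)
  out <- cohort_state(age = state$age + 1, year = state$year + 1)
  out$occupancy <- stats::setNames(res$occupancy[1, ], STATE_NAMES)
  out
}

#' Quality-adjusted life years accrued by a cohort state in one year
#'
#' Healthy occupants contribute 1 minus the background disability (pYLD);
#' disease occupants additionally lose the disease's disability weight
#' (floored at zero); the dead contribute nothing.
#'
#' @param state A [cohort_state()].
#' @param dw_chd,dw_stroke Disability weights (defaults 0.081 and 0.226).
#' @param pyld Background prevalent disability per person.
#' @return QALYs per person-year.
#' @export
#' @examples
#' annual_qaly(cohort_state(healthy = 1), pyld = 0.288)  # 0.712
annual_qaly <- function(state, dw_chd = 0.081, dw_stroke = 0.226, pyld = 0) {
  if (any(c(dw_chd, dw_stroke, pyld) < 0) || any(c(dw_chd, dw_stroke, pyld) > 1)) {
    stop("disability weights and pYLD must lie in [0, 1]")
  }
  o <- state$occupancy
  o[["healthy"]] * (1 - pyld) +
    (o[["chd_year1"]] + o[["chd_later"]]) * max(0, 1 - pyld - dw_chd) +
    (o[["stroke_year1"]] + o[["stroke_later"]]) * max(0, 1 - pyld - dw_stroke)
}

#' Health-system costs accrued by a cohort state in one year
#'
#' Every living person accrues the healthy annual cost (non-CVD category);
#' disease occupants additionally accrue the matching first-year or
#' subsequent-year excess cost (CVD category).
#'
#' @param state A [cohort_state()].
#' @param costs List or one-row data frame with `healthy_annual`,
#'   `chd_first_year`, `chd_subsequent`, `stroke_first_year`,
#'   `stroke_subsequent`.
#' @return List with `cvd` and `non_cvd` cost per person (NZ$).
#' @export
annual_cost <- function(state, costs) {
  o <- state$occupancy
  alive <- 1 - o[["dead"]]
  list(
    cvd = o[["chd_year1"]] * costs$chd_first_year +
      o[["chd_later"]] * costs$chd_subsequent +
      o[["stroke_year1"]] * costs$stroke_first_year +
      o[["stroke_later"]] * costs$stroke_subsequent,
    non_cvd = alive * costs$healthy_annual
  )
}

#' Run all stratum cohorts through the Markov model
#'
#' Simulates the 52 closed cohorts annually from the base year until death
#' or `horizon_age`, looking up rates, costs and disability at each cohort's
#' current age band (cohorts start at their band midpoint and cross band
#' boundaries as they age), applying secular trends, the intervention's
#' sodium-reduction schedule through the BP/hazard-ratio pathway, and
#' accumulating discounted QALYs and costs (end-of-cycle accrual; an
#' optional half-cycle correction averages start- and end-of-cycle
#' occupancy).
#'
#' @param bundle A `baseline_bundle`.
#' @param schedule A `reduction_schedule`, or `NULL` for no intervention.
#' @param trend A [trend_spec()].
#' @param econ An [economic_spec()].
#' @param bp_table A [bp_coefficients()] table.
#' @param hr_table A [hazard_ratio_table()].
#' @param dw Named disability weights `c(chd = , stroke = )`.
#' @param direct_cost Direct intervention cost per year offset 0..horizon
#'   (numeric vector recycled/truncated as needed), or `NULL` for none.
#' @param annual_cost_alive Recurring direct cost (NZ$/year) accrued in
#'   proportion to the fraction of the cohort still alive (programme costs
#'   serve the modelled closed cohort, which shrinks over time).
#' @param hr_scale Named multiplicative perturbations of the hazard-ratio
#'   tables, `c(chd = 1, stroke = 1)` (sensitivity analyses).
#' @param cf_multiplier Scenario multiplier on case-fatality rates.
#' @param cost_scale Named multipliers `c(disease = 1, healthy = 1)` on the
#'   cost tables.
#' @param half_cycle Use half-cycle-corrected accrual (default FALSE: plain
#'   annual cycles).
#' @return A list of class `cohort_trajectory`: `by_year` (data frame of
#'   population-weighted annual results), `totals` (discounted and
#'   undiscounted totals), `strata` (per-stratum matrices for inequality
#'   reporting) and `meta`.
#' @export
run_cohort <- function(bundle, schedule = NULL, trend = trend_spec(),
                       econ = economic_spec(),
                       bp_table = bp_coefficients(),
                       hr_table = hazard_ratio_table(),
                       dw = c(chd = 0.081, stroke = 0.226),
                       direct_cost = NULL,
                       annual_cost_alive = 0,
                       hr_scale = c(chd = 1, stroke = 1),
                       cf_multiplier = 1,
                       cost_scale = c(disease = 1, healthy = 1),
                       half_cycle = FALSE) {
  inp <- prepare_cohort_inputs(bundle, trend, econ, bp_table, hr_table)
  run_prepared(inp, schedule, dw = dw, direct_cost = direct_cost,
               annual_cost_alive = annual_cost_alive, hr_scale = hr_scale,
               cf_multiplier = cf_multiplier, cost_scale = cost_scale,
               half_cycle = half_cycle)
}

# Precompute everything that does not depend on the intervention schedule or
# on sensitivity perturbations: age/band paths, trended base rate matrices,
# cost matrices, BP coefficient and hazard-ratio lookups, initial occupancy.
# Reused across the many model evaluations of a PSA.
prepare_cohort_inputs <- function(bundle, trend = trend_spec(),
                                  econ = economic_spec(),
                                  bp_table = bp_coefficients(),
                                  hr_table = hazard_ratio_table()) {
  st <- stratum_table()
  n <- nrow(st)
  base_year <- bundle$base_year
  start_age <- st$age_band + 2.5
  n_cycles <- as.integer(ceiling(econ$horizon_age - min(start_age)))

  epi <- bundle$epi[stratum_index(bundle$epi), ]
  costs <- bundle$costs[stratum_index(bundle$costs), ]
  pop <- bundle$population$count[stratum_index(bundle$population)]

  # Age, band and lookup-row paths for every cohort and cycle.
  age <- outer(start_age, seq_len(n_cycles) - 1, "+")
  active <- age < econ$horizon_age
  band <- pmin(35 + 5 * ((age - 35) %/% 5), 95)
  # Tables are in canonical stratum order (ethnicity fastest, then band,
  # then sex), so the lookup row is pure index arithmetic.
  sex_i <- match(st$sex, SEXES)
  eth_i <- match(st$ethnicity, ETHNICITIES)
  row_idx <- (sex_i - 1L) * (2L * length(AGE_BANDS)) +
    (band - 35) / 5 * 2L + eth_i
  look <- function(field, table = epi) {
    matrix(table[[field]][row_idx], nrow = n)
  }

  years <- base_year + seq_len(n_cycles)
  tf_inc <- (1 + trend$incidence_apc)^(pmin(years, trend$trend_end_year) - base_year)
  tf_cf <- (1 + trend$case_fatality_apc)^(pmin(years, trend$trend_end_year) - base_year)
  tf_mort <- vapply(ETHNICITIES, function(e) {
    (1 + trend$mortality_apc[[e]])^(pmin(years, trend$trend_end_year) - base_year)
  }, numeric(n_cycles))
  mort_f <- t(tf_mort[, match(st$ethnicity, ETHNICITIES), drop = FALSE])

  tr_inc <- rep(tf_inc, each = n)
  tr_cf <- rep(tf_cf, each = n)
  chd_inc0 <- look("chd_incidence") * tr_inc
  str_inc0 <- look("stroke_incidence") * tr_inc
  cf_chd0 <- look("chd_case_fatality") * tr_cf
  cf_str0 <- look("stroke_case_fatality") * tr_cf
  bg <- pmin(look("background_mortality") * mort_f, 1)

  # Freeze cohorts past the horizon age: zero rates leave occupancy fixed,
  # and the active mask zeroes their accrual.
  freeze <- function(m) { m[!active] <- 0; m }
  chd_inc0 <- freeze(chd_inc0); str_inc0 <- freeze(str_inc0)
  cf_chd0 <- freeze(cf_chd0); cf_str0 <- freeze(cf_str0); bg <- freeze(bg)

  occ0 <- matrix(0, n, 6, dimnames = list(NULL, STATE_NAMES))
  prev_c <- epi$chd_prevalence
  prev_s <- epi$stroke_prevalence
  occ0[, "healthy"] <- pmax(1 - prev_c - prev_s, 0)
  occ0[, "chd_later"] <- prev_c
  occ0[, "stroke_later"] <- prev_s

  decade <- pmin(10 * (age %/% 10), max(bp_table$decades))
  coef_mat <- matrix(bp_table$values[match(decade, bp_table$decades)], nrow = n)

  list(
    st = st, n = n, n_cycles = n_cycles, base_year = base_year,
    years = years, age = age, active = active,
    male_rows = st$sex == "male",
    chd_inc0 = chd_inc0, str_inc0 = str_inc0,
    cf_chd0 = cf_chd0, cf_str0 = cf_str0, bg = bg,
    pyld = look("pyld"),
    healthy_cost0 = look("healthy_annual", costs),
    chd_fy0 = look("chd_first_year", costs),
    chd_sub0 = look("chd_subsequent", costs),
    str_fy0 = look("stroke_first_year", costs),
    str_sub0 = look("stroke_subsequent", costs),
    coef_mat = coef_mat,
    hr_chd_mat = hr_at(hr_table, "chd", age),
    hr_str_mat = hr_at(hr_table, "stroke", age),
    occ0 = occ0, pop = pop,
    discount_rate = econ$discount_rate, horizon_age = econ$horizon_age
  )
}

run_prepared <- function(inp, schedule = NULL,
                         dw = c(chd = 0.081, stroke = 0.226),
                         direct_cost = NULL, annual_cost_alive = 0,
                         hr_scale = c(chd = 1, stroke = 1),
                         cf_multiplier = 1,
                         cost_scale = c(disease = 1, healthy = 1),
                         half_cycle = FALSE) {
  n <- inp$n
  n_cycles <- inp$n_cycles
  base_year <- inp$base_year
  years <- inp$years
  active <- inp$active
  st <- inp$st

  if (is.null(schedule)) {
    chd_inc <- inp$chd_inc0
    str_inc <- inp$str_inc0
  } else {
    delta_m <- schedule_reduction(schedule, seq_len(n_cycles), "male")
    delta_f <- schedule_reduction(schedule, seq_len(n_cycles), "female")
    delta <- matrix(NA_real_, n, n_cycles)
    delta[inp$male_rows, ] <- rep(delta_m, each = sum(inp$male_rows))
    delta[!inp$male_rows, ] <- rep(delta_f, each = sum(!inp$male_rows))
    dsbp20 <- inp$coef_mat * delta / 100 / 20
    chd_inc <- inp$chd_inc0 *
      pmin(inp$hr_chd_mat * hr_scale[["chd"]], 1)^dsbp20
    str_inc <- inp$str_inc0 *
      pmin(inp$hr_str_mat * hr_scale[["stroke"]], 1)^dsbp20
  }
  cf_chd <- if (cf_multiplier == 1) inp$cf_chd0 else pmin(inp$cf_chd0 * cf_multiplier, 1)
  cf_str <- if (cf_multiplier == 1) inp$cf_str0 else pmin(inp$cf_str0 * cf_multiplier, 1)
  bg <- inp$bg
  pyld <- inp$pyld

  healthy_cost <- inp$healthy_cost0 * cost_scale[["healthy"]]
  chd_fy <- inp$chd_fy0 * cost_scale[["disease"]]
  chd_sub <- inp$chd_sub0 * cost_scale[["disease"]]
  str_fy <- inp$str_fy0 * cost_scale[["disease"]]
  str_sub <- inp$str_sub0 * cost_scale[["disease"]]

  occ <- inp$occ0
  r <- inp$discount_rate
  disc <- (1 + r)^(-seq_len(n_cycles))
  w <- inp$pop

  qaly_strat <- matrix(0, n, n_cycles)
  deaths_strat <- matrix(0, n, n_cycles)
  alive_strat <- matrix(0, n, n_cycles)
  cost_cvd_y <- cost_ncvd_y <- qaly_y <- numeric(n_cycles)

  for (t in seq_len(n_cycles)) {
    rates_t <- list(
      chd_incidence = chd_inc[, t], stroke_incidence = str_inc[, t],
      chd_case_fatality = cf_chd[, t], stroke_case_fatality = cf_str[, t],
      background_mortality = bg[, t]
    )
    pre <- occ
    res <- step_occupancy(occ, rates_t)
    occ <- res$occupancy

    acc <- if (half_cycle) (pre + occ) / 2 else occ
    a <- active[, t]
    qw_h <- 1 - pyld[, t]
    qw_c <- pmax(0, 1 - pyld[, t] - dw[["chd"]])
    qw_s <- pmax(0, 1 - pyld[, t] - dw[["stroke"]])
    q_t <- (acc[, 1L] * qw_h + (acc[, 2L] + acc[, 3L]) * qw_c +
              (acc[, 4L] + acc[, 5L]) * qw_s) * a
    alive <- (1 - acc[, 6L])
    c_ncvd <- alive * healthy_cost[, t] * a
    c_cvd <- (acc[, 2L] * chd_fy[, t] + acc[, 3L] * chd_sub[, t] +
                acc[, 4L] * str_fy[, t] + acc[, 5L] * str_sub[, t]) * a

    qaly_strat[, t] <- q_t
    deaths_strat[, t] <- res$cvd_deaths
    alive_strat[, t] <- (1 - occ[, 6L]) * a
    qaly_y[t] <- sum(q_t * w)
    cost_cvd_y[t] <- sum(c_cvd * w)
    cost_ncvd_y[t] <- sum(c_ncvd * w)
  }

  dc <- numeric(n_cycles + 1)
  if (!is.null(direct_cost)) {
    dc[seq_along(direct_cost)] <- direct_cost[seq_len(min(length(direct_cost),
                                                          n_cycles + 1))]
  }
  alive_frac <- colSums(alive_strat * w) / sum(w)
  ann_y <- annual_cost_alive * alive_frac
  dc_disc <- dc * (1 + r)^(-(0:n_cycles))

  by_year <- data.frame(
    year = years,
    qalys = qaly_y * disc,
    qalys_undiscounted = qaly_y,
    cost_intervention = (dc[-1] + ann_y) * disc,
    cost_cvd = cost_cvd_y * disc,
    cost_non_cvd = cost_ncvd_y * disc,
    cvd_deaths = colSums(deaths_strat * w),
    alive = colSums(alive_strat * w)
  )
  totals <- list(
    qalys = sum(qaly_y * disc),
    qalys_undiscounted = sum(qaly_y),
    cost_intervention = sum(dc_disc) + sum(ann_y * disc),
    cost_cvd = sum(cost_cvd_y * disc),
    cost_non_cvd = sum(cost_ncvd_y * disc),
    cost_cvd_undiscounted = sum(cost_cvd_y),
    cost_non_cvd_undiscounted = sum(cost_ncvd_y)
  )
  structure(
    list(by_year = by_year, totals = totals,
         strata = list(table = st, population = w,
                       qalys = qaly_strat * rep(disc, each = n),
                       qalys_undiscounted = qaly_strat,
                       cvd_deaths = deaths_strat, alive = alive_strat),
         meta = list(base_year = base_year, n_cycles = n_cycles,
                     discount_rate = r, horizon_age = inp$horizon_age,
                     schedule = if (!is.null(schedule)) schedule$name else "none")),
    class = "cohort_trajectory"
  )
}

#' @export
print.cohort_trajectory <- function(x, ...) {
  cat(sprintf("Cohort trajectory (%s), %d annual cycles from %d\n",
              x$meta$schedule, x$meta$n_cycles, x$meta$base_year))
  cat(sprintf("  QALYs (discounted %.0f%%): %s\n",
              100 * x$meta$discount_rate,
              format(round(x$totals$qalys), big.mark = ",")))
  cat(sprintf("  health-system costs: CVD %s, non-CVD %s (NZ$, discounted)\n",
              format(round(x$totals$cost_cvd), big.mark = ","),
              format(round(x$totals$cost_non_cvd), big.mark = ",")))
  invisible(x)
}
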