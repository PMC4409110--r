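# Intervention schedules -------------------------------------------------------
#
# Each of the eight policies is a sodium-reduction schedule over calendar
# time plus a direct-cost stream. Population-mean reductions (mmol/day) are
# adjusted to sex-specific reductions in proportion to baseline intakes.

#' Baseline dietary sodium intake profile
#'
#' National-survey baseline intakes: 4013 mg/day for men and 3115 mg/day for
#' women (population mean 3544 mg/day), with sodium's molar mass used for
#' mg/mmol conversion.
#'
#' @param intake_male,intake_female,intake_mean Baseline intakes (mg/day).
#' @param na_molar_mass Sodium molar mass (mg/mmol).
#' @return A list of class `sodium_profile`.
#' @export
sodium_profile <- function(intake_male = 4013, intake_female = 3115,
                           intake_mean = 3544, na_molar_mass = 22.99) {
  if (any(c(intake_male, intake_female, intake_mean, na_molar_mass) <= 0)) {
    stop("all intakes and the molar mass must be positive")
  }
  if (!(intake_female < intake_mean && intake_mean < intake_male)) {
    stop("expected intake_female < intake_mean < intake_male")
  }
  structure(list(intake_male = intake_male, intake_female = intake_female,
                 intake_mean = intake_mean, na_molar_mass = na_molar_mass),
            class = "sodium_profile")
}

#' Convert a sodium mass to millimoles
#'
#' @param mass Sodium (mg/day), non-negative.
#' @param profile A [sodium_profile()] supplying the molar mass.
#' @return Sodium in mmol/day.
#' @export
#' @examples
#' round(mg_to_mmol(525), 1)  # 22.8
mg_to_mmol <- function(mass, profile = sodium_profile()) {
  if (any(mass < 0)) stop("sodium mass must be non-negative")
  mass / profile$na_molar_mass
}

#' @rdname mg_to_mmol
#' @param mmol Sodium (mmol/day).
#' @export
mmol_to_mg <- function(mmol, profile = sodium_profile()) {
  if (any(mmol < 0)) stop("sodium amount must be non-negative")
  mmol * profile$na_molar_mass
}

#' Scale a population-mean sodium reduction to one sex
#'
#' Men and women consume different baseline amounts, so a population-mean
#' reduction is scaled by the ratio of the sex-specific intake to the mean
#' intake (4013/3544 for men, 3115/3544 for women under defaults).
#'
#' @param population_mean_reduction Reduction (mmol/day), non-negative.
#' @param sex `"male"` or `"female"`.
#' @param profile A [sodium_profile()].
#' @return Sex-specific reduction (mmol/day).
#' @export
#' @examples
#' sex_scaled_reduction(22.8, "male")    # 25.82
#' sex_scaled_reduction(22.8, "female")  # 20.04
sex_scaled_reduction <- function(population_mean_reduction, sex,
                                 profile = sodium_profile()) {
  if (any(population_mean_reduction < 0)) stop("reduction must be non-negative")
  sex <- match.arg(sex, SEXES)
  intake <- if (sex == "male") profile$intake_male else profile$intake_female
  population_mean_reduction * intake / profile$intake_mean
}

#' Load the intervention registry
#'
#' Reads the shipped JSON registry of the eight named interventions with
#' their effect sizes, uncertainty, phase-in schedules and direct costs, and
#' returns a named list of `intervention_spec` objects. User overrides can be
#' supplied through a different registry file or by editing the returned
#' specs.
#'
#' @param path Path to a registry JSON file; default is the shipped registry.
#' @return Named list of `intervention_spec` objects.
#' @export
intervention_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "interventions.json", package = "saltshift")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- lapply(names(raw), function(nm) {
    do.call(intervention_spec, c(list(name = nm), raw[[nm]]))
  })
  names(specs) <- names(raw)
  specs
}

#' Construct an intervention specification
#'
#' @param name Intervention identifier (one of the eight registry names, or
#'   a user-defined name for `kind = "immediate"`/`"ramp"` specs).
#' @param kind Schedule family: `"immediate"`, `"ramp"`, `"media"`,
#'   `"counselling"`, `"tax"` or `"sinking_lid"`.
#' @param label Human-readable description.
#' @param effect_mean Population-mean sodium reduction at full effect
#'   (mmol/day); derived internally for counselling, media, tax and
#'   sinking-lid kinds.
#' @param effect_sd,effect_sd_rel Absolute or relative SD of the effect size
#'   (normal distribution, truncated at zero in sampling).
#' @param phase_years Years to full effect (1 = immediate).
#' @param cost_onetime One-off direct cost at year 0 (NZ$, e.g. passing a
#'   law or running a campaign).
#' @param cost_annual Recurring annual direct cost (NZ$/year, for the
#'   lifetime of the cohort).
#' @param cost_distribution `"gamma"` or `"normal"`.
#' @param cost_sd,cost_sd_rel Absolute or relative SD of the direct cost.
#' @param sunset_year Optional year offset after which the effect reverts to
#'   zero (sunset clause scenario).
#' @param ... Kind-specific fields: `per_hour_effect`, `per_hour_sd`,
#'   `hours_mean`, `hours_sd` (counselling); `package_effect`,
#'   `campaign_share`, `share_range` (media); `target_mg`, `elasticity`,
#'   `annual_cap`, `horizon_years` (tax); `target_mg`, `years_to_target`
#'   (sinking lid).
#' @return A list of class `intervention_spec`.
#' @export
intervention_spec <- function(name, kind, label = name,
                              effect_mean = NULL, effect_sd = NULL,
                              effect_sd_rel = NULL, phase_years = 1,
                              cost_onetime = 0, cost_annual = 0,
                              cost_distribution = c("gamma", "normal"),
                              cost_sd = NULL, cost_sd_rel = NULL,
                              sunset_year = NULL, ...) {
  kind <- match.arg(kind, c("immediate", "ramp", "media", "counselling",
                            "tax", "sinking_lid"))
  cost_distribution <- match.arg(cost_distribution)
  extra <- list(...)
  if (phase_years < 1) stop("phase_years must be >= 1")
  if (cost_onetime < 0 || cost_annual < 0) stop("costs must be non-negative")
  if (!is.null(effect_mean) && effect_mean < 0) {
    stop("effect_mean must be non-negative")
  }
  cost_point <- if (cost_onetime > 0) cost_onetime else cost_annual
  if (is.null(cost_sd)) {
    cost_sd <- if (!is.null(cost_sd_rel)) cost_sd_rel * cost_point else 0
  }
  spec <- c(list(name = name, kind = kind, label = label,
                 effect_mean = effect_mean, effect_sd = effect_sd,
                 effect_sd_rel = effect_sd_rel, phase_years = phase_years,
                 cost_onetime = cost_onetime, cost_annual = cost_annual,
                 cost_distribution = cost_distribution, cost_sd = cost_sd,
                 sunset_year = sunset_year),
            extra)
  structure(spec, class = "intervention_spec")
}

#' Population-mean sodium reduction of a spec at full effect
#'
#' Counselling dilutes its per-hour trial effect over the whole adult
#' population (per-hour effect x total annual hours / adults); media
#' campaigns take a share of the package effect; tax and sinking-lid
#' schedules run down to the 2300 mg/day intake target.
#'
#' @param spec An `intervention_spec`.
#' @param profile A [sodium_profile()].
#' @param total_adults Adult population size (used for counselling dilution).
#' @return Full-effect population-mean reduction (mmol/day).
#' @export
spec_full_effect <- function(spec, profile = sodium_profile(),
                             total_adults = 2300000) {
  switch(spec$kind,
    counselling = spec$per_hour_effect * spec$hours_mean / total_adults,
    media = spec$campaign_share * spec$package_effect,
    tax = ,
    sinking_lid = (profile$intake_mean - spec$target_mg) / profile$na_molar_mass,
    spec$effect_mean
  )
}

# SD of the full-effect reduction, for sampling and tornado bounds.
spec_effect_sd <- function(spec, profile = sodium_profile(),
                           total_adults = 2300000) {
  full <- spec_full_effect(spec, profile, total_adults)
  if (spec$kind == "counselling") {
    # Product of independent normal x gamma: first-order variance propagation.
    sqrt(spec$per_hour_sd^2 * spec$hours_mean^2 +
           spec$per_hour_effect^2 * spec$hours_sd^2) / total_adults
  } else if (!is.null(spec$effect_sd)) {
    spec$effect_sd
  } else if (!is.null(spec$effect_sd_rel)) {
    spec$effect_sd_rel * full
  } else {
    0
  }
}

new_reduction_schedule <- function(name, cum_mean, profile, sunset_year = NULL,
                                   annual_price_increase = NULL) {
  horizon <- length(cum_mean)
  if (!is.null(sunset_year) && sunset_year < horizon) {
    cum_mean[(sunset_year + 1):horizon] <- 0
  }
  male_cap <- profile$intake_male / profile$na_molar_mass
  female_cap <- profile$intake_female / profile$na_molar_mass
  structure(
    list(name = name, horizon = horizon, cum_mean = cum_mean,
         cum_male = pmin(cum_mean * profile$intake_male / profile$intake_mean,
                         male_cap),
         cum_female = pmin(cum_mean * profile$intake_female /
                             profile$intake_mean, female_cap),
         sunset_year = sunset_year,
         annual_price_increase = annual_price_increase),
    class = "reduction_schedule"
  )
}

#' @export
print.reduction_schedule <- function(x, ...) {
  cat(sprintf("Sodium reduction schedule '%s' (%d-year horizon)\n",
              x$name, x$horizon))
  full <- max(x$cum_mean)
  yr <- which(x$cum_mean >= full - 1e-12)[1]
  cat(sprintf("  full effect: %.1f mmol/d (population mean) from year %d\n",
              full, yr))
  if (!is.null(x$sunset_year)) {
    cat(sprintf("  sunset: reverts to zero after year %d\n", x$sunset_year))
  }
  if (!is.null(x$annual_price_increase)) {
    cat(sprintf("  implied annual price increase: %.1f%%\n",
                100 * x$annual_price_increase))
  }
  invisible(x)
}

#' Cumulative reduction delivered by a schedule
#'
#' @param schedule A `reduction_schedule`.
#' @param year Year offset(s) since intervention start (1 = first year).
#' @param sex `"male"`, `"female"` or `"mean"`.
#' @return Cumulative reduction (mmol/day) at each year.
#' @export
schedule_reduction <- function(schedule, year, sex = "mean") {
  v <- switch(sex, male = schedule$cum_male, female = schedule$cum_female,
              mean = schedule$cum_mean,
              stop("sex must be 'male', 'female' or 'mean'"))
  idx <- pmin(pmax(year, 1), schedule$horizon)
  out <- v[idx]
  out[year < 1] <- 0
  out
}

#' Build the sodium-reduction schedule of an intervention
#'
#' Counselling, labelling and both mandatory reformulation options take
#' immediate full effect in year 1; the UK package (and its media-campaign
#' share) ramps linearly in equal annual increments over seven years; the
#' sinking lid steps down by the required annual amount until the intake
#' target is reached; the salt tax follows [solve_tax_schedule()]. All
#' effects persist for the cohort's lifetime unless `sunset_year` is set on
#' the spec.
#'
#' @param spec An `intervention_spec`.
#' @param profile A [sodium_profile()].
#' @param horizon Schedule length in years.
#' @param total_adults Adult population (counselling dilution).
#' @param effect_scale Multiplier applied to the whole schedule (used by the
#'   sensitivity machinery).
#' @return A `reduction_schedule`.
#' @export
#' @examples
#' reg <- intervention_registry()
#' s <- build_schedule(reg$uk_package)
#' round(schedule_reduction(s, 7), 1)  # 22.7
build_schedule <- function(spec, profile = sodium_profile(), horizon = 70,
                           total_adults = 2300000, effect_scale = 1) {
  if (!inherits(spec, "intervention_spec")) stop("spec must be an intervention_spec")
  t <- seq_len(horizon)
  price <- NULL
  if (spec$kind == "tax") {
    baseline_mmol <- profile$intake_mean / profile$na_molar_mass
    ts <- solve_tax_schedule(baseline_mmol, spec$target_mg, spec$elasticity,
                             spec$annual_cap, spec$horizon_years,
                             profile = profile, horizon = horizon)
    cum <- ts$cum_mean
    price <- ts$annual_price_increase
  } else if (spec$kind == "sinking_lid") {
    step <- required_annual_step(profile$intake_mean, spec$target_mg,
                                 spec$years_to_target, profile)
    total <- (profile$intake_mean - spec$target_mg) / profile$na_molar_mass
    cum <- pmin(step * t, total)
  } else {
    full <- spec_full_effect(spec, profile, total_adults)
    cum <- full * pmin(t / spec$phase_years, 1)
  }
  new_reduction_schedule(spec$name, cum * effect_scale, profile,
                         sunset_year = spec$sunset_year,
                         annual_price_increase = price)
}

#' Solve the excise-tax sodium reduction schedule
#'
#' The tax rises annually so that intake falls by a constant proportional
#' demand reduction p = 1 - (target/baseline)^(1/horizon) each year, which
#' reaches the intake target exactly at the horizon with strictly decreasing
#' absolute annual reductions (the largest in year one). The demand
#' reduction must respect the annual cap; the implied annual price increase
#' is p / |elasticity|.
#'
#' @param baseline Baseline population-mean intake (mmol/day).
#' @param target_mg Intake target (mg/day).
#' @param elasticity Price elasticity of salt demand (negative; default in
#'   the registry is -0.1).
#' @param annual_cap Maximum proportional demand reduction in any one year
#'   (or price-change cap when `cap_basis = "price"`).
#' @param horizon_years Years over which the target is reached.
#' @param profile A [sodium_profile()].
#' @param horizon Total schedule length (plateau after `horizon_years`).
#' @param cap_basis Whether the cap constrains the annual demand change
#'   (default) or the annual price change.
#' @return A `reduction_schedule` whose `annual_price_increase` reports
#'   p / |elasticity|.
#' @export
#' @examples
#' s <- solve_tax_schedule(3544 / 22.99, 2300, -0.1, 0.20, 10)
#' round(schedule_reduction(s, 1), 1)  # 6.5 mmol/d in the first year
solve_tax_schedule <- function(baseline, target_mg, elasticity,
                               annual_cap = 0.20, horizon_years = 10,
                               profile = sodium_profile(), horizon = 70,
                               cap_basis = c("demand", "price")) {
  cap_basis <- match.arg(cap_basis)
  if (elasticity >= 0) stop("elasticity must be negative")
  if (annual_cap <= 0 || annual_cap > 1) stop("annual_cap must be in (0, 1]")
  target <- target_mg / profile$na_molar_mass
  if (target > baseline) stop("target must not exceed baseline intake")
  p <- 1 - (target / baseline)^(1 / horizon_years)
  capped <- switch(cap_basis, demand = p, price = p / abs(elasticity))
  if (capped > annual_cap + 1e-12) {
    stop(sprintf(
      "infeasible horizon: annual %s reduction %.3f exceeds cap %.3f",
      cap_basis, capped, annual_cap))
  }
  t <- seq_len(horizon)
  cum <- baseline * (1 - (1 - p)^pmin(t, horizon_years))
  new_reduction_schedule("salt_tax", cum, profile,
                         annual_price_increase = p / abs(elasticity))
}

#' Annual sodium step needed to reach a target in a fixed number of years
#'
#' @param baseline_mg,target_mg Baseline and target intakes (mg/day).
#' @param years Years to target (>= 1).
#' @param profile A [sodium_profile()].
#' @return Annual reduction (mmol/day); report rounded to 1 decimal place.
#' @export
#' @examples
#' round(required_annual_step(3544, 2300, 6), 1)  # 9.0
required_annual_step <- function(baseline_mg, target_mg, years,
                                 profile = sodium_profile()) {
  if (years <= 0) stop("years must be >= 1")
  if (baseline_mg < target_mg) stop("baseline must be >= target")
  ((baseline_mg - target_mg) / profile$na_molar_mass) / years
}

#' Direct cost of an intervention at a given year offset
#'
#' One-off law or campaign costs fall at year 0; programme costs
#' (counselling, labelling) recur every year for the lifetime of the cohort.
#'
#' @param spec An `intervention_spec`.
#' @param year_offset Year(s) since intervention start (0 = launch year).
#' @param cost_scale Multiplier on the whole stream (sensitivity analyses).
#' @return Direct cost (NZ$) at each offset.
#' @export
#' @examples
#' reg <- intervention_registry()
#' intervention_cost_stream(reg$mandatory_all, c(0, 5))  # 3680000, 0
intervention_cost_stream <- function(spec, year_offset, cost_scale = 1) {
  if (any(year_offset < 0)) stop("year_offset must be non-negative")
  ((year_offset == 0) * spec$cost_onetime + spec$cost_annual) * cost_scale
}

# Discounted total of the direct-cost stream over cycles 0..horizon.
discounted_cost_stream <- function(spec, horizon, discount_rate,
                                   cost_scale = 1) {
  offsets <- 0:horizon
  sum(intervention_cost_stream(spec, offsets, cost_scale) /
        (1 + discount_rate)^offsets)
}
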