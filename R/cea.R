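# Generalised cost-effectiveness analysis --------------------------------------
#
# All interventions, including the two current-practice programmes
# (counselling and the endorsement label), are evaluated against a
# theoretical "do nothing" comparator. Observed rates already embed current
# practice, so the comparator's disease rates are back-calculated by
# removing the current-practice incidence multipliers.

# Combined incidence multiplier of a set of specs at full effect, for one
# sex and age (multiplicative composition: independent pathways through the
# same BP mechanism).
combined_multiplier <- function(specs, age, sex, disease,
                                profile = sodium_profile(),
                                bp_table = bp_coefficients(),
                                hr_table = hazard_ratio_table(),
                                total_adults = 2300000) {
  m <- 1
  for (spec in specs) {
    full <- spec_full_effect(spec, profile, total_adults)
    delta <- sex_scaled_reduction(full, sex, profile)
    m <- m * incidence_multiplier(delta, age, disease, bp_table, hr_table)
  }
  m
}

#' Back-calculate "do nothing" disease rates
#'
#' Observed incidence reflects interventions already operating (current
#' practice). Dividing the observed CHD and stroke incidence by the combined
#' incidence multiplier of the current-practice specs recovers the rates of
#' a world in which none of the modelled interventions exist; re-applying
#' the same specs reproduces the observed rates exactly.
#'
#' @param observed A `baseline_bundle` of observed (current practice) rates.
#' @param current_practice List of `intervention_spec`s currently operating
#'   (defaults, per the modelled setting, to counselling and the endorsement
#'   label programme).
#' @param profile,bp_table,hr_table Pathway tables.
#' @return A `baseline_bundle` with inflated incidence rates.
#' @export
backcalculate_do_nothing <- function(observed,
                                     current_practice = intervention_registry()[
                                       c("counselling", "endorsement_label")],
                                     profile = sodium_profile(),
                                     bp_table = bp_coefficients(),
                                     hr_table = hazard_ratio_table()) {
  if (length(current_practice) == 0) return(observed)
  out <- observed
  epi <- out$epi
  age <- epi$age_band + 2.5
  for (i in seq_len(nrow(epi))) {
    for (disease in c("chd", "stroke")) {
      m <- combined_multiplier(current_practice, age[i], epi$sex[i], disease,
                               profile, bp_table, hr_table,
                               observed$total_adults)
      if (m <= 0) stop("combined multiplier must be positive")
      col <- paste0(disease, "_incidence")
      epi[[col]][i] <- shift_incidence(epi[[col]][i], m, "remove")
    }
  }
  out$epi <- epi
  out
}

#' Incremental cost-effectiveness ratio with dominance labelling
#'
#' @param net_cost Incremental net cost (NZ$) versus the comparator.
#' @param qalys Incremental QALYs (>= 0).
#' @param threshold Willingness-to-pay benchmark (NZ$/QALY; nominal GDP per
#'   capita, 45,000).
#' @return List of class `icer` with `value` (NZ$/QALY, `NA` when dominant or
#'   undefined), `label` (`"Dominant"`, `"cost-effective"`,
#'   `"not cost-effective"` or `"dominated/undefined"`) and the inputs.
#' @export
#' @examples
#' compute_icer(-34e6, 7900)$label  # "Dominant"
compute_icer <- function(net_cost, qalys, threshold = 45000) {
  if (qalys < 0) stop("incremental QALYs must be non-negative here")
  if (qalys == 0) {
    label <- if (net_cost > 0) "dominated/undefined" else "undefined"
    value <- NA_real_
  } else if (net_cost < 0) {
    label <- "Dominant"
    value <- NA_real_
  } else {
    value <- net_cost / qalys
    label <- if (value <= threshold) "cost-effective" else "not cost-effective"
  }
  structure(list(value = value, label = label, net_cost = net_cost,
                 qalys = qalys, threshold = threshold),
            class = "icer")
}

#' @export
print.icer <- function(x, ...) {
  if (x$label == "Dominant") {
    cat("Dominant (cost-saving with health gain)\n")
  } else if (is.na(x$value)) {
    cat(x$label, "\n")
  } else {
    cat(sprintf("NZ$%s per QALY (%s at threshold NZ$%s)\n",
                format(round(x$value), big.mark = ","), x$label,
                format(x$threshold, big.mark = ",")))
  }
  invisible(x)
}

#' Per-adult cost decomposition
#'
#' Splits an intervention's incremental discounted cost (versus the
#' comparator trajectory) into direct intervention cost, CVD health-system
#' cost change and non-CVD health-system cost change, each divided by the
#' adult population; the net per-adult cost is the sum of the three
#' components.
#'
#' @param intervention,comparator `cohort_trajectory` objects with matching
#'   horizons (the intervention trajectory carries the direct cost stream).
#' @param total_adults Adult population count (> 0).
#' @return List of class `per_adult_costs` with `direct`, `cvd_delta`,
#'   `non_cvd_delta` and `net` (NZ$ per adult).
#' @export
decompose_per_adult <- function(intervention, comparator, total_adults) {
  if (total_adults <= 0) stop("adult count must be positive")
  if (intervention$meta$n_cycles != comparator$meta$n_cycles) {
    stop("trajectories must share the same horizon")
  }
  per_adult_costs(
    direct = intervention$totals$cost_intervention / total_adults,
    cvd_delta = (intervention$totals$cost_cvd -
                   comparator$totals$cost_cvd) / total_adults,
    non_cvd_delta = (intervention$totals$cost_non_cvd -
                       comparator$totals$cost_non_cvd) / total_adults
  )
}

#' @rdname decompose_per_adult
#' @param direct,cvd_delta,non_cvd_delta Per-adult cost components (NZ$).
#' @export
#' @examples
#' per_adult_costs(1.40, -509, 245)$net  # -262.6
per_adult_costs <- function(direct, cvd_delta, non_cvd_delta) {
  structure(list(direct = direct, cvd_delta = cvd_delta,
                 non_cvd_delta = non_cvd_delta,
                 net = direct + cvd_delta + non_cvd_delta),
            class = "per_adult_costs")
}

#' Ethnic inequality report
#'
#' CVD mortality rates (deaths in the report year divided by persons alive
#' that year, per 100,000), Maori minus non-Maori rate differences and
#' Maori : non-Maori rate ratios within sex and baseline age band, plus -
#' when an intervention trajectory is supplied - the discounted QALYs gained
#' per individual between the base year and the report year.
#'
#' @param comparator A `cohort_trajectory` for the "do nothing" world.
#' @param intervention Optional `cohort_trajectory` under an intervention
#'   (its rates are reported and QALY gains are versus `comparator`).
#' @param report_year Calendar year of the mortality snapshot (default 2021).
#' @return Data frame keyed by sex and baseline age band with per-ethnicity
#'   rates, `rate_difference`, `rate_ratio` and (if applicable)
#'   `qaly_gain_per_person` columns.
#' @export
inequality_report <- function(comparator, intervention = NULL,
                              report_year = 2021) {
  traj <- if (is.null(intervention)) comparator else intervention
  t_idx <- report_year - traj$meta$base_year
  if (t_idx < 1 || t_idx > traj$meta$n_cycles) {
    stop("report year outside the simulated horizon")
  }
  st <- traj$strata$table
  pop <- traj$strata$population
  deaths <- traj$strata$cvd_deaths[, t_idx] * pop
  alive <- traj$strata$alive[, t_idx] * pop

  gain_pp <- NULL
  if (!is.null(intervention)) {
    tt <- seq_len(t_idx)
    gain <- rowSums(intervention$strata$qalys[, tt, drop = FALSE]) -
      rowSums(comparator$strata$qalys[, tt, drop = FALSE])
    gain_pp <- gain  # per-person occupancy-scale QALYs
  }

  rows <- unique(st[st$ethnicity == "non_maori", c("sex", "age_band")])
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    sel <- function(e) which(st$sex == rows$sex[i] &
                               st$age_band == rows$age_band[i] &
                               st$ethnicity == e)
    im <- sel("maori"); inm <- sel("non_maori")
    rate <- function(j) {
      if (alive[j] <= 0) return(NA_real_)
      deaths[j] / alive[j] * 1e5
    }
    r_m <- rate(im); r_nm <- rate(inm)
    data.frame(
      sex = rows$sex[i], age_band = rows$age_band[i],
      rate_maori = r_m, rate_non_maori = r_nm,
      rate_difference = r_m - r_nm,
      rate_ratio = if (!is.na(r_nm) && r_nm > 0) r_m / r_nm else NA_real_,
      qaly_gain_maori = if (is.null(gain_pp)) NA_real_ else gain_pp[im],
      qaly_gain_non_maori = if (is.null(gain_pp)) NA_real_ else gain_pp[inm],
      stringsAsFactors = FALSE
    )
  }))
  attr(out, "report_year") <- report_year
  out
}

#' Equity substitution of background health
#'
#' Replaces the Maori strata's background (non-CVD) mortality and background
#' disability (pYLD) with the non-Maori values at equal sex and age, so that
#' Maori are not penalised in potential health gain by poorer background
#' health; disease rates are untouched. Idempotent.
#'
#' @param bundle A `baseline_bundle`.
#' @return The modified bundle.
#' @export
equity_substitution <- function(bundle) {
  epi <- bundle$epi
  im <- which(epi$ethnicity == "maori")
  key <- paste(epi$sex, epi$age_band)
  inm <- which(epi$ethnicity == "non_maori")[
    match(key[im], key[epi$ethnicity == "non_maori"])]
  epi$background_mortality[im] <- epi$background_mortality[inm]
  epi$pyld[im] <- epi$pyld[inm]
  bundle$epi <- epi
  bundle
}

#' Generalised cost-effectiveness analysis of sodium interventions
#'
#' The central fitting-style function of the package: back-calculates the
#' "do nothing" comparator from the observed baseline, runs the Markov
#' cohort model for the comparator and for each intervention's
#' sodium-reduction schedule and direct-cost stream, and assembles
#' incremental QALYs, net costs, ICERs with dominance labelling and the
#' per-adult cost decomposition.
#'
#' @param bundle A `baseline_bundle` of observed rates.
#' @param interventions Named list of `intervention_spec`s to evaluate
#'   (default: the full shipped registry of eight).
#' @param current_practice Names of specs treated as current practice for
#'   the comparator back-calculation.
#' @param profile,bp_table,hr_table,trend,econ Model settings.
#' @param cf_multiplier,cost_scale,hr_scale,dw Scenario knobs passed to
#'   [run_cohort()].
#' @param cost_stream_scale Multiplier on all direct-cost streams.
#' @param extra_annual_cost Additional recurring direct cost (NZ$/year)
#'   added to every law-based intervention (enforcement-cost scenario).
#' @param keep_trajectories Keep the full per-intervention trajectories
#'   (needed for [inequality_report()]).
#' @return An object of class `salt_cea` with a `results` data frame (one
#'   row per intervention), the comparator totals and trajectory, and the
#'   settings used.
#' @export
#' @examples
#' \donttest{
#' bundle <- generate_baseline(1)
#' fit <- salt_cea(bundle)
#' print(fit)
#' }
salt_cea <- function(bundle,
                     interventions = intervention_registry(),
                     current_practice = c("counselling", "endorsement_label"),
                     profile = sodium_profile(),
                     bp_table = bp_coefficients(),
                     hr_table = hazard_ratio_table(),
                     trend = trend_spec(),
                     econ = economic_spec(),
                     cf_multiplier = 1,
                     cost_scale = c(disease = 1, healthy = 1),
                     hr_scale = c(chd = 1, stroke = 1),
                     dw = c(chd = 0.081, stroke = 0.226),
                     cost_stream_scale = 1,
                     extra_annual_cost = 0,
                     keep_trajectories = TRUE) {
  validate_bundle(bundle)
  cp <- interventions[intersect(current_practice, names(interventions))]
  do_nothing <- backcalculate_do_nothing(bundle, cp, profile, bp_table,
                                         hr_table)
  inp <- prepare_cohort_inputs(do_nothing, trend, econ, bp_table, hr_table)
  comparator <- run_prepared(inp, NULL, dw = dw, hr_scale = hr_scale,
                             cf_multiplier = cf_multiplier,
                             cost_scale = cost_scale)
  n_cycles <- comparator$meta$n_cycles
  total_adults <- bundle$total_adults

  law_based <- c("mandatory_3g", "mandatory_all", "salt_tax", "sinking_lid")
  rows <- list()
  trajectories <- list()
  for (nm in names(interventions)) {
    spec <- interventions[[nm]]
    sched <- build_schedule(spec, profile, horizon = n_cycles,
                            total_adults = total_adults)
    # One-off law/campaign costs fall at year 0; recurring programme costs
    # accrue in proportion to the surviving cohort.
    dc <- c(spec$cost_onetime * cost_stream_scale, numeric(n_cycles))
    annual <- spec$cost_annual * cost_stream_scale
    if (extra_annual_cost > 0 && nm %in% law_based) {
      annual <- annual + extra_annual_cost
    }
    traj <- run_prepared(inp, sched, dw = dw, direct_cost = dc,
                         annual_cost_alive = annual, hr_scale = hr_scale,
                         cf_multiplier = cf_multiplier,
                         cost_scale = cost_scale)
    inc_qalys <- traj$totals$qalys - comparator$totals$qalys
    d_cvd <- traj$totals$cost_cvd - comparator$totals$cost_cvd
    d_ncvd <- traj$totals$cost_non_cvd - comparator$totals$cost_non_cvd
    direct <- traj$totals$cost_intervention
    net <- direct + d_cvd + d_ncvd
    icer <- compute_icer(net, max(inc_qalys, 0))
    pa <- decompose_per_adult(traj, comparator, total_adults)
    rows[[nm]] <- data.frame(
      intervention = nm, label = spec$label,
      inc_qalys = inc_qalys, cost_direct = direct,
      cost_cvd_delta = d_cvd, cost_non_cvd_delta = d_ncvd,
      net_cost = net, icer = icer$value, icer_label = icer$label,
      per_adult_direct = pa$direct, per_adult_cvd = pa$cvd_delta,
      per_adult_non_cvd = pa$non_cvd_delta, per_adult_net = pa$net,
      stringsAsFactors = FALSE
    )
    if (keep_trajectories) trajectories[[nm]] <- traj
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(
    list(results = results,
         comparator = comparator,
         trajectories = trajectories,
         do_nothing_bundle = do_nothing,
         settings = list(profile = profile, bp_table = bp_table,
                         hr_table = hr_table, trend = trend, econ = econ,
                         current_practice = current_practice,
                         total_adults = total_adults,
                         cf_multiplier = cf_multiplier)),
    class = "salt_cea"
  )
}

#' @export
print.salt_cea <- function(x, ...) {
  cat("Generalised cost-effectiveness analysis: sodium reduction\n")
  cat(sprintf("  comparator ('do nothing'): %s QALYs, NZ$%sM health-system cost\n",
              format(signif(x$comparator$totals$qalys, 3), big.mark = ","),
              format(round((x$comparator$totals$cost_cvd +
                              x$comparator$totals$cost_non_cvd) / 1e6),
                     big.mark = ",")))
  res <- x$results[order(-x$results$inc_qalys), ]
  df <- data.frame(
    intervention = res$intervention,
    QALYs_gained = signif(res$inc_qalys, 3),
    net_cost_MNZD = signif(res$net_cost / 1e6, 3),
    ICER = ifelse(res$icer_label == "Dominant", "Dominant",
                  ifelse(is.na(res$icer), res$icer_label,
                         format(round(res$icer), big.mark = ",")))
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.salt_cea <- function(object, ...) {
  res <- object$results
  structure(list(
    results = res,
    n_dominant = sum(res$icer_label == "Dominant"),
    qaly_order = res$intervention[order(-res$inc_qalys)],
    threshold = 45000
  ), class = "summary.salt_cea")
}

#' @export
print.summary.salt_cea <- function(x, ...) {
  cat("Interventions in descending QALY gain:\n  ")
  cat(paste(x$qaly_order, collapse = " > "), "\n")
  cat(sprintf("%d of %d interventions are dominant (cost-saving).\n",
              x$n_dominant, nrow(x$results)))
  invisible(x)
}

#' @export
as.data.frame.salt_cea <- function(x, ...) x$results

#' Cost-effectiveness plane
#'
#' Plots incremental QALYs against incremental net cost for every
#' intervention (deterministic points; PSA clouds can be overlaid from
#' [run_psa()] draws).
#'
#' @param x A `salt_cea` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.salt_cea <- function(x, ...) {
  res <- x$results
  graphics::plot(res$inc_qalys, res$net_cost / 1e6,
                 xlab = "Incremental QALYs",
                 ylab = "Incremental net cost (NZ$ million)",
                 pch = 19, ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  graphics::text(res$inc_qalys, res$net_cost / 1e6, res$intervention,
                 pos = 3, cex = 0.7)
  invisible(x)
}
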