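# Probabilistic sensitivity analysis and scenarios -----------------------------

#' Describe a parameter's sampling distribution
#'
#' Normal or gamma, by mean and SD, with optional truncation bounds. Gamma
#' parameters are moment-matched: shape = (mean/sd)^2, scale = sd^2/mean.
#'
#' @param name Parameter name (also keys the common-random-number stream:
#'   the same name draws the same values at the same seed in any registry).
#' @param family `"normal"` or `"gamma"`.
#' @param mean,sd Moments of the distribution; `sd = 0` yields the mean
#'   exactly.
#' @param lower,upper Optional truncation bounds (draws are clamped, and
#'   clamping is counted, not resampled, so the number of draws stays
#'   fixed).
#' @return A list of class `param_distribution`.
#' @export
param_distribution <- function(name, family = c("normal", "gamma"),
                               mean, sd, lower = NULL, upper = NULL) {
  family <- match.arg(family)
  if (sd < 0) stop("sd must be non-negative")
  if (family == "gamma" && mean <= 0) stop("gamma requires mean > 0")
  structure(list(name = name, family = family, mean = mean, sd = sd,
                 lower = lower, upper = upper),
            class = "param_distribution")
}

#' Moment-matched gamma parameters
#'
#' @param mean,sd Target mean and standard deviation (mean > 0, sd > 0).
#' @return List with `shape` and `scale`.
#' @export
#' @examples
#' gamma_moments(100, 10)  # shape 100, scale 1
gamma_moments <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) stop("gamma moments require mean > 0 and sd > 0")
  list(shape = (mean / sd)^2, scale = sd^2 / mean)
}

# Per-parameter seed: the draw stream is keyed by the parameter NAME, so
# parameters shared between intervention registries receive identical draws
# at the same seed (common random numbers across interventions).
param_seed <- function(seed, name) {
  (as.integer(seed) %% 100000L) * 17477L + sum(utf8ToInt(name)) %% 17477L
}

draw_one <- function(pd, n, seed) {
  if (pd$sd == 0) {
    x <- rep(pd$mean, n)
  } else {
    x <- with_seed(param_seed(seed, pd$name), {
      if (pd$family == "normal") {
        stats::rnorm(n, pd$mean, pd$sd)
      } else {
        gm <- gamma_moments(pd$mean, pd$sd)
        stats::rgamma(n, shape = gm$shape, scale = gm$scale)
      }
    })
  }
  trunc_n <- 0L
  if (!is.null(pd$lower)) {
    trunc_n <- trunc_n + sum(x < pd$lower)
    x <- pmax(x, pd$lower)
  }
  if (!is.null(pd$upper)) {
    trunc_n <- trunc_n + sum(x > pd$upper)
    x <- pmin(x, pd$upper)
  }
  list(x = x, truncated = trunc_n)
}

#' Draw parameter sets from a registry
#'
#' @param registry List of [param_distribution()] objects.
#' @param n Number of draws.
#' @param seed Integer seed; the same seed reproduces the draws exactly.
#' @return An `n` x `p` matrix with one column per parameter; the
#'   `"truncated"` attribute counts clamped draws per parameter.
#' @export
draw_parameters <- function(registry, n = 1, seed = 1) {
  if (length(registry) == 0) stop("registry must contain parameters")
  nms <- vapply(registry, function(p) p$name, character(1))
  draws <- matrix(NA_real_, n, length(registry), dimnames = list(NULL, nms))
  truncated <- integer(length(registry))
  names(truncated) <- nms
  for (j in seq_along(registry)) {
    d <- draw_one(registry[[j]], n, seed)
    draws[, j] <- d$x
    truncated[j] <- d$truncated
  }
  if (any(truncated > 0)) {
    message("truncated draws: ",
            paste(sprintf("%s=%d", nms[truncated > 0],
                          truncated[truncated > 0]), collapse = ", "))
  }
  attr(draws, "truncated") <- truncated
  draws
}

# Quantile of a parameter distribution (respecting truncation bounds).
param_quantile <- function(pd, p) {
  if (pd$sd == 0) return(pd$mean)
  q <- if (pd$family == "normal") {
    stats::qnorm(p, pd$mean, pd$sd)
  } else {
    gm <- gamma_moments(pd$mean, pd$sd)
    stats::qgamma(p, shape = gm$shape, scale = gm$scale)
  }
  if (!is.null(pd$lower)) q <- max(q, pd$lower)
  if (!is.null(pd$upper)) q <- min(q, pd$upper)
  q
}

#' PSA configuration
#'
#' @param n_draws Number of Monte Carlo draws (default 2000).
#' @param seed Integer seed.
#' @param interval Central interval mass for the uncertainty intervals.
#' @return List of class `psa_config`.
#' @export
psa_config <- function(n_draws = 2000, seed = 1, interval = 0.95) {
  if (n_draws < 1) stop("n_draws must be >= 1")
  structure(list(n_draws = n_draws, seed = seed, interval = interval),
            class = "psa_config")
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_draws` parameter sets from the registry, evaluates the model
#' closure for each, and summarises every output by its mean and central
#' percentile interval (order statistics of the sorted draws: for 2000
#' draws and a 95\% interval, the 50th and 1950th). Failing draws are
#' recorded, excluded from the summaries and counted, keeping the number of
#' draws fixed.
#'
#' @param closure Function mapping a named parameter vector to a named
#'   numeric output vector (e.g. QALYs and net cost).
#' @param registry List of [param_distribution()] objects.
#' @param config A [psa_config()].
#' @return List of class `psa_result`: `summary` data frame (output, mean,
#'   lower, upper), `draws` (per-draw outputs for CE-plane plotting),
#'   `parameters` (the sampled sets) and `n_failed`.
#' @export
run_psa <- function(closure, registry, config = psa_config()) {
  n <- config$n_draws
  params <- draw_parameters(registry, n, config$seed)
  out <- NULL
  failed <- logical(n)
  for (i in seq_len(n)) {
    res <- tryCatch(closure(params[i, ]), error = function(e) NULL)
    if (is.null(res)) {
      failed[i] <- TRUE
      next
    }
    if (is.null(out)) {
      out <- matrix(NA_real_, n, length(res),
                    dimnames = list(NULL, names(res)))
    }
    out[i, ] <- res
  }
  if (is.null(out)) stop("every PSA draw failed")
  ok <- which(!failed)
  alpha <- (1 - config$interval) / 2
  summ <- do.call(rbind, lapply(colnames(out), function(nm) {
    x <- sort(out[ok, nm])
    m <- length(x)
    # guard the order-statistic indices against floating-point fuzz
    # (0.025 * 2000 must select the 50th, not the 51st, draw)
    lo <- x[max(1, ceiling(alpha * m - 1e-9))]
    hi <- x[min(m, floor((1 - alpha) * m + 1e-9))]
    data.frame(output = nm, mean = mean(x), lower = lo, upper = hi,
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summ, draws = out, parameters = params,
                 n_failed = sum(failed), config = config),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d draws (%d failed), %.0f%% percentile intervals\n",
              x$config$n_draws, x$n_failed, 100 * x$config$interval))
  print(within(x$summary, {
    mean <- signif(mean, 4); lower <- signif(lower, 4)
    upper <- signif(upper, 4)
  }), row.names = FALSE)
  invisible(x)
}

#' One-way tornado analysis
#'
#' Evaluates the model closure with each parameter in turn set to its 2.5th
#' and 97.5th percentile while all others stay at their means, and ranks
#' parameters by the absolute output range induced.
#'
#' @param closure Function mapping a named parameter vector to a named
#'   numeric output vector.
#' @param registry List of [param_distribution()] objects.
#' @param output Name or index of the closure output to rank on.
#' @param probs The two percentile points.
#' @return Data frame of class `tornado_result` (parameter, parameter values
#'   and outputs at both percentiles, absolute range), sorted by descending
#'   range; the `"base"` attribute holds the all-means output.
#' @export
tornado <- function(closure, registry, output = 1,
                    probs = c(0.025, 0.975)) {
  if (length(registry) == 0) stop("registry must contain parameters")
  means <- vapply(registry, function(p) p$mean, numeric(1))
  names(means) <- vapply(registry, function(p) p$name, character(1))
  base <- closure(means)[output]
  rows <- lapply(registry, function(pd) {
    lo <- param_quantile(pd, probs[1])
    hi <- param_quantile(pd, probs[2])
    p_lo <- means; p_lo[pd$name] <- lo
    p_hi <- means; p_hi[pd$name] <- hi
    v_lo <- closure(p_lo)[output]
    v_hi <- closure(p_hi)[output]
    data.frame(parameter = pd$name, param_low = lo, param_high = hi,
               value_low = unname(v_lo), value_high = unname(v_hi),
               range = abs(unname(v_hi) - unname(v_lo)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$range), ]
  rownames(out) <- NULL
  attr(out, "base") <- unname(base)
  class(out) <- c("tornado_result", "data.frame")
  out
}

#' @export
plot.tornado_result <- function(x, ...) {
  base <- attr(x, "base")
  k <- nrow(x)
  graphics::barplot(
    rbind(x$value_low - base, x$value_high - base)[, k:1],
    horiz = TRUE, beside = FALSE, names.arg = rev(x$parameter),
    las = 1, xlab = "Output change from base", ...
  )
  graphics::abline(v = 0)
  invisible(x)
}

#' Default sensitivity-parameter registry for an intervention
#'
#' One entry per uncertain input: the intervention's sodium effect size
#' (normal, truncated at zero; counselling contributes its per-hour effect
#' and annual-hours parameters instead), its direct cost (gamma or normal as
#' specified), multiplicative perturbations of the CHD and stroke hazard
#' ratios (normal, SD 10\%), the disability weights and the disease/healthy
#' cost tables (gamma, SD 10\%).
#'
#' @param spec An `intervention_spec`.
#' @param profile A [sodium_profile()].
#' @param total_adults Adult population count.
#' @param hr_sd_rel Relative SD on the hazard-ratio scales.
#' @param dw_sd_rel Relative SD on the disability weights.
#' @param cost_sd_rel Relative SD on the health-system cost scales.
#' @return List of [param_distribution()] objects.
#' @export
default_param_registry <- function(spec, profile = sodium_profile(),
                                   total_adults = 2300000,
                                   hr_sd_rel = 0.10, dw_sd_rel = 0.10,
                                   cost_sd_rel = 0.10) {
  reg <- list()
  if (spec$kind == "counselling") {
    reg <- c(reg, list(
      param_distribution("per_hour_effect", "normal", spec$per_hour_effect,
                         spec$per_hour_sd, lower = 0),
      param_distribution("annual_hours", "gamma", spec$hours_mean,
                         spec$hours_sd, lower = 0)
    ))
  } else {
    full <- spec_full_effect(spec, profile, total_adults)
    reg <- c(reg, list(
      param_distribution("effect", "normal", full,
                         spec_effect_sd(spec, profile, total_adults),
                         lower = 0)
    ))
  }
  cost_point <- if (spec$cost_onetime > 0) spec$cost_onetime else spec$cost_annual
  if (cost_point > 0) {
    reg <- c(reg, list(
      param_distribution("direct_cost", spec$cost_distribution, cost_point,
                         spec$cost_sd, lower = 0)
    ))
  }
  c(reg, list(
    param_distribution("hr_chd", "normal", 1, hr_sd_rel, lower = 0.01),
    param_distribution("hr_stroke", "normal", 1, hr_sd_rel, lower = 0.01),
    param_distribution("dw_chd", "normal", 0.081, dw_sd_rel * 0.081,
                       lower = 0, upper = 1),
    param_distribution("dw_stroke", "normal", 0.226, dw_sd_rel * 0.226,
                       lower = 0, upper = 1),
    param_distribution("cost_disease", "gamma", 1, cost_sd_rel, lower = 0),
    param_distribution("cost_healthy", "gamma", 1, cost_sd_rel, lower = 0)
  ))
}

#' Build a CEA model closure for sensitivity analyses
#'
#' Returns a function mapping a named parameter vector (as produced from
#' [default_param_registry()]) to incremental QALYs and net cost for one
#' intervention versus the "do nothing" comparator. The comparator is
#' re-simulated per call so that draws of shared parameters (hazard ratios,
#' disability weights, cost tables) propagate consistently to both worlds.
#'
#' @param bundle A `baseline_bundle` of observed rates.
#' @param spec The `intervention_spec` under analysis.
#' @param profile,bp_table,hr_table,trend,econ Model settings.
#' @param current_practice Specs removed to form the comparator.
#' @return Function `params -> c(qalys, net_cost)`.
#' @export
cea_closure <- function(bundle, spec,
                        profile = sodium_profile(),
                        bp_table = bp_coefficients(),
                        hr_table = hazard_ratio_table(),
                        trend = trend_spec(), econ = economic_spec(),
                        current_practice = intervention_registry()[
                          c("counselling", "endorsement_label")]) {
  do_nothing <- backcalculate_do_nothing(bundle, current_practice, profile,
                                         bp_table, hr_table)
  inp <- prepare_cohort_inputs(do_nothing, trend, econ, bp_table, hr_table)
  total_adults <- bundle$total_adults
  full_default <- spec_full_effect(spec, profile, total_adults)
  cost_point <- if (spec$cost_onetime > 0) spec$cost_onetime else spec$cost_annual

  function(params) {
    p <- function(nm, default) {
      if (nm %in% names(params)) unname(params[[nm]]) else default
    }
    effect <- if (spec$kind == "counselling") {
      p("per_hour_effect", spec$per_hour_effect) *
        p("annual_hours", spec$hours_mean) / total_adults
    } else {
      p("effect", full_default)
    }
    effect_scale <- if (full_default > 0) effect / full_default else 1
    cost_scale_stream <- if (cost_point > 0) {
      p("direct_cost", cost_point) / cost_point
    } else {
      1
    }
    hr_scale <- c(chd = p("hr_chd", 1), stroke = p("hr_stroke", 1))
    dw <- c(chd = p("dw_chd", 0.081), stroke = p("dw_stroke", 0.226))
    cost_scale <- c(disease = p("cost_disease", 1),
                    healthy = p("cost_healthy", 1))

    comparator <- run_prepared(inp, NULL, dw = dw, hr_scale = hr_scale,
                               cost_scale = cost_scale)
    sched <- build_schedule(spec, profile, horizon = inp$n_cycles,
                            total_adults = total_adults,
                            effect_scale = effect_scale)
    dc <- c(spec$cost_onetime * cost_scale_stream, numeric(inp$n_cycles))
    traj <- run_prepared(inp, sched, dw = dw, direct_cost = dc,
                         annual_cost_alive = spec$cost_annual * cost_scale_stream,
                         hr_scale = hr_scale, cost_scale = cost_scale)
    c(qalys = traj$totals$qalys - comparator$totals$qalys,
      net_cost = traj$totals$cost_intervention +
        (traj$totals$cost_cvd - comparator$totals$cost_cvd) +
        (traj$totals$cost_non_cvd - comparator$totals$cost_non_cvd))
  }
}

#' Named scenario analyses
#'
#' Reruns the full analysis under structural scenarios: discount rates of 0\%
#' and 6\%; a 20-year sunset clause on the mandatory reformulation laws (the
#' sodium effect reverts to zero afterwards); all direct intervention costs
#' 50\% greater; the media campaign carrying 15\% or 45\% of the package
#' effect; the alternative (flat) sodium-BP meta-analysis table; reduced
#' background case-fatality rates (multiplier 0.9, reflecting possible
#' upward bias from the limited administrative look-back window); an
#' alternative price elasticity for the salt tax (affects the implied tax
#' path, not the capped demand schedule); and Australian-style legislation
#' plus enforcement costs (an extra half of AUS$0.49 per person per year on
#' law-based interventions).
#'
#' @param bundle A `baseline_bundle`.
#' @param scenarios Character vector of scenario names (see Details);
#'   `"baseline"` is always available.
#' @param interventions Named list of `intervention_spec`s.
#' @param ... Passed on to [salt_cea()].
#' @return List of class `scenario_results`: one `results` data frame per
#'   scenario (with a `scenario` column).
#' @export
run_scenarios <- function(bundle,
                          scenarios = c("discount_0", "discount_6"),
                          interventions = intervention_registry(), ...) {
  known <- c("baseline", "discount_0", "discount_6", "sunset_20y",
             "costs_plus_50pct", "media_share_15", "media_share_45",
             "he_macgregor_bp", "cfr_reduced", "pe_variants",
             "enforcement_costs_aus")
  bad <- setdiff(scenarios, known)
  if (length(bad)) stop("unknown scenario: ", paste(bad, collapse = ", "))
  out <- lapply(scenarios, function(sc) {
    specs <- interventions
    args <- list(bundle = bundle, interventions = specs,
                 keep_trajectories = FALSE, ...)
    if (sc == "discount_0") args$econ <- economic_spec(0)
    if (sc == "discount_6") args$econ <- economic_spec(0.06)
    if (sc == "costs_plus_50pct") args$cost_stream_scale <- 1.5
    if (sc == "he_macgregor_bp") args$bp_table <- bp_coefficients("he_macgregor")
    if (sc == "cfr_reduced") args$cf_multiplier <- 0.9
    if (sc == "enforcement_costs_aus") {
      args$extra_annual_cost <- 0.245 * bundle$total_adults
    }
    if (sc == "sunset_20y") {
      for (nm in intersect(c("mandatory_3g", "mandatory_all"), names(specs))) {
        specs[[nm]]$sunset_year <- 20
      }
      args$interventions <- specs
    }
    if (sc %in% c("media_share_15", "media_share_45") &&
        "uk_media" %in% names(specs)) {
      specs$uk_media$campaign_share <- if (sc == "media_share_15") 0.15 else 0.45
      args$interventions <- specs
    }
    if (sc == "pe_variants" && "salt_tax" %in% names(specs)) {
      specs$salt_tax$elasticity <- -0.2
      args$interventions <- specs
    }
    fit <- do.call(salt_cea, args)
    cbind(scenario = sc, fit$results)
  })
  names(out) <- scenarios
  structure(out, class = "scenario_results")
}

#' @export
print.scenario_results <- function(x, ...) {
  for (sc in names(x)) {
    cat("Scenario:", sc, "\n")
    df <- x[[sc]]
    print(data.frame(intervention = df$intervention,
                     QALYs = signif(df$inc_qalys, 3),
                     net_cost_MNZD = signif(df$net_cost / 1e6, 3)),
          row.names = FALSE)
    cat("\n")
  }
  invisible(x)
}
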