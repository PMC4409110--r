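# Reporting pipeline -----------------------------------------------------------

#' Pipeline run configuration
#'
#' Bundles every setting of a full analysis run so that a run is
#' reproducible from its configuration and seed alone. Round-trips
#' losslessly through JSON ([write_run_config()] / [read_run_config()]).
#'
#' @param seed Integer seed for the synthetic baseline (and PSA, unless
#'   `psa_seed` differs).
#' @param baseline_dir Optional directory of baseline CSV files (from
#'   [write_baseline()]); when `NULL` the synthetic generator is used.
#' @param interventions Character vector of intervention names, or `"all"`.
#' @param discount_rate Annual discount rate.
#' @param trend_end_year Last year of the secular trends.
#' @param bp_source `"law"` or `"he_macgregor"`.
#' @param psa_n PSA draws per intervention (0 disables the PSA outputs'
#'   uncertainty intervals; the file of draws is still written, empty).
#' @param psa_seed Seed for the PSA draws.
#' @param out_dir Output directory for all artifact files.
#' @param verbose Log progress to stderr.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, baseline_dir = NULL, interventions = "all",
                       discount_rate = 0.03, trend_end_year = 2026,
                       bp_source = "law", psa_n = 0, psa_seed = seed,
                       out_dir = tempfile("saltshift_run_"),
                       verbose = FALSE) {
  if (!is.null(baseline_dir) && !dir.exists(baseline_dir)) {
    stop("baseline_dir does not exist: ", baseline_dir)
  }
  structure(list(seed = as.integer(seed), baseline_dir = baseline_dir,
                 interventions = interventions,
                 discount_rate = discount_rate,
                 trend_end_year = trend_end_year, bp_source = bp_source,
                 psa_n = as.integer(psa_n), psa_seed = as.integer(psa_seed),
                 out_dir = out_dir, verbose = isTRUE(verbose)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$interventions <- as.character(raw$interventions)
  do.call(run_config, raw)
}

fmt_csv_num <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.10g", df[[j]])
  }
  df
}

#' Run the full analysis pipeline and write all artifact files
#'
#' Generates (or reads) the baseline, fits the generalised CEA, and writes
#' to `config$out_dir`: `table4.csv` (incremental QALYs, net cost and ICER
#' per intervention, with 95\% uncertainty intervals when a PSA is run),
#' `table5.csv` (per-adult cost decomposition), `table6.csv` (ethnic
#' inequality report), `ce_plane.csv` (deterministic cost-effectiveness
#' plane coordinates), `psa_draws.csv` (per-draw QALY/net-cost pairs) and
#' `run.log` (seed and configuration echo). Reruns with the same
#' configuration produce byte-identical CSVs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the fitted `salt_cea` object and the paths
#'   of all written files.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- c(
    sprintf("saltshift pipeline, seed %d", config$seed),
    sprintf("config: %s",
            jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA))
  )
  say <- function(msg) {
    if (config$verbose) message(msg)
    log_lines <<- c(log_lines, msg)
  }

  bundle <- if (is.null(config$baseline_dir)) {
    say("generating synthetic baseline")
    generate_baseline(config$seed)
  } else {
    say(paste("reading baseline from", config$baseline_dir))
    read_baseline(config$baseline_dir)
  }

  registry <- intervention_registry()
  selected <- if (identical(config$interventions, "all")) {
    names(registry)
  } else {
    unknown <- setdiff(config$interventions, names(registry))
    if (length(unknown)) stop("unknown intervention: ",
                              paste(unknown, collapse = ", "))
    config$interventions
  }

  bp_table <- bp_coefficients(config$bp_source)
  trend <- trend_spec(trend_end_year = config$trend_end_year)
  econ <- economic_spec(config$discount_rate)
  say(sprintf("fitting CEA for %d interventions", length(selected)))
  fit <- salt_cea(bundle, registry[selected], bp_table = bp_table,
                  trend = trend, econ = econ)

  res <- fit$results
  psa_rows <- list()
  ui <- data.frame(intervention = res$intervention,
                   qalys_lower = NA_real_, qalys_upper = NA_real_,
                   net_cost_lower = NA_real_, net_cost_upper = NA_real_,
                   icer_ratio_of_means = NA_real_,
                   icer_mean_of_ratios = NA_real_)
  if (config$psa_n > 0) {
    for (nm in selected) {
      say(paste("PSA:", nm))
      closure <- cea_closure(bundle, registry[[nm]], bp_table = bp_table,
                             trend = trend, econ = econ)
      psa <- run_psa(closure, default_param_registry(registry[[nm]]),
                     psa_config(config$psa_n, config$psa_seed))
      i <- match(nm, ui$intervention)
      ui$qalys_lower[i] <- psa$summary$lower[psa$summary$output == "qalys"]
      ui$qalys_upper[i] <- psa$summary$upper[psa$summary$output == "qalys"]
      ui$net_cost_lower[i] <- psa$summary$lower[psa$summary$output == "net_cost"]
      ui$net_cost_upper[i] <- psa$summary$upper[psa$summary$output == "net_cost"]
      # both PSA ICER conventions: ratio of expected values and expected ratio
      q <- psa$draws[, "qalys"]; nc <- psa$draws[, "net_cost"]
      keep <- !is.na(q) & q > 0
      ui$icer_ratio_of_means[i] <- mean(nc[keep]) / mean(q[keep])
      ui$icer_mean_of_ratios[i] <- mean(nc[keep] / q[keep])
      psa_rows[[nm]] <- data.frame(intervention = nm,
                                   draw = seq_len(nrow(psa$draws)),
                                   qalys = psa$draws[, "qalys"],
                                   net_cost = psa$draws[, "net_cost"])
    }
  }

  paths <- list()
  wr <- function(df, file) {
    p <- file.path(config$out_dir, file)
    utils::write.csv(fmt_csv_num(df), p, row.names = FALSE, quote = FALSE)
    paths[[file]] <<- p
  }

  table4 <- merge(
    data.frame(intervention = res$intervention, label = res$label,
               inc_qalys = res$inc_qalys, net_cost = res$net_cost,
               icer = res$icer, icer_label = res$icer_label),
    ui, by = "intervention", sort = FALSE
  )
  wr(table4, "table4.csv")
  wr(data.frame(intervention = res$intervention,
                direct = res$per_adult_direct,
                cvd_delta = res$per_adult_cvd,
                non_cvd_delta = res$per_adult_non_cvd,
                net = res$per_adult_net),
     "table5.csv")

  ineq_list <- list(
    cbind(scenario = "do_nothing",
          inequality_report(fit$comparator))
  )
  for (nm in intersect(c("counselling", "mandatory_all"), selected)) {
    ineq_list[[nm]] <- cbind(
      scenario = nm,
      inequality_report(fit$comparator, fit$trajectories[[nm]])
    )
  }
  wr(do.call(rbind, ineq_list), "table6.csv")

  wr(data.frame(intervention = res$intervention,
                inc_qalys = res$inc_qalys, net_cost = res$net_cost),
     "ce_plane.csv")
  psa_df <- if (length(psa_rows)) {
    do.call(rbind, psa_rows)
  } else {
    data.frame(intervention = character(), draw = integer(),
               qalys = double(), net_cost = double())
  }
  wr(psa_df, "psa_draws.csv")

  writeLines(log_lines, log_path)
  paths[["run.log"]] <- log_path
  invisible(list(fit = fit, paths = paths, config = config))
}
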