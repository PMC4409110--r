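# Sodium -> blood pressure -> disease risk pathway -----------------------------

#' Systolic BP response to sodium per age group
#'
#' Meta-analysis coefficients for the change in systolic blood pressure
#' (mm Hg) per 100 mmol/day change in sodium intake, by age decade:
#' 30-39: 5.5, 40-49: 6.6, 50-59: 9.2, 60-69: 10.3. Ages 70+ hold the 60-69
#' value by default (a conservative choice; set `extrapolation = "linear"`
#' to continue the 50s-to-60s slope). The `"he_macgregor"` source is an
#' alternative meta-analysis represented as a flat, age-invariant
#' coefficient, used in scenario analyses.
#'
#' @param source `"law"` (default, age-specific) or `"he_macgregor"`.
#' @param extrapolation `"hold"` or `"linear"` for ages 70 and over.
#' @param flat_value Coefficient used for the flat alternative table.
#' @return A list of class `bp_table`.
#' @export
bp_coefficients <- function(source = c("law", "he_macgregor"),
                            extrapolation = c("hold", "linear"),
                            flat_value = 5.8) {
  source <- match.arg(source)
  extrapolation <- match.arg(extrapolation)
  if (source == "he_macgregor") {
    values <- rep(flat_value, 8)
  } else {
    base <- c(5.5, 6.6, 9.2, 10.3)
    ext <- if (extrapolation == "hold") {
      rep(10.3, 4)
    } else {
      10.3 + (10.3 - 9.2) * seq_len(4)
    }
    values <- c(base, ext)
  }
  structure(list(source = source, decades = seq(30, 100, by = 10),
                 values = values),
            class = "bp_table")
}

#' Systolic BP reduction from a sodium reduction
#'
#' Linear in the sodium change: coefficient(age) x delta / 100.
#'
#' @param delta_sodium Sodium reduction (mmol/day), non-negative.
#' @param age Age in years (>= 30).
#' @param table A [bp_coefficients()] table.
#' @return Systolic BP reduction (mm Hg).
#' @export
#' @examples
#' sodium_to_sbp(100, 55)  # 9.2
sodium_to_sbp <- function(delta_sodium, age, table = bp_coefficients()) {
  if (any(delta_sodium < 0)) stop("sodium reduction must be non-negative")
  if (any(age < 30)) stop("BP coefficients are undefined below age 30")
  decade <- pmin(10 * (age %/% 10), max(table$decades))
  coef <- table$values[match(decade, table$decades)]
  coef * delta_sodium / 100
}

#' Age-specific hazard ratios for a 20 mm Hg systolic BP reduction
#'
#' The published point estimates range from 0.49 to 0.67 for CHD and from
#' 0.38 to 0.67 for stroke, strongest at young ages and attenuating with
#' age. The default table assigns the strongest value to ages 35-44 and the
#' weakest to 85+, log-linearly interpolated across the intermediate decades
#' (the exact per-age values behind the printed ranges are not public, so
#' the table is fully overridable). Sampling SD is 10\% of each point
#' estimate.
#'
#' @param chd_range,stroke_range Strongest and weakest hazard ratio per
#'   disease.
#' @param sd_rel Relative SD attached to every entry.
#' @return A list of class `hr_table` with per-decade hazard ratios
#'   (decades 35, 45, ..., 85) for `chd` and `stroke`.
#' @export
hazard_ratio_table <- function(chd_range = c(0.49, 0.67),
                               stroke_range = c(0.38, 0.67),
                               sd_rel = 0.10) {
  if (any(c(chd_range, stroke_range) <= 0) ||
      any(c(chd_range, stroke_range) > 1)) {
    stop("hazard ratios must lie in (0, 1]")
  }
  decades <- seq(35, 85, by = 10)
  interp <- function(range) {
    exp(seq(log(range[1]), log(range[2]), length.out = length(decades)))
  }
  structure(list(decades = decades,
                 chd = interp(chd_range), stroke = interp(stroke_range),
                 sd_rel = sd_rel),
            class = "hr_table")
}

# Hazard ratio at an exact age (decade lookup, clamped to the table range),
# with an optional multiplicative scale clamped so the ratio stays <= 1.
hr_at <- function(table, disease, age, scale = 1) {
  decade <- pmin(pmax(35 + 10 * ((age - 35) %/% 10), 35), 85)
  hr <- table[[disease]][match(decade, table$decades)]
  pmin(hr * scale, 1)
}

#' Scale a 20 mm Hg hazard ratio to an arbitrary BP reduction
#'
#' Continuous, multiplicative rescaling: hr20^(delta_sbp / 20), so that
#' successive BP reductions compose multiplicatively.
#'
#' @param hr20 Hazard ratio for a 20 mm Hg systolic BP reduction, in (0, 1].
#' @param delta_sbp Systolic BP reduction (mm Hg), non-negative.
#' @return Incidence rate multiplier.
#' @export
#' @examples
#' scale_hazard_ratio(0.49, 20)  # 0.49
#' scale_hazard_ratio(0.49, 0)   # 1
scale_hazard_ratio <- function(hr20, delta_sbp) {
  if (any(hr20 <= 0)) stop("hazard ratio must be positive")
  if (any(hr20 > 1)) stop("hazard ratio must be <= 1 (a risk reduction)")
  if (any(delta_sbp < 0)) stop("BP reduction must be non-negative")
  hr20^(delta_sbp / 20)
}

#' Apply or remove an incidence-rate multiplier
#'
#' `direction = "apply"` multiplies the rate (an intervention lowering
#' incidence); `direction = "remove"` divides by the multiplier, supporting
#' the back-calculation of "do nothing" rates from rates observed under
#' current practice. Removed rates are clamped at 1 with a warning.
#'
#' @param baseline_rate Rate(s) in \[0, 1\].
#' @param multiplier Rate multiplier(s) in (0, 1].
#' @param direction `"apply"` or `"remove"`.
#' @return Shifted rate(s).
#' @export
shift_incidence <- function(baseline_rate, multiplier,
                            direction = c("apply", "remove")) {
  direction <- match.arg(direction)
  if (any(multiplier <= 0) || any(multiplier > 1)) {
    stop("multiplier must lie in (0, 1]")
  }
  if (any(baseline_rate < 0) || any(baseline_rate > 1)) {
    stop("rates must lie in [0, 1]")
  }
  if (direction == "apply") {
    baseline_rate * multiplier
  } else {
    out <- baseline_rate / multiplier
    if (any(out > 1)) {
      warning("removed rate exceeded 1 and was clamped")
      out <- pmin(out, 1)
    }
    out
  }
}

#' Incidence multiplier implied by a sodium reduction
#'
#' Composes the full pathway: sodium reduction -> systolic BP reduction
#' (age-specific coefficient) -> hazard-ratio rescaling for the disease.
#'
#' @param delta_sodium Sodium reduction (mmol/day).
#' @param age Age in years.
#' @param disease `"chd"` or `"stroke"`.
#' @param bp_table A [bp_coefficients()] table.
#' @param hr_table A [hazard_ratio_table()].
#' @param hr_scale Multiplicative perturbation of the hazard ratios.
#' @return Multiplier(s) in (0, 1].
#' @export
incidence_multiplier <- function(delta_sodium, age, disease,
                                 bp_table = bp_coefficients(),
                                 hr_table = hazard_ratio_table(),
                                 hr_scale = 1) {
  disease <- match.arg(disease, c("chd", "stroke"))
  dsbp <- sodium_to_sbp(delta_sodium, age, bp_table)
  hr <- hr_at(hr_table, disease, age, hr_scale)
  scale_hazard_ratio(hr, dsbp)
}
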