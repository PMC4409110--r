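#' @keywords internal
"_PACKAGE"

# Five-year age bands covering the modelled adult population (95 = "95+").
AGE_BANDS <- seq(35, 95, by = 5)
SEXES <- c("male", "female")
ETHNICITIES <- c("non_maori", "maori")

#' Enumerate the 52 population strata
#'
#' The model is stratified by sex, 5-year age band (35-39, ..., 95+) and
#' ethnicity (Maori / non-Maori): 2 x 13 x 2 = 52 strata. All baseline rate,
#' cost and population tables carry one row per stratum in this canonical
#' order.
#'
#' @return A data frame with columns `sex`, `age_band` (band start, years)
#'   and `ethnicity`.
#' @export
#' @examples
#' nrow(stratum_table())  # 52
stratum_table <- function() {
  out <- expand.grid(
    ethnicity = ETHNICITIES,
    age_band = AGE_BANDS,
    sex = SEXES,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  out[, c("sex", "age_band", "ethnicity")]
}

#' Age band containing an exact age
#'
#' @param age Age in years (>= 35).
#' @return Band start(s) in `seq(35, 95, 5)`; ages of 95 and over map to 95.
#' @export
age_band_of <- function(age) {
  if (any(age < 35)) stop("ages below 35 are outside the modelled cohort")
  pmin(35 + 5 * ((age - 35) %/% 5), 95)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Format numbers for delimited output at full double precision so a
# write/read round trip is exact.
num_chr <- function(x) sprintf("%.17g", x)

# Integer rounding that preserves the vector total (largest remainder).
round_preserve_sum <- function(x, total = round(sum(x))) {
  fl <- floor(x)
  deficit <- total - sum(fl)
  if (deficit > 0) {
    idx <- order(x - fl, decreasing = TRUE)[seq_len(deficit)]
    fl[idx] <- fl[idx] + 1
  }
  fl
}

match_arg1 <- function(arg, choices) {
  match.arg(arg, choices)
}
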