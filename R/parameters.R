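# Model parameters: grade definitions, mortality/cost/utility lookups, the
# log-normal eGFR-decline law, and config loading.

#' CKD health states
#'
#' The ordered severity scale used throughout the package: the six KDIGO
#' eGFR grades, the dialysis-dependent end-stage state (ESRD), and death.
#'
#' @return Character vector of state labels, ordered from least to most
#'   severe.
#' @export
#' @examples
#' ckd_states()
ckd_states <- function() {
  c("G1", "G2", "G3a", "G3b", "G4", "G5", "ESRD", "DEAD")
}

# eGFR band breakpoints, least severe last. Grade bands are closed at the
# lower bound (45 -> G3a); the dialysis threshold is reached inclusively:
# once eGFR has fallen *to* the threshold, renal replacement therapy starts.
.grade_breaks <- function(esrd_threshold) {
  c(esrd_threshold, 15, 30, 45, 60, 90)
}

# Integer state codes 1..7 (G1..G5, ESRD) from eGFR.
.grade_code <- function(egfr, esrd_threshold) {
  code <- 7L - findInterval(egfr, .grade_breaks(esrd_threshold))
  code[egfr <= esrd_threshold] <- 7L
  code
}

#' Map eGFR values to CKD grades
#'
#' Classifies estimated glomerular filtration rate (mL/min/1.73 m\eqn{^2})
#' into the KDIGO grades G1--G5, with ESRD (dialysis dependence) below the
#' renal replacement threshold. Grade bands are inclusive at their lower
#' bound (eGFR 45 is G3a); an eGFR at or below the ESRD threshold counts as
#' ESRD, so that a patient whose function falls exactly to the threshold at
#' the end of a cycle starts dialysis in that cycle.
#'
#' @param egfr Numeric vector of eGFR values (must be non-negative).
#' @param params A [ckd_parameters()] object; only the `esrd_threshold`
#'   element (default 7) is used.
#' @return An ordered factor with levels `G1 < G2 < ... < G5 < ESRD`.
#' @export
#' @examples
#' grade_from_egfr(c(76, 45, 44.9, 6.9, 0))
grade_from_egfr <- function(egfr, params = ckd_parameters()) {
  if (!is.numeric(egfr) || anyNA(egfr)) {
    abort("`egfr` must be numeric with no missing values")
  }
  if (any(egfr < 0)) {
    abort("`egfr` must be non-negative")
  }
  codes <- .grade_code(egfr, params$esrd_threshold)
  factor(ckd_states()[codes], levels = ckd_states()[1:7], ordered = TRUE)
}

#' Log-normal parameters from the mean and SD of the decline magnitude
#'
#' The per-patient annual eGFR decline slope is modelled as log-normal
#' (all slopes strictly positive: no patient has continuously improving
#' kidney function). This converts the published mean/SD of the decline
#' speed into the log-scale location and scale by moment matching:
#' \deqn{\sigma^2 = \log(1 + (sd/mean)^2), \quad
#'       \mu = \log(mean) - \sigma^2 / 2.}
#'
#' @param mean Mean decline speed, mL/min/1.73 m\eqn{^2}/year (> 0).
#' @param sd Standard deviation of the decline speed, same units (> 0).
#' @return Named list with elements `meanlog` and `sdlog`, usable directly
#'   with [stats::rlnorm()].
#' @export
#' @examples
#' lognormal_params(2.2, 6.5)
lognormal_params <- function(mean, sd) {
  .assert_number(mean, "mean")
  .assert_number(sd, "sd")
  if (mean <= 0 || sd <= 0) {
    abort("`mean` and `sd` must both be positive")
  }
  s2 <- log1p((sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Annual mortality hazard by age, sex and health state
#'
#' Predialysis mortality is a sex-specific Gompertz-type baseline
#' \eqn{a e^{b \cdot age}} multiplied by a grade-specific hazard ratio.
#' Dialysis (ESRD) mortality uses its own coefficients with no sex term and
#' no grade multiplier.
#'
#' @param age Age in years (vectorised).
#' @param sex `"male"` or `"female"` (vectorised, recycled).
#' @param state Health state label (see [ckd_states()]); `"DEAD"` is an
#'   error.
#' @param params A [ckd_parameters()] object.
#' @return Annual hazard (events per person-year), same length as the
#'   longest input.
#' @export
#' @examples
#' annual_mortality_rate(37, "male", "G2")
#' annual_mortality_rate(70, "female", "ESRD")
annual_mortality_rate <- function(age, sex, state, params = ckd_parameters()) {
  state <- as.character(state)
  sex <- as.character(sex)
  if (!is.numeric(age) || any(is.na(age)) || any(age < 0)) {
    abort("`age` must be non-negative")
  }
  if (!all(sex %in% c("male", "female"))) {
    abort("`sex` must be \"male\" or \"female\"")
  }
  if (any(state == "DEAD")) {
    abort("mortality is undefined for the DEAD state")
  }
  if (!all(state %in% ckd_states()[1:7])) {
    abort("unknown health state in `state`")
  }
  df <- data.frame(age = age, sex = sex, state = state)  # recycles
  mult <- setNames(.grade_multipliers(params), ckd_states()[1:6])
  base <- ifelse(df$sex == "male",
                 params$mort_male_a * exp(params$mort_male_b * df$age),
                 params$mort_female_a * exp(params$mort_female_b * df$age))
  out <- base * unname(mult[df$state])
  dial <- df$state == "ESRD"
  out[dial] <- params$mort_dialysis_a *
    exp(params$mort_dialysis_b * df$age[dial])
  out
}

#' Convert an annual hazard to a per-cycle transition probability
#'
#' Exponential-hazard conversion \eqn{p = 1 - e^{-r \cdot c}} for a hazard
#' `rate` (per year) over a cycle of length `cycle` years. Satisfies hazard
#' additivity: the survival over two consecutive cycles equals survival over
#' their union.
#'
#' @param rate Annual hazard, non-negative (vectorised).
#' @param cycle Cycle length in years (> 0).
#' @return Probability in \[0, 1).
#' @export
#' @examples
#' rate_to_cycle_prob(9.678e-4, 0.25)
rate_to_cycle_prob <- function(rate, cycle = 0.25) {
  if (!is.numeric(rate) || any(is.na(rate)) || any(rate < 0)) {
    abort("`rate` must be non-negative")
  }
  .assert_number(cycle, "cycle")
  if (cycle <= 0) abort("`cycle` must be positive")
  -expm1(-rate * cycle)
}

.default_parameters <- function() {
  list(
    # cohort and run controls
    initial_age = 37,
    initial_egfr = 73,
    male_fraction = 0.5,
    cycle_length = 0.25,
    max_age = 110,
    cohort_size = 1e5,
    seed = 1L,
    # kidney-function model
    esrd_threshold = 7,
    decline_mean = 2.2,
    decline_sd = 6.5,
    decline_mean_treated = 1.3,
    decline_sd_treated = 8.5,
    improve_rate = 0.59,
    # mortality: hazard = a * exp(b * age), annual scale
    mort_male_a = 3.338e-5,
    mort_male_b = 0.091,
    mort_female_a = 1.615e-5,
    mort_female_b = 0.098,
    mort_dialysis_a = 1.32e-3,
    mort_dialysis_b = 0.060,
    hr_g1 = 1, hr_g2 = 1, hr_g3a = 1.2, hr_g3b = 1.8, hr_g4 = 3.2,
    hr_g5 = 5.9,
    # annual utility weights
    utility_g1 = 1, utility_g2 = 0.9, utility_g3a = 0.87,
    utility_g3b = 0.85, utility_g4 = 0.85, utility_g5 = 0.85,
    utility_dialysis = 0.72,
    # annual costs, 1000 USD
    cost_g1 = 1.6, cost_g2 = 1.7, cost_g3a = 3.5, cost_g3b = 3.5,
    cost_g4 = 12.7, cost_g5 = 12.7, cost_dialysis = 84.6,
    # economics
    discount_cost = 0.03,
    discount_utility = 0.03,
    wtp = 50
  )
}

.validate_parameters <- function(p) {
  num_in <- function(key, lower, upper) {
    v <- p[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) ||
        v < lower || v > upper) {
      abort(sprintf("parameter `%s` must be a number in [%s, %s]",
                    key, lower, upper))
    }
  }
  for (k in grep("^utility_", names(p), value = TRUE)) num_in(k, 0, 1)
  for (k in grep("^cost_", names(p), value = TRUE)) num_in(k, 0, Inf)
  for (k in grep("^mort_", names(p), value = TRUE)) num_in(k, 0, Inf)
  for (k in grep("^hr_", names(p), value = TRUE)) num_in(k, 0, Inf)
  # monotone over the occupiable grades; the published uncertainty ranges
  # allow hr_g2 below the (never-occupied) G1 baseline of 1
  hr <- .grade_multipliers(p)[2:6]
  if (is.unsorted(hr)) {
    abort("grade mortality multipliers `hr_g2`..`hr_g5` must be non-decreasing")
  }
  num_in("discount_cost", 0, 1 - 1e-12)
  num_in("discount_utility", 0, 1 - 1e-12)
  num_in("decline_mean", 1e-12, Inf)
  num_in("decline_sd", 1e-12, Inf)
  num_in("decline_mean_treated", 1e-12, Inf)
  num_in("decline_sd_treated", 1e-12, Inf)
  num_in("improve_rate", 1e-12, 1)
  num_in("esrd_threshold", 1e-12, 15 - 1e-12)
  num_in("initial_age", 0, Inf)
  num_in("max_age", 0, Inf)
  num_in("cycle_length", 1e-12, Inf)
  num_in("cohort_size", 1, Inf)
  num_in("male_fraction", 0, 1)
  num_in("wtp", 0, Inf)
  num_in("seed", -2^31, 2^31)
  if (p$max_age <= p$initial_age) {
    abort("parameter `max_age` must exceed `initial_age`")
  }
  if (p$initial_egfr <= p$esrd_threshold) {
    abort("parameter `initial_egfr` must be above `esrd_threshold` (patients start predialysis)")
  }
  invisible(p)
}

.apply_overrides <- function(p, overrides) {
  if (length(overrides) == 0L) return(p)
  if (is.null(names(overrides)) || any(names(overrides) == "")) {
    abort("parameter overrides must be named")
  }
  unknown <- setdiff(names(overrides), names(p))
  if (length(unknown)) {
    abort(sprintf("unknown parameter(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  modifyList(p, lapply(overrides, function(v) {
    if (is.integer(v)) as.double(v) else v
  }))
}

#' Base-case model parameters
#'
#' Builds the full parameter set for both microsimulation models: the
#' log-normal eGFR decline law for the control arm (mean 2.2, SD 6.5
#' mL/min/1.73 m\eqn{^2}/year) and the treated arm (1.3, 8.5), age- and
#' sex-specific Gompertz mortality with grade multipliers, annual utility
#' weights and costs per state, 3\% annual discounting, a
#' 50,000 USD/QALY willingness-to-pay threshold, and the run controls
#' (initial age 37, initial eGFR 73, equal sex mix, quarterly cycles,
#' 110-year age cap).
#'
#' @param ... Named overrides of any default, e.g.
#'   `ckd_parameters(initial_egfr = 76)`. Unknown names and out-of-range
#'   values are errors.
#' @return A validated list of class `ckd_params`.
#' @seealso [load_parameters()] to read overrides from a YAML config file;
#'   [sa_parameter_ranges()] for the sensitivity-analysis ranges.
#' @export
#' @examples
#' p <- ckd_parameters()
#' p$decline_mean
#' ckd_parameters(cohort_size = 1000)$cohort_size
ckd_parameters <- function(...) {
  p <- .apply_overrides(.default_parameters(), list(...))
  .validate_parameters(p)
  structure(p, class = "ckd_params")
}

#' Load model parameters, optionally from a config file
#'
#' With no arguments this returns the base case (see [ckd_parameters()]).
#' A config file is a flat YAML document whose keys are parameter names;
#' named arguments in `...` are applied after the file. Unknown keys and
#' values violating a parameter's range are rejected with an error naming
#' the key.
#'
#' @param path Path to a YAML config file, or `NULL`.
#' @param ... Further named overrides applied after the file.
#' @return A validated `ckd_params` object.
#' @export
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines("initial_egfr: 76", cfg)
#' load_parameters(cfg)$initial_egfr
load_parameters <- function(path = NULL, ...) {
  p <- .default_parameters()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(sprintf("config file not found: %s", path))
    }
    cfg <- yaml::read_yaml(path)
    if (!is.list(cfg)) abort("config file must be a mapping of key: value")
    p <- .apply_overrides(p, cfg)
  }
  p <- .apply_overrides(p, list(...))
  .validate_parameters(p)
  structure(p, class = "ckd_params")
}

#' @export
print.ckd_params <- function(x, ...) {
  cat("<ckd_params>\n")
  cat(sprintf("  cohort: start age %g, eGFR %g, %g%% male, cycle %g yr, cap %g yr\n",
              x$initial_age, x$initial_egfr, 100 * x$male_fraction,
              x$cycle_length, x$max_age))
  cat(sprintf("  decline (mL/min/1.73m2/yr): control %g +/- %g, treated %g +/- %g\n",
              x$decline_mean, x$decline_sd,
              x$decline_mean_treated, x$decline_sd_treated))
  cat(sprintf("  ESRD threshold: eGFR %g; discounting %g%% (costs) / %g%% (utilities); WTP %g k USD/QALY\n",
              x$esrd_threshold, 100 * x$discount_cost,
              100 * x$discount_utility, x$wtp))
  invisible(x)
}

#' @export
as_tibble.ckd_params <- function(x, ...) {
  tibble(parameter = names(x), value = unlist(unname(x)))
}
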