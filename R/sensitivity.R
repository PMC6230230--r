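# One-way and probabilistic sensitivity analyses over the published
# parameter ranges, reporting between-model differences (grade-based minus
# kidney function-based) in life-years, discounted utilities and costs, and
# the V0/V1 threshold statistics.

#' Sensitivity-analysis parameter ranges
#'
#' The published lower/upper limits for every parameter varied in the
#' sensitivity analyses. Mortality formula coefficients are varied through
#' multiplicative modifiers (`kind = "multiplier"`) applied to the baseline
#' coefficient of \eqn{a e^{b \cdot age}}; all other entries replace the
#' named parameter directly. G1-specific utilities, costs and multipliers
#' are not varied because with the base-case initial eGFR below 90 no
#' patient ever occupies G1.
#'
#' @return A tibble with columns `parameter, base, lower, upper, kind`.
#' @export
sa_parameter_ranges <- function() {
  tribble_ <- function(...) {
    m <- matrix(list(...), ncol = 4, byrow = TRUE)
    tibble(parameter = unlist(m[, 1]), base = unlist(m[, 2]),
           lower = unlist(m[, 3]), upper = unlist(m[, 4]))
  }
  out <- tribble_(
    "decline_mean", 2.2, 0.1, 10,
    "decline_sd", 6.5, 0.1, 10,
    "initial_age", 37, 30, 60,
    "initial_egfr", 73, 30, 75,
    "mort_baseline_mult", 1, 0.8, 1.2,
    "hr_g2", 1, 0.9, 1.1,
    "hr_g3a", 1.2, 1.1, 1.3,
    "hr_g3b", 1.8, 1.7, 1.9,
    "hr_g4", 3.2, 3.0, 3.4,
    "hr_g5", 5.9, 5.6, 6.2,
    "mort_dialysis_mult", 1, 0.8, 1.2,
    "utility_g2", 0.9, 0.8, 1,
    "utility_g3a", 0.87, 0.77, 0.97,
    "utility_g3b", 0.85, 0.75, 0.95,
    "utility_g4", 0.85, 0.75, 0.95,
    "utility_g5", 0.85, 0.75, 0.95,
    "utility_dialysis", 0.72, 0.62, 0.82,
    "cost_g2", 1.7, 0.9, 3.4,
    "cost_g3a", 3.5, 1.8, 7.0,
    "cost_g3b", 3.5, 1.8, 7.0,
    "cost_g4", 12.7, 6.4, 25.4,
    "cost_g5", 12.7, 6.4, 25.4,
    "cost_dialysis", 84.6, 42.3, 169.1,
    "improve_rate", 0.59, 0.1, 0.9,
    "discount_cost", 0.03, 0, 0.1,
    "discount_utility", 0.03, 0, 0.1
  )
  out$kind <- ifelse(grepl("_mult$", out$parameter), "multiplier", "value")
  out
}

# Apply a named set of sensitivity values to a parameter set. The treated
# arm's decline distribution is re-derived from the control arm via the
# slope improve rate, holding the base-case SD ratio fixed, so varying the
# control decline or the improve rate moves the intervention coherently.
.apply_sa_values <- function(params, values) {
  p <- unclass(params)
  sd_ratio <- p$decline_sd_treated / p$decline_sd
  for (nm in names(values)) {
    v <- values[[nm]]
    if (nm == "mort_baseline_mult") {
      p$mort_male_a <- p$mort_male_a * v
      p$mort_female_a <- p$mort_female_a * v
    } else if (nm == "mort_dialysis_mult") {
      p$mort_dialysis_a <- p$mort_dialysis_a * v
    } else if (nm %in% names(p)) {
      p[[nm]] <- v
    } else {
      abort(sprintf("unknown sensitivity parameter: %s", nm))
    }
  }
  p$decline_mean_treated <- p$decline_mean * p$improve_rate
  p$decline_sd_treated <- p$decline_sd * sd_ratio
  .validate_parameters(p)
  structure(p, class = "ckd_params")
}

# Scalar summary of one paired comparison: control-arm life-years/QALYs/
# costs per model, V0/V1 per model, and grade-based minus kidney
# function-based differences.
.sa_scalars <- function(cmp) {
  dg <- cmp$dg
  kf <- cmp$kf
  tibble(
    life_years_dg = dg$control$life_years_mean,
    life_years_kf = kf$control$life_years_mean,
    qaly_dg = dg$control$qaly_mean,
    qaly_kf = kf$control$qaly_mean,
    cost_dg = dg$control$cost_mean,
    cost_kf = kf$control$cost_mean,
    v0_dg = dg$v0, v0_kf = kf$v0,
    v1_dg = dg$v1, v1_kf = kf$v1,
    d_life_years = dg$control$life_years_mean - kf$control$life_years_mean,
    d_qaly = dg$control$qaly_mean - kf$control$qaly_mean,
    d_cost = dg$control$cost_mean - kf$control$cost_mean,
    d_v0 = dg$v0 - kf$v0,
    d_v1 = dg$v1 - kf$v1
  )
}

#' One-way sensitivity analysis
#'
#' Varies each ranged parameter independently across evenly spaced grid
#' points between its published lower and upper limit, holding everything
#' else at base, and runs the full paired model comparison at each point.
#' Every evaluation reuses the same seed so that differences across grid
#' points reflect the parameter, not the random stream.
#'
#' @param params Base [ckd_parameters()].
#' @param parameters Character vector of parameters to vary (default: all
#'   of [sa_parameter_ranges()]). Names without a published range are
#'   skipped with a message.
#' @param grid_points Number of evenly spaced values per parameter.
#' @param n Evaluation cohort size per cohort (reduced by default relative
#'   to the base case so a full sweep stays desk-scale).
#' @param seed Seed reused for every evaluation.
#' @param verbose Print progress?
#' @return A tibble with one row per evaluation: `parameter, value`, the
#'   per-model scalars (control-arm life-years, QALYs, costs; V0, V1) and
#'   the between-model differences `d_*` (grade-based minus
#'   kidney function-based; monetary columns in 1000 USD).
#' @export
one_way_sa <- function(params, parameters = NULL, grid_points = 3,
                       n = 2e4, seed = params$seed, verbose = FALSE) {
  stopifnot(inherits(params, "ckd_params"))
  ranges <- sa_parameter_ranges()
  if (is.null(parameters)) {
    parameters <- ranges$parameter
  } else {
    unknown <- setdiff(parameters, ranges$parameter)
    if (length(unknown)) {
      message("skipping parameter(s) without a published range: ",
              paste(unknown, collapse = ", "))
      parameters <- intersect(parameters, ranges$parameter)
    }
  }
  ranges <- ranges[ranges$parameter %in% parameters, , drop = FALSE]
  map_dfr(seq_len(nrow(ranges)), function(i) {
    nm <- ranges$parameter[i]
    vals <- seq(ranges$lower[i], ranges$upper[i], length.out = grid_points)
    map_dfr(vals, function(v) {
      if (verbose) message(sprintf("one-way SA: %s = %g", nm, v))
      pp <- .apply_sa_values(params, setNames(list(v), nm))
      cmp <- run_paired_comparison(pp, n = n, seed = seed)
      dplyr::bind_cols(tibble(parameter = nm, value = v), .sa_scalars(cmp))
    })
  })
}

#' Probabilistic sensitivity analysis
#'
#' Each draw samples every ranged parameter independently and uniformly
#' within its published limits (the limits are the only published
#' information about parameter uncertainty), rebuilds the parameter set,
#' and runs the full paired model comparison. Utility draws are not forced
#' to be monotone across severity states; occasional orderings with a more
#' severe state scoring higher are possible and retained.
#'
#' @param params Base [ckd_parameters()].
#' @param n_draws Number of parameter draws.
#' @param n Evaluation cohort size per cohort within each draw.
#' @param seed Master seed; draw `i` uses a substream derived from it, so
#'   the whole analysis is reproducible.
#' @param verbose Print progress?
#' @return A tibble with one row per draw: `draw`, the sampled parameter
#'   values (one column per parameter in [sa_parameter_ranges()]), the
#'   per-model scalars and the between-model differences as in
#'   [one_way_sa()]. Summarise with [psa_summary()].
#' @export
probabilistic_sa <- function(params, n_draws = 200, n = 2e4,
                             seed = params$seed, verbose = FALSE) {
  stopifnot(inherits(params, "ckd_params"))
  if (n_draws < 1) abort("`n_draws` must be at least 1")
  ranges <- sa_parameter_ranges()
  set.seed(.derive_seed(seed, 991L))
  draws <- matrix(runif(n_draws * nrow(ranges), min = rep(ranges$lower, each = n_draws),
                        max = rep(ranges$upper, each = n_draws)),
                  nrow = n_draws)
  colnames(draws) <- ranges$parameter
  map_dfr(seq_len(n_draws), function(i) {
    if (verbose) message(sprintf("PSA draw %d / %d", i, n_draws))
    vals <- as.list(draws[i, ])
    pp <- .apply_sa_values(params, vals)
    cmp <- run_paired_comparison(pp, n = n, seed = .derive_seed(seed, 1000L + i))
    dplyr::bind_cols(tibble(draw = i), as_tibble(draws[i, , drop = FALSE]),
                     .sa_scalars(cmp))
  })
}

#' Summarise a probabilistic sensitivity analysis
#'
#' Percentile summary (2.5th, 50th, 97.5th) of the between-model
#' differences, plus the fraction of draws in which the grade-based model's
#' value is below the kidney function-based model's.
#'
#' @param psa Output of [probabilistic_sa()].
#' @param probs Percentiles to report.
#' @return A tibble with one row per difference metric.
#' @export
psa_summary <- function(psa, probs = c(0.025, 0.5, 0.975)) {
  metrics <- c("d_life_years", "d_qaly", "d_cost", "d_v0", "d_v1")
  map_dfr(metrics, function(m) {
    q <- quantile(psa[[m]], probs = probs, names = FALSE)
    tibble(metric = m, lower = q[1], median = q[2], upper = q[3],
           prop_dg_lower = mean(psa[[m]] < 0))
  })
}
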