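# Outcome layer: life-years, discounted QALYs and costs, Kaplan-Meier renal
# survival, and the cost-effectiveness threshold statistics V0/V1.

#' Compute per-patient economics from a trajectory table
#'
#' Recomputes life-years (age at death or censoring), discounted QALYs and
#' discounted costs directly from per-cycle trajectory records. The
#' simulators accrue the same quantities on-line; this function provides an
#' independent path over the exported trajectories (useful for audits -- the
#' two must agree exactly). Per surviving cycle, the QALY increment is the
#' post-transition state's annual utility weight times the cycle length,
#' discounted at \eqn{(1+r)^{-t}} with `t` the years elapsed at the cycle
#' start; costs likewise with the cost discount rate. The cycle in which the
#' patient dies accrues nothing.
#'
#' @param trajectories Tibble with columns `patient_id, cycle, state, alive`
#'   (see [cohort_trajectories()]).
#' @param params A [ckd_parameters()] object (utilities, costs, discount
#'   rates, cycle length, initial age).
#' @return Tibble with one row per patient: `patient_id, life_years, qaly,
#'   cost`.
#' @export
economics <- function(trajectories, params = ckd_parameters()) {
  cl <- params$cycle_length
  u <- setNames(c(.state_utilities(params), 0), ckd_states())
  co <- setNames(c(.state_costs(params), 0), ckd_states())
  ru <- params$discount_utility
  rc <- params$discount_cost
  trajectories %>%
    group_by(.data$patient_id) %>%
    arrange(.data$cycle, .by_group = TRUE) %>%
    summarise(
      life_years = params$initial_age + max(.data$cycle[.data$alive]) * cl,
      qaly = sum(ifelse(.data$alive & .data$cycle > 0,
                        u[as.character(.data$state)] * cl *
                          (1 + ru)^(-(.data$cycle - 1) * cl), 0)),
      cost = sum(ifelse(.data$alive & .data$cycle > 0,
                        co[as.character(.data$state)] * cl *
                          (1 + rc)^(-(.data$cycle - 1) * cl), 0)),
      .groups = "drop"
    )
}

#' Kaplan-Meier renal survival
#'
#' Product-limit estimate of the probability of not yet requiring renal
#' replacement therapy. The event is entry into the ESRD state; death
#' before ESRD and reaching the maximum-age cap are censoring. Confidence
#' intervals use the Greenwood variance (via [survival::survfit()], log
#' transform).
#'
#' @param x A `ckd_cohort`, or a data frame with numeric columns `time`
#'   (years) and `event` (1 = ESRD onset, 0 = censored).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A `ckd_km` tibble: `time, n_risk, n_event, n_censor, survival,
#'   std_err, lower, upper`, beginning with the time-0 row (survival 1).
#'   The fitted `survfit` object is attached as an attribute for exact
#'   evaluation at arbitrary times via [km_survival_at()].
#' @export
#' @examples
#' km <- km_renal_survival(data.frame(time = 1:4, event = c(1, 0, 1, 0)))
#' km_survival_at(km, c(1, 3))  # 0.75, 0.375
km_renal_survival <- function(x, conf_level = 0.95) {
  if (inherits(x, "ckd_cohort")) {
    pt <- x$patients
    time <- ifelse(pt$esrd, pt$time_to_esrd, pt$followup)
    event <- as.integer(pt$esrd)
  } else if (is.data.frame(x) && all(c("time", "event") %in% names(x))) {
    time <- x$time
    event <- as.integer(x$event)
  } else {
    abort("`x` must be a ckd_cohort or a data frame with `time` and `event`")
  }
  if (length(time) < 1L) abort("at least one observation is required")
  fit <- survfit(Surv(time, event) ~ 1, conf.int = conf_level,
                 conf.type = "log")
  out <- tibble(
    time = c(0, fit$time),
    n_risk = c(length(time), fit$n.risk),
    n_event = c(0, fit$n.event),
    n_censor = c(0, fit$n.censor),
    survival = c(1, fit$surv),
    std_err = c(0, fit$surv * fit$std.err),
    lower = c(1, fit$lower),
    upper = c(1, fit$upper)
  )
  out <- structure(out, class = c("ckd_km", class(tibble())))
  attr(out, "survfit") <- fit
  out
}

#' Evaluate a renal-survival curve at given times
#'
#' Right-continuous step evaluation of the product-limit curve.
#'
#' @param km A `ckd_km` object from [km_renal_survival()].
#' @param times Numeric vector of times (years).
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(km, times) {
  fit <- attr(km, "survfit")
  if (is.null(fit)) abort("`km` must come from km_renal_survival()")
  s <- summary(fit, times = times, extend = TRUE)
  s$surv[match(times, s$time)]
}

#' Summarise one simulated cohort into arm-level outcomes
#'
#' Means and standard deviations of life-years (age at death or censoring),
#' discounted QALYs and discounted costs, plus the Kaplan-Meier renal
#' survival curve.
#'
#' @param cohort A `ckd_cohort`.
#' @return A `ckd_arm_outcome` list with elements `model, arm, n,
#'   life_years_mean/sd, qaly_mean/sd, cost_mean/sd, km`.
#' @export
arm_outcome <- function(cohort) {
  stopifnot(inherits(cohort, "ckd_cohort"))
  pt <- cohort$patients
  structure(
    list(
      model = cohort$model,
      arm = cohort$arm,
      n = cohort$n,
      life_years_mean = mean(pt$life_years),
      life_years_sd = sd(pt$life_years),
      qaly_mean = mean(pt$qaly),
      qaly_sd = sd(pt$qaly),
      cost_mean = mean(pt$cost),
      cost_sd = sd(pt$cost),
      km = km_renal_survival(cohort)
    ),
    class = "ckd_arm_outcome"
  )
}

#' @export
print.ckd_arm_outcome <- function(x, ...) {
  cat(sprintf("<ckd_arm_outcome> %s / %s (n = %d)\n", x$model, x$arm, x$n))
  cat(sprintf("  life-years %.2f (+/- %.2f); QALY %.2f (+/- %.2f); cost %.2f (+/- %.2f) k USD\n",
              x$life_years_mean, x$life_years_sd, x$qaly_mean, x$qaly_sd,
              x$cost_mean, x$cost_sd))
  invisible(x)
}

#' @export
as_tibble.ckd_arm_outcome <- function(x, ...) {
  tibble(model = x$model, arm = x$arm, n = x$n,
         life_years_mean = x$life_years_mean,
         life_years_sd = x$life_years_sd,
         qaly_mean = x$qaly_mean, qaly_sd = x$qaly_sd,
         cost_mean = x$cost_mean, cost_sd = x$cost_sd)
}

#' Cost-effectiveness threshold statistics V0 and V1
#'
#' For paired control/intervention outcomes, V0 = Ca - Cb is the
#' intervention price below which the intervention is dominant (assuming it
#' yields more utility), and V1 = lambda (Ub - Ua) + (Ca - Cb) is the price
#' below which it is cost-effective at willingness-to-pay lambda. Ca/Cb are
#' the mean discounted lifetime disease costs (excluding intervention cost)
#' and Ua/Ub the mean discounted QALYs of the control and intervention
#' arms. All monetary amounts in 1000 USD; lambda in 1000 USD per QALY.
#' The identity V1 - V0 = lambda (Ub - Ua) holds exactly.
#'
#' @param control,intervention [arm_outcome()] results (or any lists with
#'   `cost_mean` and `qaly_mean`).
#' @param lambda Willingness-to-pay threshold, 1000 USD/QALY (default 50).
#' @return A one-row tibble with columns `v0` and `v1` (1000 USD).
#' @export
#' @examples
#' thresholds(list(cost_mean = 286.85, qaly_mean = 19.43),
#'            list(cost_mean = 199.98, qaly_mean = 20.00))
thresholds <- function(control, intervention, lambda = 50) {
  for (o in list(control, intervention)) {
    if (!is.list(o) || is.null(o$cost_mean) || is.null(o$qaly_mean)) {
      abort("`control` and `intervention` must have `cost_mean` and `qaly_mean`")
    }
  }
  .assert_number(lambda, "lambda", 0, Inf)
  ca <- control$cost_mean
  cb <- intervention$cost_mean
  ua <- control$qaly_mean
  ub <- intervention$qaly_mean
  tibble(v0 = ca - cb, v1 = lambda * (ub - ua) + (ca - cb))
}
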