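# Paired model comparison: run the kidney-function model, translate its
# trajectories into per-grade transition probabilities, run the grade-based
# model with them, and compare the two models' economics on the same
# parameter set.

.new_comparison <- function(model, control, intervention, lambda) {
  th <- thresholds(control, intervention, lambda)
  structure(
    list(model = model, control = control, intervention = intervention,
         v0 = th$v0, v1 = th$v1, lambda = lambda),
    class = "ckd_comparison"
  )
}

#' Run the full paired comparison of both microsimulation models
#'
#' For each arm (control and intervention) this: (1) simulates an
#' independent calibration cohort under the kidney function-based model,
#' (2) estimates the per-grade transition table from it
#' ([estimate_transitions()]), (3) simulates evaluation cohorts under both
#' the kidney function-based and the (freshly calibrated) grade-based
#' model, and (4) summarises each cohort with [arm_outcome()]. Each model
#' then gets its V0/V1 threshold statistics from its own control and
#' intervention pair. The intervention enters the grade-based model only
#' through its translated transition probabilities; mortality, costs and
#' utilities are shared. All cohorts use independent random substreams
#' derived from `seed`, so a run is fully reproducible from
#' (parameters, seed).
#'
#' @param params A [ckd_parameters()] object.
#' @param n Evaluation cohort size per model and arm.
#' @param n_calibration Calibration cohort size (defaults to `n`).
#' @param seed Master seed.
#' @param weighting Transition-estimator weighting passed to
#'   [estimate_transitions()].
#' @param verbose Print per-stage progress messages?
#' @return A `ckd_model_comparison` object: per-model `ckd_comparison`
#'   entries (`$kf`, `$dg`, each with control/intervention
#'   [arm_outcome()]s and `v0`/`v1`), the per-arm transition tables, and
#'   run metadata. Use [tidy()] for a long per-metric table, [glance()] for
#'   one row per model.
#' @export
#' @examples
#' p <- ckd_parameters(cohort_size = 500)
#' cmp <- run_paired_comparison(p, seed = 7)
#' glance(cmp)
run_paired_comparison <- function(params, n = params$cohort_size,
                                  n_calibration = n, seed = params$seed,
                                  weighting = c("patient", "pair"),
                                  verbose = FALSE) {
  stopifnot(inherits(params, "ckd_params"))
  weighting <- match.arg(weighting)
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  outcomes <- list(kf = list(), dg = list())
  trans <- list()
  k <- 0L
  for (arm in c("control", "intervention")) {
    t0 <- Sys.time()
    calib <- simulate_cohort_kf(params, arm, n = n_calibration,
                                seed = .derive_seed(seed, k + 1L))
    trans[[arm]] <- estimate_transitions(calib, params,
                                         weighting = weighting)
    say("[%s] calibration + translation done (%.1fs)", arm,
        as.numeric(Sys.time() - t0, units = "secs"))
    kf <- simulate_cohort_kf(params, arm, n = n,
                             seed = .derive_seed(seed, k + 2L),
                             count_pairs = FALSE)
    dg <- simulate_cohort_dg(params, trans[[arm]], arm = arm, n = n,
                             seed = .derive_seed(seed, k + 3L))
    outcomes$kf[[arm]] <- arm_outcome(kf)
    outcomes$dg[[arm]] <- arm_outcome(dg)
    say("[%s] evaluation cohorts done (%.1fs total)", arm,
        as.numeric(Sys.time() - t0, units = "secs"))
    k <- k + 3L
  }
  structure(
    list(
      kf = .new_comparison("kf", outcomes$kf$control,
                           outcomes$kf$intervention, params$wtp),
      dg = .new_comparison("dg", outcomes$dg$control,
                           outcomes$dg$intervention, params$wtp),
      transitions = trans,
      params = params, n = n, n_calibration = n_calibration, seed = seed
    ),
    class = "ckd_model_comparison"
  )
}

#' @export
print.ckd_comparison <- function(x, ...) {
  cat(sprintf("<ckd_comparison> %s model\n", x$model))
  print(x$control)
  print(x$intervention)
  cat(sprintf("  V0 = %.2f, V1 = %.2f (1000 USD, lambda = %g)\n",
              x$v0, x$v1, x$lambda))
  invisible(x)
}

#' Tidy a model comparison into a long per-metric table
#'
#' @param x A `ckd_model_comparison` from [run_paired_comparison()].
#' @param ... Unused.
#' @return A tibble with columns `model, arm, metric, mean, sd` for
#'   life-years, discounted QALYs and discounted costs.
#' @export
tidy.ckd_model_comparison <- function(x, ...) {
  map_dfr(list(x$dg, x$kf), function(cmpr) {
    map_dfr(list(cmpr$control, cmpr$intervention), function(oc) {
      tibble(
        model = oc$model, arm = oc$arm,
        metric = c("life_years", "qaly", "cost"),
        mean = c(oc$life_years_mean, oc$qaly_mean, oc$cost_mean),
        sd = c(oc$life_years_sd, oc$qaly_sd, oc$cost_sd)
      )
    })
  })
}

#' One-row-per-model summary of a comparison
#'
#' @param x A `ckd_model_comparison`.
#' @param ... Unused.
#' @return A tibble with one row per model: control/intervention means of
#'   life-years, QALYs and costs, plus `v0` and `v1` (1000 USD).
#' @export
glance.ckd_model_comparison <- function(x, ...) {
  map_dfr(list(x$dg, x$kf), function(cmpr) {
    tibble(
      model = cmpr$model,
      life_years_control = cmpr$control$life_years_mean,
      life_years_intervention = cmpr$intervention$life_years_mean,
      qaly_control = cmpr$control$qaly_mean,
      qaly_intervention = cmpr$intervention$qaly_mean,
      cost_control = cmpr$control$cost_mean,
      cost_intervention = cmpr$intervention$cost_mean,
      v0 = cmpr$v0,
      v1 = cmpr$v1
    )
  })
}

#' @export
print.ckd_model_comparison <- function(x, ...) {
  cat(sprintf("<ckd_model_comparison> n = %d per cohort (calibration %d), seed %s\n",
              x$n, x$n_calibration, format(x$seed)))
  print(glance(x))
  invisible(x)
}
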