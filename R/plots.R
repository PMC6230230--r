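# ggplot2 displays for the main result types.

#' Plot a renal-survival curve
#'
#' Step plot of the Kaplan-Meier renal survival with its confidence band.
#'
#' @param object A `ckd_km` from [km_renal_survival()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ckd_km <- function(object, ...) {
  ggplot(object, aes(x = .data$time, y = .data$survival)) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper),
                fill = "grey70", alpha = 0.5) +
    geom_step(linewidth = 0.7) +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "Years from start", y = "Renal survival",
         title = "Kaplan-Meier renal survival") +
    theme_minimal()
}

#' Plot renal survival for all four cohorts of a model comparison
#'
#' Overlays the control/intervention Kaplan-Meier renal-survival curves of
#' both models.
#'
#' @param object A `ckd_model_comparison` from [run_paired_comparison()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ckd_model_comparison <- function(object, ...) {
  curves <- map_dfr(list(object$dg, object$kf), function(cmpr) {
    map_dfr(list(cmpr$control, cmpr$intervention), function(oc) {
      km <- oc$km
      tibble(model = oc$model, arm = oc$arm,
             time = km$time, survival = km$survival)
    })
  })
  labeller <- c(dg = "grade-based", kf = "kidney function-based")
  curves$model <- labeller[curves$model]
  ggplot(curves, aes(x = .data$time, y = .data$survival,
                     colour = .data$model, linetype = .data$arm)) +
    geom_step(linewidth = 0.7) +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "Years from start", y = "Renal survival",
         colour = "Model", linetype = "Arm") +
    theme_minimal()
}

#' Tornado-style display of a one-way sensitivity analysis
#'
#' For each varied parameter, shows the range of a chosen between-model
#' difference metric across the parameter's grid.
#'
#' @param ow Output of [one_way_sa()].
#' @param metric One of the difference columns (default `"d_v0"`).
#' @return A ggplot object.
#' @export
plot_tornado <- function(ow, metric = "d_v0") {
  if (!metric %in% names(ow)) abort(sprintf("no column `%s` in `ow`", metric))
  rng <- ow %>%
    group_by(.data$parameter) %>%
    summarise(lo = min(.data[[metric]]), hi = max(.data[[metric]]),
              .groups = "drop") %>%
    mutate(spread = .data$hi - .data$lo) %>%
    arrange(.data$spread)
  rng$parameter <- factor(rng$parameter, levels = rng$parameter)
  ggplot(rng, aes(y = .data$parameter)) +
    geom_segment(aes(x = .data$lo, xend = .data$hi,
                     yend = .data$parameter), linewidth = 3,
                 colour = "steelblue") +
    labs(x = metric, y = NULL,
         title = "One-way sensitivity: between-model difference") +
    theme_minimal()
}

#' Scatter display of a probabilistic sensitivity analysis
#'
#' Plots one model's values against the other's across PSA draws for a
#' chosen metric; points below the identity line are draws where the
#' grade-based model gives the smaller value.
#'
#' @param psa Output of [probabilistic_sa()].
#' @param metric One of `"life_years"`, `"qaly"`, `"cost"`, `"v0"`,
#'   `"v1"`.
#' @return A ggplot object.
#' @export
plot_psa <- function(psa, metric = "v0") {
  xcol <- paste0(metric, "_kf")
  ycol <- paste0(metric, "_dg")
  if (!all(c(xcol, ycol) %in% names(psa))) {
    abort(sprintf("no columns `%s`/`%s` in `psa`", xcol, ycol))
  }
  ggplot(psa, aes(x = .data[[xcol]], y = .data[[ycol]])) +
    geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    geom_point(alpha = 0.5) +
    labs(x = paste(metric, "(kidney function-based)"),
         y = paste(metric, "(grade-based)")) +
    theme_minimal()
}
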