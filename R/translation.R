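# Translation: estimate the grade-based model's per-cycle transition
# probabilities from kidney-function trajectories, so both models can be
# compared under the same conditions. Pairs ending in death are excluded
# because the grade-based model applies its own mortality.

# Per-(patient, source grade) pair counts and progression flags from an
# explicit trajectory table; also the pooled 6 x 7 from-to pair matrix.
.pair_stats_from_trajectories <- function(traj, subsample_fraction = NULL,
                                          seed = NULL) {
  states <- ckd_states()
  pairs <- traj %>%
    group_by(.data$patient_id) %>%
    arrange(.data$cycle, .by_group = TRUE) %>%
    mutate(next_state = lead(.data$state),
           next_alive = lead(.data$alive)) %>%
    ungroup() %>%
    filter(.data$alive, !is.na(.data$next_alive), .data$next_alive,
           as.integer(.data$state) <= 6L)
  if (!is.null(subsample_fraction)) {
    .assert_number(subsample_fraction, "subsample_fraction", 0, 1)
    if (!is.null(seed)) set.seed(seed)
    keep <- runif(nrow(pairs)) < subsample_fraction
    pairs <- pairs[keep, , drop = FALSE]
  }
  from <- as.integer(factor(as.character(pairs$state), levels = states))
  to <- as.integer(factor(as.character(pairs$next_state), levels = states))
  pc <- matrix(tabulate(from + (to - 1L) * 6L, 42L), 6L, 7L)
  per <- tibble(patient_id = pairs$patient_id, from = from,
                worse = to > from) %>%
    group_by(.data$patient_id, .data$from) %>%
    summarise(n = dplyr::n(), ev = any(.data$worse), .groups = "drop")
  by_grade <- per %>%
    group_by(.data$from) %>%
    summarise(n_patients = dplyr::n(), sum_ratio = sum(.data$ev / .data$n),
              .groups = "drop")
  n_patients <- integer(6L)
  sum_ratio <- numeric(6L)
  n_patients[by_grade$from] <- by_grade$n_patients
  sum_ratio[by_grade$from] <- by_grade$sum_ratio
  alive_states <- unique(as.integer(factor(
    as.character(traj$state[traj$alive]), levels = states)))
  visited <- seq_len(6L) %in% alive_states
  list(pc = pc, n_patients = n_patients, sum_ratio = sum_ratio,
       visited = visited)
}

#' Estimate grade transition probabilities from kidney-function output
#'
#' Builds the per-grade per-cycle progression probabilities that drive
#' [simulate_cohort_dg()] from simulated kidney-function trajectories,
#' using only alive-alive consecutive-cycle pairs (pairs ending in death
#' are excluded; the grade-based model applies its own mortality). A
#' transition spanning several grades counts once as a single progression
#' event from its source grade, matching the adjacent chain topology of the
#' grade-based model.
#'
#' Two estimators are available:
#' \describe{
#'   \item{`weighting = "patient"` (default)}{the registry-style fraction
#'     of *patients* observed in grade g who progress: each patient
#'     occupying g contributes its event indicator divided by its number of
#'     pairs in g. This is the expectation of sampling one random visit
#'     pair per patient per grade, the way grade-transition probabilities
#'     are read off real patient records.}
#'   \item{`weighting = "pair"`}{the pooled fraction of all alive-alive
#'     pairs in grade g that progress. Pairs per patient scale inversely
#'     with the decline slope, so this weights slow decliners more
#'     heavily and yields systematically smaller probabilities.}
#' }
#'
#' @param x A kidney-function `ckd_cohort` (its streaming pair statistics
#'   are used), or a trajectory tibble with columns
#'   `patient_id, cycle, state, alive`.
#' @param params A [ckd_parameters()] object (validated for consistency
#'   with the cohort). A grade that the trajectories occupied but for which
#'   no alive-alive pair exists is an estimation error naming the grade;
#'   grades never reached (e.g. under zero decline) simply get `NA`.
#' @param weighting `"patient"` or `"pair"` (see above).
#' @param collapse If `TRUE` (default), return the adjacent-chain
#'   `ckd_transitions` table; if `FALSE`, the full from-to matrix of
#'   observed pairs as a `ckd_transition_matrix` (pair weighting only),
#'   enabling multi-grade jumps in [simulate_cohort_dg()].
#' @param subsample_fraction Optionally use a random fraction of the pairs
#'   (mimicking literal random sampling of visit pairs); only available
#'   when `x` is a trajectory table, since the streaming counters do not
#'   retain the individual pairs.
#' @param seed Seed for the subsampling draw.
#' @return A `ckd_transitions` tibble (`state, p_progress, n_pairs,
#'   n_events, n_patients`) or, with `collapse = FALSE`, a
#'   `ckd_transition_matrix` tibble (`from, to, n, p`) carrying the 6 x 7
#'   count matrix as an attribute.
#' @export
#' @examples
#' p <- ckd_parameters(cohort_size = 500)
#' kf <- simulate_cohort_kf(p, "control", seed = 42)
#' estimate_transitions(kf, p)
estimate_transitions <- function(x, params,
                                 weighting = c("patient", "pair"),
                                 collapse = TRUE,
                                 subsample_fraction = NULL, seed = NULL) {
  stopifnot(inherits(params, "ckd_params"))
  weighting <- match.arg(weighting)
  if (inherits(x, "ckd_cohort")) {
    if (x$model != "kf" || is.null(x$pair_counts)) {
      abort("`x` must be a kidney-function cohort with pair counts")
    }
    if (!is.null(subsample_fraction)) {
      if (is.null(x$trajectories)) {
        abort("`subsample_fraction` needs a trajectory table; re-simulate with `keep_trajectories = TRUE` or pass trajectories directly")
      }
      st <- .pair_stats_from_trajectories(x$trajectories,
                                          subsample_fraction, seed)
    } else {
      st <- list(pc = attr(x$pair_counts, "matrix"),
                 n_patients = x$pair_counts$n_patients,
                 sum_ratio = x$pair_counts$sum_ratio,
                 visited = x$pair_counts$visited)
    }
  } else if (is.data.frame(x)) {
    need <- c("patient_id", "cycle", "state", "alive")
    if (!all(need %in% names(x))) {
      abort("trajectory table must have columns patient_id, cycle, state, alive")
    }
    st <- .pair_stats_from_trajectories(x, subsample_fraction, seed)
  } else {
    abort("`x` must be a ckd_cohort or a trajectory table")
  }

  grades <- ckd_states()[1:6]
  pc <- st$pc
  denom <- rowSums(pc)
  # grades the trajectories actually occupied (alive) must be estimable; a
  # grade occupied only by patients who then died has no alive-alive pair
  empty <- which(st$visited & denom == 0)
  if (length(empty)) {
    abort(sprintf("no alive-alive pairs observed for reachable grade(s): %s",
                  paste(grades[empty], collapse = ", ")))
  }

  if (!collapse) {
    if (weighting == "patient") {
      abort("`collapse = FALSE` is only available with `weighting = \"pair\"`")
    }
    # expand.grid and as.integer(pc) share column-major order (from fastest)
    df <- as_tibble(expand.grid(from = grades,
                                to = ckd_states()[1:7],
                                stringsAsFactors = FALSE))
    df$n <- as.integer(pc)
    df$p <- ifelse(rep(denom, 7) > 0, df$n / rep(denom, 7), NA_real_)
    df <- df %>% filter(!is.na(.data$p))
    out <- structure(df, class = c("ckd_transition_matrix", class(tibble())))
    attr(out, "matrix") <- pc
    return(out)
  }

  worse <- row(pc) < col(pc)
  events <- rowSums(pc * worse)
  p <- if (weighting == "pair") {
    ifelse(denom > 0, events / denom, NA_real_)
  } else {
    ifelse(st$n_patients > 0, st$sum_ratio / st$n_patients, NA_real_)
  }
  structure(
    tibble(state = grades, p_progress = p,
           n_pairs = as.integer(denom), n_events = as.integer(events),
           n_patients = as.integer(st$n_patients)),
    class = c("ckd_transitions", "tbl_df", "tbl", "data.frame")
  )
}
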