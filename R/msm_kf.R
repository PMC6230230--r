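# Kidney function-based microsimulation (MSM-kf): two states (alive/dead);
# the alive state carries an eGFR that declines linearly at a per-patient
# slope drawn once from a log-normal law. Severity (and hence mortality,
# cost, utility) is recomputed from eGFR each quarter; once eGFR reaches the
# renal replacement threshold the patient is permanently on dialysis.

# Half male / half female; an odd cohort's extra patient is decided by the
# (already seeded) RNG stream.
.assign_sexes <- function(n) {
  half <- n %/% 2L
  male <- c(rep(TRUE, half), rep(FALSE, half))
  if (n %% 2L == 1L) male <- c(male, runif(1) < 0.5)
  male
}

# Core per-cycle loop, vectorised over patients. Within a cycle: (1) the
# death test at the current age and state, (2) survivors' eGFR moves along
# its closed-form line eGFR0 - slope * elapsed, (3) the grade is recomputed,
# (4) the survivors accrue the cycle's cost and utility in the
# post-transition state, discounted at the cycle-start time.
.sim_kf <- function(params, male, slope, keep_traj = FALSE,
                    count_pairs = TRUE) {
  n <- length(male)
  cl <- params$cycle_length
  a0 <- params$initial_age
  n_cycles <- .n_cycles(params)
  thr <- params$esrd_threshold
  breaks <- .grade_breaks(thr)
  mult <- .grade_multipliers(params)
  u_state <- .state_utilities(params)
  c_state <- .state_costs(params)
  disc_u <- (1 + params$discount_utility)^(-(0:(n_cycles - 1L)) * cl)
  disc_c <- (1 + params$discount_cost)^(-(0:(n_cycles - 1L)) * cl)

  egfr0 <- params$initial_egfr
  egfr <- rep(egfr0, n)
  grade <- rep(.grade_code(egfr0, thr), n)
  qaly <- numeric(n)
  cost <- numeric(n)
  death_cycle <- rep(NA_integer_, n)
  esrd_cycle <- rep(NA_integer_, n)
  pair_counts <- matrix(0L, nrow = 6L, ncol = 7L)  # from G1..G5 x to G1..ESRD
  # per-patient pair counts / progression flags by source grade, for the
  # per-patient (registry-style) transition estimator
  pp_n <- matrix(0L, nrow = n, ncol = 6L)
  pp_ev <- matrix(FALSE, nrow = n, ncol = 6L)
  visited <- rep(FALSE, 6L)
  visited[.grade_code(egfr0, thr)] <- TRUE
  active <- seq_len(n)
  if (keep_traj) {
    Gmat <- matrix(NA_integer_, n, n_cycles + 1L)
    Emat <- matrix(NA_real_, n, n_cycles + 1L)
    Gmat[, 1L] <- grade
    Emat[, 1L] <- egfr
  }

  # per-cycle death-probability lookup indexed by state code + sex offset:
  # 1..6 female predialysis, 7..12 male predialysis, 13 dialysis
  sex_off <- 6L * male
  for (t in 0:(n_cycles - 1L)) {
    if (!length(active)) break
    age <- a0 + t * cl
    lut <- c(
      -expm1(-params$mort_female_a * exp(params$mort_female_b * age) *
               mult * cl),
      -expm1(-params$mort_male_a * exp(params$mort_male_b * age) *
               mult * cl),
      -expm1(-params$mort_dialysis_a *
               exp(params$mort_dialysis_b * age) * cl)
    )
    g <- grade[active]
    idx <- g + sex_off[active]
    idx[g == 7L] <- 13L

    die <- runif(length(active)) < lut[idx]
    dead <- active[die]
    death_cycle[dead] <- t
    surv <- active[!die]

    nd <- surv[grade[surv] < 7L]
    if (length(nd)) {
      g_old <- grade[nd]
      e_new <- pmax(egfr0 - slope[nd] * ((t + 1L) * cl), 0)
      g_new <- .grade_code(e_new, thr)
      if (count_pairs) {
        pair_counts <- pair_counts +
          matrix(tabulate(g_old + (g_new - 1L) * 6L, 42L), 6L, 7L)
        lin <- nd + (g_old - 1L) * n
        pp_n[lin] <- pp_n[lin] + 1L
        pp_ev[lin[g_new > g_old]] <- TRUE
      }
      visited[unique(g_new[g_new < 7L])] <- TRUE
      egfr[nd] <- e_new
      grade[nd] <- g_new
      started <- nd[g_new == 7L]
      esrd_cycle[started] <- t + 1L
    }

    gs <- grade[surv]
    qaly[surv] <- qaly[surv] + u_state[gs] * cl * disc_u[t + 1L]
    cost[surv] <- cost[surv] + c_state[gs] * cl * disc_c[t + 1L]
    if (keep_traj) {
      Gmat[surv, t + 2L] <- gs
      e_show <- egfr[surv]
      e_show[gs == 7L] <- NA_real_
      Emat[surv, t + 2L] <- e_show
      Gmat[dead, t + 2L] <- 8L
    }
    active <- surv
  }

  out <- list(death_cycle = death_cycle, esrd_cycle = esrd_cycle,
              qaly = qaly, cost = cost, n_cycles = n_cycles,
              pair_counts = if (count_pairs) pair_counts,
              # per grade: patients with >= 1 alive-alive pair, and the sum
              # of per-patient event/pair ratios
              pp_n_patients = if (count_pairs) colSums(pp_n > 0L),
              pp_sum_ratio = if (count_pairs) {
                colSums((pp_ev * 1) / pmax(pp_n, 1L))
              },
              visited = visited)
  if (keep_traj) {
    out$Gmat <- Gmat
    out$Emat <- Emat
  }
  out
}

.build_trajectories <- function(Gmat, Emat, male, arm, a0, cl,
                                death_cycle, n_cycles) {
  n <- nrow(Gmat)
  len <- ifelse(!is.na(death_cycle), death_cycle + 2L, n_cycles + 1L)
  pid <- rep(seq_len(n), len)
  cyc <- sequence(len) - 1L
  idx <- cbind(pid, cyc + 1L)
  codes <- Gmat[idx]
  sexes <- ifelse(male, "male", "female")
  tibble(
    patient_id = pid,
    arm = arm,
    sex = sexes[pid],
    cycle = cyc,
    age = a0 + cyc * cl,
    egfr = if (is.null(Emat)) NA_real_ else Emat[idx],
    state = factor(ckd_states()[codes], levels = ckd_states()),
    alive = codes != 8L
  )
}

.finish_cohort <- function(model, arm, params, male, slope, sim, seed,
                           keep_traj) {
  n <- length(male)
  cl <- params$cycle_length
  a0 <- params$initial_age
  died <- !is.na(sim$death_cycle)
  followup_cycles <- ifelse(died, sim$death_cycle, sim$n_cycles)
  patients <- tibble(
    patient_id = seq_len(n),
    arm = arm,
    sex = ifelse(male, "male", "female"),
    slope = if (is.null(slope)) NA_real_ else slope,
    died = died,
    life_years = a0 + followup_cycles * cl,
    esrd = !is.na(sim$esrd_cycle),
    time_to_esrd = sim$esrd_cycle * cl,
    followup = followup_cycles * cl,
    qaly = sim$qaly,
    cost = sim$cost
  )
  pc <- sim$pair_counts
  pair_counts <- NULL
  if (!is.null(pc)) {
    worse <- row(pc) < col(pc)
    pair_counts <- tibble(
      state = ckd_states()[1:6],
      n_pairs = as.integer(rowSums(pc)),
      n_events = as.integer(rowSums(pc * worse)),
      n_patients = as.integer(sim$pp_n_patients),
      sum_ratio = sim$pp_sum_ratio,
      visited = sim$visited
    )
    attr(pair_counts, "matrix") <- pc
  }
  trajectories <- NULL
  if (keep_traj) {
    trajectories <- .build_trajectories(sim$Gmat, sim$Emat, male, arm, a0,
                                        cl, sim$death_cycle, sim$n_cycles)
  }
  structure(
    list(model = model, arm = arm, n = n, seed = seed,
         patients = patients, pair_counts = pair_counts,
         trajectories = trajectories, params = params),
    class = "ckd_cohort"
  )
}

#' Simulate a cohort under the kidney function-based model (MSM-kf)
#'
#' Each virtual patient draws a constant annual eGFR decline slope once from
#' the arm's log-normal distribution and then walks quarterly cycles: a
#' Bernoulli death test at the current age/state hazard, then (if alive) the
#' eGFR moves down its line and the CKD grade is recomputed. Once eGFR
#' reaches the ESRD threshold the patient is permanently on dialysis
#' (dialysis mortality, cost and utility). Simulation ends at death or at
#' the maximum-age cap (censoring). Costs and utilities accrue per surviving
#' cycle in the post-transition state, discounted at the cycle-start time.
#'
#' @param params A [ckd_parameters()] object.
#' @param arm `"control"` or `"intervention"`; selects the decline
#'   distribution (`decline_mean`/`decline_sd` vs the `_treated` pair).
#' @param n Cohort size (half male, half female; an odd size's extra
#'   patient is randomised).
#' @param seed Integer seed for this cohort's random stream; the same seed
#'   reproduces the cohort exactly.
#' @param keep_trajectories Keep the full per-cycle record (one row per
#'   patient-cycle)? Memory grows as `n` times the number of cycles; intended
#'   for small cohorts and validation.
#' @param sexes Optional character vector (`"male"`/`"female"`, length `n`)
#'   overriding the default half-and-half assignment.
#' @param slopes Optional numeric vector (length `n` or 1) of fixed decline
#'   slopes, bypassing the log-normal draw. Useful for deterministic
#'   validation runs.
#' @param count_pairs Maintain the streaming consecutive-pair statistics
#'   used by [estimate_transitions()]? Disable for evaluation cohorts that
#'   will not be translated (slightly faster).
#' @return A `ckd_cohort` object: a list with `patients` (one row per
#'   patient: sex, slope, death/censoring, ESRD onset, accrued discounted
#'   QALYs and costs), `pair_counts` (per-grade consecutive-pair counts used
#'   by [estimate_transitions()]), and optionally `trajectories`.
#' @seealso [simulate_cohort_dg()], [estimate_transitions()],
#'   [arm_outcome()]
#' @export
#' @examples
#' coh <- simulate_cohort_kf(ckd_parameters(), "control", n = 200, seed = 1)
#' dplyr::glimpse(coh$patients)
simulate_cohort_kf <- function(params, arm = c("control", "intervention"),
                               n = params$cohort_size, seed = params$seed,
                               keep_trajectories = FALSE, sexes = NULL,
                               slopes = NULL, count_pairs = TRUE) {
  stopifnot(inherits(params, "ckd_params"))
  arm <- match.arg(arm)
  n <- as.integer(n)
  if (n < 1L) abort("`n` must be at least 1")
  set.seed(seed)
  if (is.null(sexes)) {
    male <- .assign_sexes(n)
  } else {
    if (length(sexes) != n || !all(sexes %in% c("male", "female"))) {
      abort("`sexes` must be length `n` with values \"male\"/\"female\"")
    }
    male <- sexes == "male"
  }
  if (is.null(slopes)) {
    dist <- if (arm == "control") {
      lognormal_params(params$decline_mean, params$decline_sd)
    } else {
      lognormal_params(params$decline_mean_treated, params$decline_sd_treated)
    }
    slope <- rlnorm(n, dist$meanlog, dist$sdlog)
  } else {
    if (any(slopes < 0)) abort("`slopes` must be non-negative")
    slope <- rep_len(as.double(slopes), n)
  }
  sim <- .sim_kf(params, male, slope, keep_traj = keep_trajectories,
                 count_pairs = count_pairs)
  .finish_cohort("kf", arm, params, male, slope, sim, seed,
                 keep_trajectories)
}

#' Simulate a single patient under the kidney function-based model
#'
#' Convenience wrapper around [simulate_cohort_kf()] for one patient with a
#' known sex (and optionally a fixed slope), always keeping the full
#' trajectory.
#'
#' @inheritParams simulate_cohort_kf
#' @param sex `"male"` or `"female"`.
#' @param slope Optional fixed decline slope.
#' @return A one-patient `ckd_cohort` with `trajectories` filled in.
#' @export
simulate_patient_kf <- function(params, arm = c("control", "intervention"),
                                sex = "male", seed = params$seed,
                                slope = NULL) {
  simulate_cohort_kf(params, arm, n = 1L, seed = seed,
                     keep_trajectories = TRUE, sexes = sex, slopes = slope)
}

#' Per-cycle trajectory records of a simulated cohort
#'
#' Returns the trajectory table (requires the cohort to have been simulated
#' with `keep_trajectories = TRUE`), one row per patient-cycle in
#' deterministic order, with the documented column order
#' `patient_id, arm, sex, cycle, age, egfr, state, alive`. Suitable for
#' direct CSV export.
#'
#' @param cohort A `ckd_cohort`.
#' @return A tibble.
#' @export
cohort_trajectories <- function(cohort) {
  stopifnot(inherits(cohort, "ckd_cohort"))
  if (is.null(cohort$trajectories)) {
    abort("cohort was simulated without `keep_trajectories = TRUE`")
  }
  cohort$trajectories
}

#' @export
print.ckd_cohort <- function(x, ...) {
  lab <- if (x$model == "kf") "kidney function-based" else "disease grade-based"
  cat(sprintf("<ckd_cohort> %s model, %s arm, n = %d (seed %s)\n",
              lab, x$arm, x$n, format(x$seed)))
  cat(sprintf("  deaths: %d; reached ESRD: %d\n",
              sum(x$patients$died), sum(x$patients$esrd)))
  cat(sprintf("  mean life-years %.2f; mean discounted QALY %.2f; mean discounted cost %.1f k USD\n",
              mean(x$patients$life_years), mean(x$patients$qaly),
              mean(x$patients$cost)))
  invisible(x)
}

#' @export
as_tibble.ckd_cohort <- function(x, ...) x$patients

#' Tidy a simulated cohort into its per-patient summary table
#'
#' @param x A `ckd_cohort`.
#' @param ... Unused.
#' @return The `patients` tibble (one row per patient).
#' @export
tidy.ckd_cohort <- function(x, ...) x$patients
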