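# Disease grade-based microsimulation (MSM-dg): discrete states G1..G5,
# ESRD and dead; per-cycle progression probabilities depend on the grade
# only. Mortality, costs and utilities are shared with the kidney
# function-based model; the progression probabilities normally come from
# estimate_transitions() so both models run under the same conditions.

#' Construct a per-grade transition table
#'
#' A transition table gives, for each predialysis grade, the per-cycle
#' probability of progressing to the next-worse state (G5's target is
#' ESRD). [estimate_transitions()] builds one from simulated
#' kidney-function trajectories; this constructor is for hand-specified
#' tables (validation, exploration).
#'
#' @param p Named numeric vector of per-cycle progression probabilities,
#'   names among `G1, G2, G3a, G3b, G4, G5`; each in \[0, 1\]. Grades not
#'   named get `NA` (allowed if unreachable from the initial grade).
#' @param n_pairs,n_events Optional integer vectors (same names) recording
#'   the pair counts behind each estimate.
#' @return A `ckd_transitions` tibble with columns
#'   `state, p_progress, n_pairs, n_events`.
#' @export
#' @examples
#' transition_table(c(G2 = 0.01, G3a = 0.02, G3b = 0.03, G4 = 0.05, G5 = 0.05))
transition_table <- function(p, n_pairs = NULL, n_events = NULL) {
  grades <- ckd_states()[1:6]
  if (is.null(names(p)) || !all(names(p) %in% grades)) {
    abort("`p` must be named with CKD grades (G1..G5)")
  }
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    abort("progression probabilities must lie in [0, 1]")
  }
  full <- setNames(rep(NA_real_, 6L), grades)
  full[names(p)] <- p
  np <- setNames(rep(NA_integer_, 6L), grades)
  if (!is.null(n_pairs)) np[names(n_pairs)] <- as.integer(n_pairs)
  ne <- setNames(rep(NA_integer_, 6L), grades)
  if (!is.null(n_events)) ne[names(n_events)] <- as.integer(n_events)
  structure(
    tibble(state = grades, p_progress = unname(full),
           n_pairs = unname(np), n_events = unname(ne)),
    class = c("ckd_transitions", "tbl_df", "tbl", "data.frame")
  )
}

# Per-cycle loop for the grade-based model. Death first (at the current
# age/sex/grade), then progression; ESRD and death absorbing; no regression
# to milder grades.
.sim_dg <- function(params, male, p_prog, trans_matrix = NULL,
                    keep_traj = FALSE) {
  n <- length(male)
  cl <- params$cycle_length
  a0 <- params$initial_age
  n_cycles <- .n_cycles(params)
  mult <- .grade_multipliers(params)
  u_state <- .state_utilities(params)
  c_state <- .state_costs(params)
  disc_u <- (1 + params$discount_utility)^(-(0:(n_cycles - 1L)) * cl)
  disc_c <- (1 + params$discount_cost)^(-(0:(n_cycles - 1L)) * cl)

  g0 <- .grade_code(params$initial_egfr, params$esrd_threshold)
  grade <- rep(g0, n)
  qaly <- numeric(n)
  cost <- numeric(n)
  death_cycle <- rep(NA_integer_, n)
  esrd_cycle <- rep(NA_integer_, n)
  active <- seq_len(n)
  cum_rows <- NULL
  if (!is.null(trans_matrix)) {
    # row g: normalised cumulative probabilities over targets g..7
    cum_rows <- lapply(1:6, function(g) {
      cs <- cumsum(trans_matrix[g, g:7])
      cs / cs[length(cs)]
    })
  }
  if (keep_traj) {
    Gmat <- matrix(NA_integer_, n, n_cycles + 1L)
    Gmat[, 1L] <- grade
  }

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
      v <- runif(length(nd))
      if (is.null(trans_matrix)) {
        g_new <- g_old + as.integer(v < p_prog[g_old])
      } else {
        g_new <- g_old
        for (gv in unique(g_old)) {
          sel <- g_old == gv
          cp <- cum_rows[[gv]]
          # target index among gv..7: count of cumulative bins at or below v
          g_new[sel] <- gv + findInterval(v[sel], cp[-length(cp)])
        }
      }
      grade[nd] <- g_new
      started <- nd[g_new == 7L]
      esrd_cycle[started] <- t + 1L
    }

    gs <- grade[surv]
    qaly[surv] <- qaly[surv] + u_state[gs] * cl * disc_u[t + 1L]
    cost[surv] <- cost[surv] + c_state[gs] * cl * disc_c[t + 1L]
    if (keep_traj) {
      Gmat[surv, t + 2L] <- gs
      Gmat[dead, t + 2L] <- 8L
    }
    active <- surv
  }

  out <- list(death_cycle = death_cycle, esrd_cycle = esrd_cycle,
              qaly = qaly, cost = cost, n_cycles = n_cycles,
              pair_counts = NULL)
  if (keep_traj) {
    out$Gmat <- Gmat
    out$Emat <- NULL
  }
  out
}

# Walk the chain (or jump graph) from the initial grade and require a
# defined transition entry for every predialysis grade the simulation could
# occupy. Grades cut off by a zero probability upstream need no entry.
.check_transitions_cover <- function(transitions, params) {
  g0 <- .grade_code(params$initial_egfr, params$esrd_threshold)
  if (g0 >= 7L) abort("initial state must be a predialysis grade")
  grades <- ckd_states()[1:6]
  if (inherits(transitions, "ckd_transition_matrix")) {
    m <- attr(transitions, "matrix")
    reach <- g0
    repeat {
      nxt <- integer(0)
      for (g in reach) {
        if (sum(m[g, ]) > 0) {
          nxt <- c(nxt, setdiff(which(m[g, ] > 0), 7L))
        }
      }
      nxt <- setdiff(unique(c(reach, nxt[nxt > g0])), reach)
      if (!length(nxt)) break
      reach <- sort(unique(c(reach, nxt)))
    }
    bad <- grades[reach][rowSums(m[reach, , drop = FALSE]) <= 0]
    if (length(bad)) {
      abort(sprintf("transition matrix has no observations for occupiable grade(s): %s",
                    paste(bad, collapse = ", ")))
    }
    return(invisible(transitions))
  }
  p <- setNames(transitions$p_progress, transitions$state)[grades]
  g <- g0
  repeat {
    if (is.na(p[g])) {
      abort(sprintf("no transition probability for reachable grade %s",
                    grades[g]))
    }
    if (p[g] <= 0 || g == 6L) break
    g <- g + 1L
  }
  invisible(transitions)
}

#' Simulate a cohort under the disease grade-based model (MSM-dg)
#'
#' Discrete-state microsimulation over the CKD grades. Each quarterly
#' cycle: a Bernoulli death test from the age/sex/grade hazard (the same
#' mortality model as [simulate_cohort_kf()]), then, if alive, progression
#' to the next-worse state with the current grade's per-cycle probability.
#' There is no regression to milder grades; ESRD and death are absorbing.
#' The trajectory's eGFR field is unset (the grade is the state). Costs and
#' utilities accrue exactly as in the kidney-function model.
#'
#' @inheritParams simulate_cohort_kf
#' @param transitions A `ckd_transitions` table (from
#'   [estimate_transitions()] or [transition_table()]), or a
#'   `ckd_transition_matrix` (from `estimate_transitions(collapse = FALSE)`)
#'   allowing multi-grade jumps. Every grade reachable from the initial
#'   grade must be covered, otherwise a configuration error is raised.
#' @param arm Arm label attached to the output (the arm enters this model
#'   only through its translated `transitions`).
#' @return A `ckd_cohort` object (see [simulate_cohort_kf()]); the
#'   `patients$slope` column is `NA` here.
#' @export
#' @examples
#' tt <- transition_table(c(G2 = 0.01, G3a = 0.02, G3b = 0.03,
#'                          G4 = 0.05, G5 = 0.05))
#' coh <- simulate_cohort_dg(ckd_parameters(), tt, n = 200, seed = 1)
#' coh
simulate_cohort_dg <- function(params, transitions,
                               arm = c("control", "intervention"),
                               n = params$cohort_size, seed = params$seed,
                               keep_trajectories = FALSE, sexes = NULL) {
  stopifnot(inherits(params, "ckd_params"))
  arm <- match.arg(arm)
  n <- as.integer(n)
  if (n < 1L) abort("`n` must be at least 1")
  .check_transitions_cover(transitions, params)
  set.seed(seed)
  if (is.null(sexes)) {
    male <- .assign_sexes(n)
  } else {
    if (length(sexes) != n || !all(sexes %in% c("male", "female"))) {
      abort("`sexes` must be length `n` with values \"male\"/\"female\"")
    }
    male <- sexes == "male"
  }
  if (inherits(transitions, "ckd_transition_matrix")) {
    sim <- .sim_dg(params, male, p_prog = NULL,
                   trans_matrix = attr(transitions, "matrix"),
                   keep_traj = keep_trajectories)
  } else {
    p_prog <- setNames(transitions$p_progress, transitions$state)
    p_prog <- unname(p_prog[ckd_states()[1:6]])
    sim <- .sim_dg(params, male, p_prog, keep_traj = keep_trajectories)
  }
  .finish_cohort("dg", arm, params, male, slope = NULL, sim, seed,
                 keep_trajectories)
}

#' Simulate a single patient under the disease grade-based model
#'
#' @inheritParams simulate_cohort_dg
#' @param sex `"male"` or `"female"`.
#' @return A one-patient `ckd_cohort` with `trajectories` filled in.
#' @export
simulate_patient_dg <- function(params, transitions, sex = "male",
                                arm = c("control", "intervention"),
                                seed = params$seed) {
  simulate_cohort_dg(params, transitions, arm = arm, n = 1L, seed = seed,
                     keep_trajectories = TRUE, sexes = sex)
}

#' @export
print.ckd_transitions <- function(x, ...) {
  cat("<ckd_transitions> per-cycle progression probabilities\n")
  print(structure(x, class = class(tibble())))
  invisible(x)
}
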