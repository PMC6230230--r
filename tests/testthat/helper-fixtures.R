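# Shared fixtures: all cohorts in tests are generated in code, seeded.

# Base case with a small default cohort for cheap runs.
small_params <- function(n = 500, ...) {
  ckd_parameters(cohort_size = n, ...)
}

# No mortality at all: isolates the kidney-function / progression dynamics.
immortal_params <- function(...) {
  ckd_parameters(mort_male_a = 0, mort_female_a = 0, mort_dialysis_a = 0,
                 ...)
}

# Hand-built trajectory table (one patient unless ids given).
traj_tbl <- function(states, alive = rep(TRUE, length(states)),
                     patient_id = 1L) {
  tibble::tibble(
    patient_id = patient_id,
    cycle = seq_along(states) - 1L,
    state = factor(states, levels = ckd_states()),
    alive = alive
  )
}
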