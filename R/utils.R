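# Internal helpers shared across modules.

# Derive a reproducible substream seed (< 2^31) from a master seed and a
# stream index. Used so each cohort in a multi-cohort run gets its own seed.
.derive_seed <- function(seed, k) {
  as.integer(((as.double(seed) %% 1e6) * 1009 + as.double(k) * 7919) %% 2147483647)
}

.assert_number <- function(x, name, lower = -Inf, upper = Inf,
                           allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && is.na(x))) {
    abort(sprintf("`%s` must be a single number", name))
  }
  if (!is.na(x) && (x < lower || x > upper)) {
    abort(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  }
  invisible(x)
}

# Per-state annual utility weights / costs as vectors indexed by state code
# (1..6 = G1..G5 predialysis, 7 = dialysis/ESRD).
.state_utilities <- function(params) {
  c(params$utility_g1, params$utility_g2, params$utility_g3a,
    params$utility_g3b, params$utility_g4, params$utility_g5,
    params$utility_dialysis)
}

.state_costs <- function(params) {
  c(params$cost_g1, params$cost_g2, params$cost_g3a, params$cost_g3b,
    params$cost_g4, params$cost_g5, params$cost_dialysis)
}

.grade_multipliers <- function(params) {
  c(params$hr_g1, params$hr_g2, params$hr_g3a, params$hr_g3b,
    params$hr_g4, params$hr_g5)
}

.n_cycles <- function(params) {
  as.integer(ceiling((params$max_age - params$initial_age) /
                       params$cycle_length - 1e-9))
}
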