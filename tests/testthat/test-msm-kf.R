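test_that("a deterministic decliner crosses the grade bands on schedule", {
  p0 <- immortal_params()
  one <- simulate_patient_kf(p0, "control", sex = "male", seed = 1,
                             slope = 2.2)
  # closed form: (73 - 7) / 2.2 = 30 years to renal replacement
  expect_equal(one$patients$time_to_esrd, 30)
  tr <- cohort_trajectories(one)
  seen <- unique(as.character(tr$state[tr$alive]))
  expect_equal(seen, c("G2", "G3a", "G3b", "G4", "G5", "ESRD"))
})

test_that("cycles to ESRD equal the ceiling of crossing time over cycle length", {
  p0 <- immortal_params()
  set.seed(99)
  slopes <- c(2.2, runif(12, 1.0, 12))
  for (s in slopes) {
    one <- simulate_patient_kf(p0, "control", sex = "female", seed = 2,
                               slope = s)
    cycles <- one$patients$time_to_esrd / p0$cycle_length
    expect_equal(cycles, ceiling(((73 - 7) / s) / 0.25 - 1e-12))
  }
})

test_that("zero decline and zero mortality leave the patient in G2 to the cap", {
  p0 <- immortal_params()
  coh <- simulate_cohort_kf(p0, "control", n = 8, seed = 3, slopes = 0,
                            keep_trajectories = TRUE)
  expect_true(all(!coh$patients$died))
  expect_true(all(!coh$patients$esrd))
  expect_true(all(coh$patients$life_years == p0$max_age))
  tr <- cohort_trajectories(coh)
  expect_true(all(as.character(tr$state) == "G2"))
  expect_true(all(tr$egfr == 73))
})

test_that("overwhelming hazard kills in the first cycle with no accrual", {
  ph <- ckd_parameters(mort_male_a = 1e9, mort_female_a = 1e9)
  coh <- simulate_cohort_kf(ph, "control", n = 10, seed = 4)
  expect_true(all(coh$patients$died))
  expect_true(all(coh$patients$life_years == ph$initial_age))
  expect_true(all(coh$patients$qaly == 0))
  expect_true(all(coh$patients$cost == 0))
})

test_that("cohorts are half male, half female, and seed-reproducible", {
  p <- small_params()
  coh <- simulate_cohort_kf(p, "control", n = 4, seed = 5)
  expect_equal(sum(coh$patients$sex == "male"), 2)
  expect_equal(sum(coh$patients$sex == "female"), 2)
  odd <- simulate_cohort_kf(p, "control", n = 5, seed = 5)
  expect_true(sum(odd$patients$sex == "male") %in% c(2, 3))

  a <- simulate_cohort_kf(p, "control", n = 300, seed = 11)
  b <- simulate_cohort_kf(p, "control", n = 300, seed = 11)
  expect_identical(a$patients, b$patients)
  c2 <- simulate_cohort_kf(p, "control", n = 300, seed = 12)
  expect_false(identical(a$patients, c2$patients))
})

test_that("sampled cohort slopes match the decline law", {
  p <- ckd_parameters()
  coh <- simulate_cohort_kf(p, "control", n = 2e4, seed = 21)
  se <- 6.5 / sqrt(2e4)
  expect_lt(abs(mean(coh$patients$slope) - 2.2), 3 * se)
  expect_true(all(coh$patients$slope > 0))
})

test_that("trajectory invariants hold: monotone decline, no resurrection", {
  p <- small_params()
  coh <- simulate_cohort_kf(p, "control", n = 60, seed = 31,
                            keep_trajectories = TRUE)
  tr <- cohort_trajectories(coh)
  by_pat <- split(tr, tr$patient_id)
  for (d in by_pat) {
    e <- d$egfr[!is.na(d$egfr)]
    expect_true(all(diff(e) <= 1e-12))
    expect_true(all(diff(as.integer(d$state)) >= 0))   # never improves
    expect_true(all(diff(d$alive) <= 0))               # alive is a prefix
    expect_equal(d$age, p$initial_age + d$cycle * p$cycle_length)
  }
})

test_that("mean age at death matches a deterministic life table", {
  # zero decline isolates G2 mortality; oracle is the cohort-level
  # recursion over the same per-cycle death probabilities
  p <- ckd_parameters()
  n_cyc <- ceiling((p$max_age - p$initial_age) / p$cycle_length)
  expect_life <- function(a, b) {
    ages <- p$initial_age + (0:(n_cyc - 1)) * p$cycle_length
    pd <- 1 - exp(-a * exp(b * ages) * p$cycle_length)
    surv <- cumprod(1 - pd)
    p$initial_age + p$cycle_length * sum(surv)
  }
  oracle <- mean(c(expect_life(p$mort_male_a, p$mort_male_b),
                   expect_life(p$mort_female_a, p$mort_female_b)))
  coh <- simulate_cohort_kf(p, "control", n = 2e4, seed = 41, slopes = 0)
  se <- sd(coh$patients$life_years) / sqrt(2e4)
  expect_lt(abs(mean(coh$patients$life_years) - oracle), 3 * se)
})

test_that("slower decline dominates renal survival at equal spread", {
  p <- ckd_parameters(decline_mean_treated = 1.3, decline_sd_treated = 6.5)
  ctl <- simulate_cohort_kf(p, "control", n = 2e4, seed = 51)
  trt <- simulate_cohort_kf(p, "intervention", n = 2e4, seed = 52)
  s_ctl <- km_survival_at(km_renal_survival(ctl), 5)
  s_trt <- km_survival_at(km_renal_survival(trt), 5)
  expect_gte(s_trt, s_ctl)
})

test_that("trajectory-based economics reproduce the on-line accrual exactly", {
  p <- small_params()
  coh <- simulate_cohort_kf(p, "control", n = 250, seed = 61,
                            keep_trajectories = TRUE)
  ec <- economics(cohort_trajectories(coh), p)
  expect_equal(ec$qaly, coh$patients$qaly, tolerance = 1e-12)
  expect_equal(ec$cost, coh$patients$cost, tolerance = 1e-12)
  expect_equal(ec$life_years, coh$patients$life_years, tolerance = 1e-12)
})
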