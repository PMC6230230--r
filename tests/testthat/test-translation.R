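test_that("hand-counted pairs give the published estimator", {
  p <- ckd_parameters()
  tr <- traj_tbl(c("G2", "G2", "G3a", "G3a"))
  tt <- estimate_transitions(tr, p)
  pvec <- setNames(tt$p_progress, tt$state)
  # one of two G2 pairs progresses; the single G3a pair does not
  expect_equal(unname(pvec["G2"]), 0.5)
  expect_equal(unname(pvec["G3a"]), 0)
  expect_equal(tt$n_pairs[tt$state == "G2"], 2L)
  expect_equal(tt$n_pairs[tt$state == "G3a"], 1L)
  # pair weighting coincides for a single patient
  tt2 <- estimate_transitions(tr, p, weighting = "pair")
  expect_equal(tt2$p_progress, tt$p_progress)
})

test_that("pairs ending in death are excluded from the denominators", {
  p <- ckd_parameters()
  tr <- traj_tbl(c("G2", "G2", "DEAD"), alive = c(TRUE, TRUE, FALSE))
  tt <- estimate_transitions(tr, p)
  expect_equal(tt$n_pairs[tt$state == "G2"], 1L)
  expect_equal(tt$p_progress[tt$state == "G2"], 0)
})

test_that("a multi-grade jump counts once as a progression from its source grade", {
  p <- ckd_parameters()
  tr <- traj_tbl(c("G2", "G4", "G4"))
  tt <- estimate_transitions(tr, p)
  expect_equal(tt$n_events[tt$state == "G2"], 1L)
  expect_equal(tt$n_pairs[tt$state == "G2"], 1L)
  expect_equal(tt$p_progress[tt$state == "G2"], 1)
  # the skipped grade was never occupied, so it needs no estimate
  expect_true(is.na(tt$p_progress[tt$state == "G3a"]))
  expect_equal(tt$p_progress[tt$state == "G4"], 0)
})

test_that("a zero-decline cohort yields zero progression for occupied grades", {
  p0 <- immortal_params()
  kf <- simulate_cohort_kf(p0, "control", n = 40, seed = 1, slopes = 0)
  tt <- estimate_transitions(kf, p0)
  expect_equal(tt$p_progress[tt$state == "G2"], 0)
  expect_true(all(is.na(tt$p_progress[tt$state %in%
                                        c("G3a", "G3b", "G4", "G5")])))
})

test_that("an occupied grade without alive-alive pairs raises a named error", {
  p <- ckd_parameters()
  # patient enters G3a and immediately dies: G3a occupied, no pair
  tr <- traj_tbl(c("G2", "G2", "G3a", "DEAD"),
                 alive = c(TRUE, TRUE, TRUE, FALSE))
  expect_error(estimate_transitions(tr, p), "G3a")
})

test_that("streaming cohort counters agree with explicit trajectory counting", {
  p <- small_params()
  coh <- simulate_cohort_kf(p, "control", n = 400, seed = 17,
                            keep_trajectories = TRUE)
  from_cohort <- estimate_transitions(coh, p)
  from_traj <- estimate_transitions(cohort_trajectories(coh), p)
  expect_equal(from_cohort$p_progress, from_traj$p_progress,
               tolerance = 1e-12)
  expect_equal(from_cohort$n_pairs, from_traj$n_pairs)
  expect_equal(from_cohort$n_events, from_traj$n_events)
  pair_cohort <- estimate_transitions(coh, p, weighting = "pair")
  pair_traj <- estimate_transitions(cohort_trajectories(coh), p,
                                    weighting = "pair")
  expect_equal(pair_cohort$p_progress, pair_traj$p_progress,
               tolerance = 1e-12)
})

test_that("degenerate slopes reproduce the analytic crossing fraction", {
  # every patient declines at exactly s: within a grade band of width w the
  # patient spends ceiling(w / (s * cycle)) cycles, exactly one of which
  # crosses out, so the per-patient estimator equals 1 / cycles-in-grade
  p0 <- immortal_params()
  s <- 3.1
  kf <- simulate_cohort_kf(p0, "control", n = 30, seed = 2, slopes = s)
  tt <- estimate_transitions(kf, p0)
  pvec <- setNames(tt$p_progress, tt$state)
  cl <- p0$cycle_length
  e_path <- 73 - s * cl * seq_len(1e4)
  cycles_g3a <- sum(e_path < 60 & e_path >= 45)
  # alive-alive pairs with source G3a = cycles spent in the band
  expect_equal(unname(pvec["G3a"]), 1 / cycles_g3a)
})

test_that("faster mean decline yields element-wise larger progression probabilities", {
  p_fast <- ckd_parameters(decline_mean = 4.4)
  p_base <- ckd_parameters()
  kf_fast <- simulate_cohort_kf(p_fast, "control", n = 2e4, seed = 3)
  kf_base <- simulate_cohort_kf(p_base, "control", n = 2e4, seed = 3)
  t_fast <- estimate_transitions(kf_fast, p_fast)
  t_base <- estimate_transitions(kf_base, p_base)
  sel <- t_fast$state %in% c("G2", "G3a", "G3b", "G4", "G5")
  se <- sqrt(t_base$p_progress * (1 - t_base$p_progress) /
               pmax(t_base$n_patients, 1))
  expect_true(all(t_fast$p_progress[sel] >=
                    t_base$p_progress[sel] - 3 * se[sel]))
})

test_that("subsampling pairs reproduces literal random sampling", {
  p <- small_params()
  coh <- simulate_cohort_kf(p, "control", n = 500, seed = 23,
                            keep_trajectories = TRUE)
  full <- estimate_transitions(coh, p)
  sub <- estimate_transitions(coh, p, subsample_fraction = 0.5, seed = 7)
  ok <- !is.na(full$p_progress) & !is.na(sub$p_progress)
  expect_true(all(abs(sub$p_progress[ok] - full$p_progress[ok]) < 0.2))
  expect_true(all(sub$n_pairs[ok] < full$n_pairs[ok]))
  sub2 <- estimate_transitions(coh, p, subsample_fraction = 0.5, seed = 7)
  expect_equal(sub$p_progress, sub2$p_progress)
})
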