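test_that("economics match hand-computed accrual on simple trajectories", {
  p <- ckd_parameters(discount_cost = 0, discount_utility = 0)
  # alive exactly one year (4 cycles) in G2, then dead
  tr <- traj_tbl(c("G2", "G2", "G2", "G2", "G2", "DEAD"),
                 alive = c(rep(TRUE, 5), FALSE))
  ec <- economics(tr, p)
  expect_equal(ec$qaly, 0.9)
  expect_equal(ec$cost, 1.7)
  expect_equal(ec$life_years, 37 + 1)
})

test_that("undiscounted QALYs with unit utility equal survival time", {
  p <- ckd_parameters(discount_cost = 0, discount_utility = 0,
                      utility_g2 = 1, utility_g3a = 1, utility_g3b = 1,
                      utility_g4 = 1, utility_g5 = 1, utility_dialysis = 1)
  coh <- simulate_cohort_kf(p, "control", n = 200, seed = 1)
  expect_equal(coh$patients$qaly,
               coh$patients$life_years - p$initial_age, tolerance = 1e-9)
})

test_that("discounted accrual follows the geometric series", {
  p <- ckd_parameters()
  # ten years in G2 at 3%: 0.9 * sum_{k=0..39} 0.25 * 1.03^(-k/4)
  tr <- traj_tbl(c(rep("G2", 41), "DEAD"), alive = c(rep(TRUE, 41), FALSE))
  oracle <- 0.9 * 0.25 * (1 - 1.03^(-10)) / (1 - 1.03^(-0.25))
  ec <- economics(tr, p)
  expect_equal(ec$qaly, oracle, tolerance = 1e-10)
  # same series for costs at the cost rate
  expect_equal(ec$cost, 1.7 * 0.25 * (1 - 1.03^(-10)) / (1 - 1.03^(-0.25)),
               tolerance = 1e-10)
})

test_that("zero discounting reduces QALYs to utility-weighted occupancy", {
  p <- ckd_parameters(discount_cost = 0, discount_utility = 0)
  coh <- simulate_cohort_kf(p, "control", n = 150, seed = 2,
                            keep_trajectories = TRUE)
  tr <- cohort_trajectories(coh)
  u <- c(G1 = 1, G2 = 0.9, G3a = 0.87, G3b = 0.85, G4 = 0.85, G5 = 0.85,
         ESRD = 0.72, DEAD = 0)
  occupancy <- tapply(
    u[as.character(tr$state)] * 0.25 * (tr$alive & tr$cycle > 0),
    tr$patient_id, sum)
  expect_equal(as.vector(occupancy[order(as.integer(names(occupancy)))]),
               coh$patients$qaly, tolerance = 1e-9)
})

test_that("V0/V1 arithmetic reproduces the published table rows", {
  t_dg <- thresholds(list(cost_mean = 286.85, qaly_mean = 19.43),
                     list(cost_mean = 199.98, qaly_mean = 20.00))
  expect_equal(t_dg$v0, 86.87, tolerance = 1e-12)
  t_kf <- thresholds(list(cost_mean = 213.42, qaly_mean = 20.34),
                     list(cost_mean = 122.99, qaly_mean = 21.12))
  expect_equal(t_kf$v0, 90.43, tolerance = 1e-12)
  # V1 from the rounded printed row: 50 * (20.00 - 19.43) + 86.87
  expect_equal(t_dg$v1, 50 * 0.57 + 86.87, tolerance = 1e-12)
  # identical arms give zero thresholds
  same <- list(cost_mean = 100, qaly_mean = 10)
  t0 <- thresholds(same, same)
  expect_equal(t0$v0, 0)
  expect_equal(t0$v1, 0)
})

test_that("the V1 - V0 identity holds to machine precision", {
  set.seed(3)
  for (i in 1:25) {
    ctl <- list(cost_mean = runif(1, 50, 400), qaly_mean = runif(1, 10, 25))
    trt <- list(cost_mean = runif(1, 50, 400), qaly_mean = runif(1, 10, 25))
    lam <- runif(1, 10, 100)
    th <- thresholds(ctl, trt, lambda = lam)
    expect_equal(th$v1 - th$v0, lam * (trt$qaly_mean - ctl$qaly_mean),
                 tolerance = 1e-12)
  }
})

test_that("the product-limit estimator matches the hand example", {
  km <- km_renal_survival(data.frame(time = c(1, 2, 3, 4),
                                     event = c(1, 0, 1, 0)))
  expect_equal(km_survival_at(km, 1), 0.75)
  expect_equal(km_survival_at(km, 3), 0.375)
  expect_equal(km$survival[1], 1)
  expect_true(all(diff(km$survival) <= 0))
})

test_that("without events the curve stays at one; without censoring it is empirical", {
  none <- km_renal_survival(data.frame(time = rep(5, 10), event = 0))
  expect_true(all(none$survival == 1))
  set.seed(4)
  tm <- round(rexp(200, 0.2), 2) + 0.01
  km <- km_renal_survival(data.frame(time = tm, event = 1))
  for (q in c(1, 3, 8)) {
    expect_equal(km_survival_at(km, q), mean(tm > q), tolerance = 1e-12)
  }
})

test_that("arm outcomes summarise a cohort coherently", {
  p <- small_params()
  coh <- simulate_cohort_kf(p, "control", n = 400, seed = 5)
  oc <- arm_outcome(coh)
  expect_equal(oc$life_years_mean, mean(coh$patients$life_years))
  expect_equal(oc$cost_sd, sd(coh$patients$cost))
  expect_gte(oc$life_years_sd, 0)
  expect_s3_class(oc$km, "ckd_km")
  expect_equal(oc$km$survival[1], 1)
  expect_true(all(diff(oc$km$survival) <= 0))
  # discounting can only shrink utility accrual
  p_nod <- ckd_parameters(discount_utility = 0)
  coh_nod <- simulate_cohort_kf(p_nod, "control", n = 400, seed = 5)
  expect_true(all(coh$patients$qaly <= coh_nod$patients$qaly + 1e-12))
})
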