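# TMDD ODE system: right-hand side, integration, observables.

p_typ <- tmdd_params()

test_that("drug-free initial conditions are a steady state of the RHS", {
  y0 <- c(0, 0, p_typ$BL_SR * p_typ$V_C, p_typ$BL_CR * p_typ$V_C, 0)
  d <- tmdd_rhs(0, y0, p_typ)[[1]]
  expect_lt(max(abs(d)), 1e-12)
})

test_that("pure absorption: depot feeds the central compartment 1:1", {
  y0 <- c(0, 0, 0, 0, 100)
  p0 <- tmdd_params(BL_SR = 1e-12, BL_CR = 1e-12) # negligible targets
  d <- tmdd_rhs(0, y0, p0)[[1]]
  expect_equal(d[1], p0$k_A * 100, tolerance = 1e-8)
  expect_equal(d[5], -p0$k_A * 100)
})

test_that("drug-free trajectory is flat over 200 days", {
  traj <- simulate_profile(p_typ, doses = NULL, times = seq(0, 200, 1))
  for (obs in list(observe_total_mab(traj), observe_total_sr(traj),
                   observe_free_ro(traj))) {
    expect_lt(diff(range(obs)) / max(abs(obs), 1), 1e-6)
  }
})

test_that("with all sinks and sources removed, totals are conserved", {
  eps <- 1e-12
  p0 <- tmdd_params(CL_A = eps, CL_SR = eps, CL_C1 = eps,
                    CL_CR = eps, CL_C2 = eps)
  traj <- simulate_profile(p0, dose_regimen(1, 0, 70), times = seq(0, 56, 0.5))
  tot_ab <- traj$A1 + traj$A2 + traj$A5
  tot_sr <- traj$A3
  tot_cr <- traj$A4
  expect_lt(diff(range(tot_ab)) / max(tot_ab), 1e-6)
  expect_lt(diff(range(tot_sr)) / max(tot_sr), 1e-6)
  expect_lt(diff(range(tot_cr)) / max(tot_cr), 1e-6)
})

test_that("compiled and R right-hand sides produce the same trajectories", {
  doses <- dose_regimen(3, c(0, 14, 28), 70)
  times <- seq(0, 42, 0.5)
  trC <- simulate_profile(p_typ, doses, times = times)
  trR <- simulate_profile(p_typ, doses, times = times, use_compiled = FALSE)
  for (col in c("A1", "A2", "A3", "A4", "A5", "FCR")) {
    expect_lt(max(abs(trC[[col]] - trR[[col]])) / max(abs(trR[[col]])), 1e-6)
  }
})

test_that("pre-dose observables sit at their baselines", {
  traj <- simulate_profile(p_typ, dose_regimen(1, 1, 70),
                           times = seq(0, 28, 0.5))
  expect_equal(observe_total_mab(traj)[1], 0)
  expect_equal(observe_free_ro(traj)[1], 100)
  expect_equal(observe_total_sr(traj)[1], 14, tolerance = 1e-6)
})

test_that("saturating antibody drives free receptor occupancy to zero", {
  traj <- simulate_profile(p_typ, dose_regimen(100, 0, 70),
                           times = seq(0, 7, 0.1))
  expect_lt(min(observe_free_ro(traj)), 0.1)
})

test_that("steady-state volume matches the reported total", {
  expect_equal(p_typ$V_C + p_typ$V_P, 6.38, tolerance = 1e-12)
})

test_that("trough receptor occupancy increases with dose (q2w)", {
  min_ro <- vapply(c(0.5, 1, 3, 8), function(d) {
    traj <- simulate_profile(p_typ, dose_regimen(d, seq(0, 70, 14), 70),
                             times = seq(0, 84, 0.25))
    idx <- traj$time >= 2 & traj$time <= 84
    min(100 - observe_free_ro(traj)[idx])
  }, numeric(1))
  expect_true(all(diff(min_ro) > 0))
})

test_that("near-maximal occupancy is reached within every q2w interval at 3 mg/kg", {
  traj <- simulate_profile(p_typ, dose_regimen(3, seq(0, 70, 14), 70),
                           times = seq(0, 84, 0.25))
  fr <- observe_free_ro(traj)
  for (k in 1:6) {
    idx <- traj$time >= (k - 1) * 14 & traj$time <= k * 14
    expect_lt(min(fr[idx]), 2) # free RO dips below 2% in each interval
  }
})

test_that("free antibody falls below the cellular receptor pool 4-12 days post dose", {
  # at 1 mg/kg q2w the cellular-receptor pathway dominates elimination:
  # free mAb drops below the baseline receptor amount within the interval
  traj <- simulate_profile(p_typ, dose_regimen(1, seq(0, 70, 14), 70),
                           times = seq(0, 98, 0.1))
  after <- traj$time > 70.5
  cross <- traj$time[after][which(traj$FAB[after] <
                                    p_typ$BL_CR * p_typ$V_C)[1]] - 70
  expect_gte(cross, 4)
  expect_lte(cross, 12)
})

test_that("single 1 mg/kg dose: occupancy largely recovers by day 14", {
  traj <- simulate_profile(p_typ, dose_regimen(1, 0, 70),
                           times = seq(0, 14, 0.5))
  fr <- observe_free_ro(traj)
  expect_lt(fr[2], 5) # rapid near-complete occupancy after dosing
  expect_gt(fr[traj$time == 14], 50) # and substantial return by day 14
})

test_that("dose and input validation errors are raised", {
  expect_error(simulate_profile(p_typ, data.frame(time = 0, amount_mg = -5)),
               "positive")
  expect_error(simulate_profile(p_typ, times = c(1, 0)), "sorted")
  expect_error(simulate_profile(p_typ, mw_mab_kda = 0), "molecular weight")
})

test_that("trajectory export writes a tidy long table", {
  traj <- simulate_profile(p_typ, dose_regimen(1, 0, 70),
                           times = seq(0, 7, 1))
  path <- tempfile(fileext = ".csv")
  export_trajectory(traj, path)
  tab <- read.csv(path)
  expect_setequal(names(tab), c("time_day", "state", "value", "unit"))
  expect_true(all(c("A1", "free_ro", "total_mab") %in% tab$state))
  unlink(path)
})
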