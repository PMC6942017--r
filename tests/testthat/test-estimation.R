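# Estimation: DR population fit, subject-level TMDD fit, bootstrap.

test_that("noise-free data at typical values are recovered to 1e-3", {
  study <- generate_study(generator_config(seed = 1, zero_noise = TRUE),
                          streams = "tcell")
  fit <- fit_dr_population(study$data, "TEM", multi_start = 1,
                           estimate_variance = FALSE,
                           init_var = c(w_R0 = 0.01, w_Emax = 0.01,
                                        sigma = 0.01))
  truth <- c(63.1, 0.0665, 0.715, 0.353)
  est <- unlist(fit$estimates[c("R0", "k_out", "E_max", "ED50")])
  expect_rel_equal(est, truth, 1e-3)
})

test_that("a full stochastic trial is fit with sensible estimates", {
  study <- generate_study(generator_config(seed = 12), streams = "tcell")
  fit <- fit_dr_population(study$data, "TEM")
  expect_gt(fit$estimates$R0, 40)
  expect_lt(fit$estimates$R0, 90)
  expect_gt(fit$estimates$E_max, 0.4)
  expect_lt(fit$estimates$E_max, 0.95)
  expect_true(is.finite(fit$objective))
  expect_equal(nrow(fit$eta), 36)
  # empirical Bayes modes should center near zero
  expect_lt(abs(mean(fit$eta[, "eta_R0"])), 0.3)
})

test_that("placebo-only data trigger an identifiability refusal", {
  study <- generate_study(generator_config(seed = 2), streams = "tcell")
  placebo <- study$data[study$data$ARM == "placebo", ]
  expect_error(fit_dr_population(placebo, "TEM"), "identifiability")
})

test_that("Emax estimation error shrinks as arms grow", {
  err_at <- function(n_active, seeds) {
    mean(vapply(seeds, function(s) {
      d <- simulate_trial(tiny_design(n_active = n_active), seed = s,
                          streams = "tcell")
      f <- fit_dr_population(d, "TEM", multi_start = 1, seed = s)
      abs(f$estimates$E_max - 0.715)
    }, numeric(1)))
  }
  expect_lt(err_at(64, 1:3), err_at(8, 1:3) + 0.02)
})

test_that("noise-free subject-level TMDD fit recovers the free parameters", {
  recs <- subject_records(tmdd_params())
  fit <- fit_subject_tmdd(recs)
  truth <- unlist(tmdd_params()[c("CL_A", "V_C", "k_A", "BL_SR")])
  expect_rel_equal(fit$estimates, truth, 0.01)
  expect_equal(fit$n_pk, 8) # day-1 pre-dose PK is zero, excluded
})

test_that("subject estimates shrink toward the typical value", {
  # generative subject at +1 SD on CL_A: the penalized estimate must land
  # between the typical and the generative value
  omega <- sqrt(log(1 + 0.425^2))
  cl_gen <- 0.999 * exp(omega)
  recs <- subject_records(tmdd_params(CL_A = cl_gen))
  fit <- fit_subject_tmdd(recs)
  expect_gt(fit$estimates[["CL_A"]], 0.999)
  expect_lt(fit$estimates[["CL_A"]], cl_gen)
})

test_that("subjects with insufficient quantifiable PK are refused", {
  recs <- subject_records(tmdd_params(), pk_days = c(1, 3, 8, 15))
  few <- recs[!(recs$STREAM == "PK" & recs$TIME > 3), ]
  expect_error(fit_subject_tmdd(few), "fewer than")
  blq <- recs
  blq$BLQ[blq$STREAM == "PK"] <- 1L # all PK below LLOQ
  expect_error(fit_subject_tmdd(blq), "fewer than")
})

test_that("bootstrap replicates are reproducible under a fixed seed", {
  d <- simulate_trial(tiny_design(), seed = 8, streams = "tcell")
  init <- list(TEM = dr_params_tem(), TREG = dr_params_treg())
  b1 <- bootstrap_dr(d, n_boot = 3, seed = 21, init = init)
  b2 <- bootstrap_dr(d, n_boot = 3, seed = 21, init = init)
  expect_identical(b1$replicates, b2$replicates)
})

test_that("the identity resample collapses the bootstrap onto the point fit", {
  d <- simulate_trial(tiny_design(), seed = 8, streams = "tcell")
  fitT <- fit_dr_population(d, "TEM")
  fitR <- fit_dr_population(d, "TREG")
  ident <- function(ids_by_arm, b) unlist(ids_by_arm, use.names = FALSE)
  boot <- bootstrap_dr(d, n_boot = 1, seed = 1,
                       init = list(TEM = fitT, TREG = fitR),
                       resample_fn = ident)
  bands <- dr_uncertainty_bands(boot, dose_grid = c(0, 3, 8))
  expect_equal(bands$lo, bands$hi) # single replicate: degenerate band
  em <- boot$replicates$E_max[boot$replicates$population == "TEM"]
  expect_equal(em, fitT$estimates$E_max, tolerance = 0.02)
})

test_that("bootstrap band covers the generating Emax and peaks near 3 mg/kg", {
  study <- generate_study(generator_config(seed = 3), streams = "tcell")
  fitT <- fit_dr_population(study$data, "TEM")
  fitR <- fit_dr_population(study$data, "TREG")
  boot <- bootstrap_dr(study$data, n_boot = 30, seed = 11,
                       init = list(TEM = fitT, TREG = fitR))
  em <- boot$replicates$E_max[boot$replicates$population == "TEM"]
  ci <- quantile(em, c(0.05, 0.95))
  expect_lte(ci[[1]], 0.715)
  expect_gte(ci[[2]], 0.715)
  bands <- dr_uncertainty_bands(boot, dose_grid = seq(0, 16, 0.25))
  ratio <- bands[bands$quantity == "ratio", ]
  peak <- ratio$dose[which.max(ratio$median)]
  expect_gt(peak, 1.5)
  expect_lt(peak, 5.5)
})
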