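# Shared fixtures and small utilities for the test suite.

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}

# Relative agreement of two complex solutions on all five outputs,
# normalised by the dominant amount so that near-zero components do not
# inflate the relative error.
complex_rel_diff <- function(a, b) {
  fields <- c("CPX1", "CPX2", "FAB", "FSR", "FCR")
  va <- unlist(a[fields])
  vb <- unlist(b[fields])
  max(abs(va - vb) / max(abs(vb), 1e-12))
}

# Log-uniform draw over [10^lo, 10^hi].
runif_log <- function(n, lo, hi) 10^runif(n, lo, hi)

# A reduced two-cohort design for fast end-to-end tests.
tiny_design <- function(n_active = 4, n_placebo = 1) {
  trial_design(cohorts = data.frame(
    arm = c("1mgkg_q2w", "8mgkg_q2w"),
    dose_mgkg = c(1, 8),
    interval = "q2w",
    n_active = n_active,
    n_placebo = n_placebo,
    n_tmdd = n_active,
    stringsAsFactors = FALSE))
}

# Minimal single-subject record set built from a noise-free profile, used
# by the subject-level estimation tests.
subject_records <- function(params, dose_mgkg = 3, weight = 70,
                            pk_days = c(1, 3, 8, 15, 29, 43, 57, 71, 85),
                            id = 1L) {
  dose_days <- c(1, 15, 29, 43, 57, 71)
  doses <- dose_regimen(dose_mgkg, dose_days, weight)
  traj <- simulate_profile(params, doses, times = c(0, pk_days))
  i <- match(pk_days, traj$time)
  obs <- function(stream, dv) {
    data.frame(ID = id, ARM = "test", TIME = pk_days, EVID = 0L, MDV = 0L,
               AMT = 0, DOSE = dose_mgkg, DOSE2WK = dose_mgkg, WT = weight,
               STREAM = stream, DV = dv, PRED = dv, BLQ = 0L)
  }
  rbind(
    data.frame(ID = id, ARM = "test", TIME = dose_days, EVID = 1L, MDV = 1L,
               AMT = dose_mgkg * weight, DOSE = dose_mgkg,
               DOSE2WK = dose_mgkg, WT = weight, STREAM = ".",
               DV = NA_real_, PRED = NA_real_, BLQ = 0L),
    obs("PK", observe_total_mab(traj)[i]),
    obs("SIL7R", observe_total_sr(traj)[i]),
    obs("FREERO", observe_free_ro(traj)[i]))
}
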