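# Population layer: IIV draws, residual error, trial simulation, pcVPC.

test_that("zero-variance IIV reproduces the typical values exactly", {
  set.seed(1)
  d <- draw_subject(tmdd_params(), iiv_spec(c(CL_A = 0, V_C = 0)), n = 3)
  for (s in d) {
    expect_identical(s$CL_A, tmdd_params()$CL_A)
    expect_identical(s$V_C, tmdd_params()$V_C)
  }
})

test_that("log-normal draws reproduce the specified CV and median", {
  set.seed(20)
  draws <- draw_subject(tmdd_params(), iiv_spec(c(CL_A = 0.425)), n = 1e5)
  cl <- vapply(draws, function(x) x$CL_A, numeric(1))
  emp_cv <- sd(cl) / mean(cl)
  expect_lt(abs(emp_cv - 0.425), 0.02 * 0.425 + 0.005)
  expect_equal(median(cl), 0.999, tolerance = 0.01) # log-normal median
})

test_that("invalid covariance and names are rejected", {
  expect_error(iiv_spec(c(a = 0.1, b = 0.1),
                        corr = matrix(c(1, 2, 2, 1), 2)), "positive semi")
  expect_error(draw_subject(tmdd_params(), iiv_spec(c(nope = 0.1))),
               "not in parameter set")
})

test_that("residual error models behave as specified", {
  set.seed(3)
  expect_identical(as.numeric(apply_residual(c(10, 20), 0, 0)), c(10, 20))
  # proportional sigma 0.434 on a prediction of 1000: SD of replicates ~ 434
  reps <- apply_residual(rep(1000, 2e4), prop = 0.434)
  expect_equal(sd(reps), 434, tolerance = 0.05)
  # additive error can push a small prediction below zero: clamped + flagged
  set.seed(4)
  out <- apply_residual(rep(1, 500), add = 18.2)
  expect_true(any(attr(out, "clamped")))
  expect_true(all(out >= 0))
})

test_that("simulated PK observation counts per arm match the study table", {
  d <- simulate_trial(seed = 1)
  counts <- tapply(d$EVID == 0 & d$STREAM == "PK", d$ARM, sum)
  expected <- c("1mgkg_q2w" = 91, "3mgkg_q2w" = 150,
                "8mgkg_q2w" = 149, "6mgkg_q1w" = 84)
  for (arm in names(expected)) {
    expect_gt(counts[[arm]], 0.8 * expected[[arm]])
    expect_lt(counts[[arm]], 1.2 * expected[[arm]])
  }
})

test_that("placebo subjects carry only T-cell rows, fluctuating at baseline", {
  d <- simulate_trial(seed = 2)
  pl <- d[d$ARM == "placebo", ]
  expect_true(all(pl$STREAM %in% c("TEM", "TREG")))
  expect_true(all(pl$EVID == 0))
  tem <- pl$DV[pl$STREAM == "TEM"]
  expect_gt(mean(tem), 63.1 * 0.5)
  expect_lt(mean(tem), 63.1 * 1.7)
})

test_that("a fixed seed reproduces the dataset bit for bit", {
  d1 <- simulate_trial(seed = 33)
  d2 <- simulate_trial(seed = 33)
  expect_identical(d1, d2)
  d3 <- simulate_trial(seed = 34)
  expect_false(identical(d1$DV, d3$DV))
})

test_that("simulated baselines agree with the study's summary statistics", {
  d <- simulate_trial(seed = 6)
  base_sr <- d$DV[d$STREAM == "SIL7R" & d$TIME == 1]
  expect_equal(mean(base_sr), 14, tolerance = 0.15)
  expect_gt(sd(base_sr) / mean(base_sr), 0.20) # between-subject CV ~35-39%
  expect_lt(sd(base_sr) / mean(base_sr), 0.55)
  base_tem <- d$DV[d$STREAM == "TEM" & d$TIME == 1]
  expect_gt(mean(base_tem), 45)
  expect_lt(mean(base_tem), 110)
  base_trg <- d$DV[d$STREAM == "TREG" & d$TIME == 1]
  expect_equal(mean(base_trg), 50.3, tolerance = 0.2)
})

test_that("BLQ flags mark PK values below the LLOQ", {
  d <- simulate_trial(seed = 9)
  pk <- d[d$STREAM == "PK", ]
  expect_true(all(pk$DV[pk$BLQ == 1] < 75))
  expect_true(all(pk$DV[pk$BLQ == 0] >= 75))
  expect_gt(sum(pk$BLQ), 0) # early/late samples at 1 mg/kg fall below LLOQ
})

test_that("prediction correction is the identity when PRED is constant in a bin", {
  base <- data.frame(ID = rep(1:20, 2), ARM = "x",
                     TIME = rep(c(1, 8), each = 20),
                     EVID = 0L, MDV = 0L, AMT = 0, DOSE = 1, DOSE2WK = 1,
                     WT = 70, STREAM = "PK",
                     DV = NA_real_, PRED = rep(c(100, 50), each = 20),
                     BLQ = 0L)
  gen <- function(seed) {
    set.seed(seed)
    base$DV <- base$PRED * exp(rnorm(nrow(base), 0, 0.2))
    base
  }
  obs <- gen(1)
  v <- pcvpc(obs, function(i) gen(100 + i), n_sim = 20, stream = "PK")
  med <- v[v$percentile == "p50", ]
  raw_med <- tapply(obs$DV, obs$TIME, median)
  expect_equal(med$obs, as.numeric(raw_med), tolerance = 1e-12)
})

test_that("pcVPC is self-consistent when data come from the simulated model", {
  design <- tiny_design()
  d <- simulate_trial(design, seed = 42)
  v <- pcvpc(d, function(i) simulate_trial(design, seed = 4200 + i),
             n_sim = 25, stream = "TEM")
  inside <- mean(v$obs >= v$lo & v$obs <= v$hi)
  # the band is a nominal 80% interval per (bin, percentile), so the
  # within-band fraction should sit near 0.8, not at 1
  expect_gt(inside, 0.6)
  expect_lte(inside, 1)
})

test_that("a single replicate collapses the band onto that replicate", {
  design <- tiny_design(n_active = 2, n_placebo = 1)
  d <- simulate_trial(design, seed = 5, streams = "tcell")
  v <- pcvpc(d, function(i) simulate_trial(design, seed = 77,
                                           streams = "tcell"),
             n_sim = 1, stream = "TEM")
  expect_equal(v$lo, v$hi)
})
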