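#' Right-hand side of the TMDD ODE system (reference R implementation)
#'
#' Five states, all amounts in nmol: total central antibody `A1`, peripheral
#' free antibody `A2`, total soluble receptor `A3`, total cellular receptor
#' `A4`, and the subcutaneous depot `A5`. The free/bound split is obtained
#' at every evaluation from [solve_complex_pair()]; receptor synthesis
#' enters as the zero-order rates `k_syn1`, `k_syn2`.
#'
#' \deqn{dA_1/dt = k_A A_5 + Q(A_2/V_P - FAB/V_C) - (CL_A/V_C)FAB -
#'       (CL_{C1}/V_C)CPX_1 - (CL_{C2}/V_C)CPX_2}
#' \deqn{dA_2/dt = Q(FAB/V_C - A_2/V_P)}
#' \deqn{dA_3/dt = k_{syn1} - (CL_{SR}/V_C)FSR - (CL_{C1}/V_C)CPX_1}
#' \deqn{dA_4/dt = k_{syn2} - (CL_{CR}/V_C)FCR - (CL_{C2}/V_C)CPX_2}
#' \deqn{dA_5/dt = -k_A A_5}
#'
#' A compiled C translation of this function (sharing the same QE solution)
#' is what [simulate_profile()] integrates by default; this R version is the
#' readable reference and is cross-checked against the C version in the
#' test suite.
#'
#' @param t time (day); unused (the system is autonomous) but required by
#'   the deSolve calling convention.
#' @param state numeric vector `c(A1, A2, A3, A4, A5)` (nmol); small
#'   negative excursions from the integrator are clamped to zero.
#' @param params a [tmdd_params()] object.
#' @return A list: derivative vector, then named QE outputs `CPX1`, `CPX2`,
#'   `FAB`, `FSR`, `FCR`.
#' @export
tmdd_rhs <- function(t, state, params) {
  y <- pmax(unname(state), 0)
  p <- params
  s <- solve_complex_pair(y[1], y[3], y[4], p$KD1, p$KD2, p$V_C)
  dA1 <- p$k_A * y[5] + p$Q * (state[[2]] / p$V_P - s$FAB / p$V_C) -
    p$CL_A / p$V_C * s$FAB - p$CL_C1 / p$V_C * s$CPX1 - p$CL_C2 / p$V_C * s$CPX2
  dA2 <- p$Q * (s$FAB / p$V_C - state[[2]] / p$V_P)
  dA3 <- p$k_syn1 - p$CL_SR / p$V_C * s$FSR - p$CL_C1 / p$V_C * s$CPX1
  dA4 <- p$k_syn2 - p$CL_CR / p$V_C * s$FCR - p$CL_C2 / p$V_C * s$CPX2
  dA5 <- -p$k_A * y[5]
  list(c(dA1, dA2, dA3, dA4, dA5),
       CPX1 = unname(s$CPX1), CPX2 = unname(s$CPX2), FAB = unname(s$FAB),
       FSR = unname(s$FSR), FCR = unname(s$FCR))
}

#' Build a subcutaneous dose regimen
#'
#' @param dose_mgkg dose level (mg/kg).
#' @param days dosing days.
#' @param weight_kg body weight (kg).
#' @return `data.frame` with columns `time` (day) and `amount_mg`.
#' @examples
#' dose_regimen(3, seq(0, 70, by = 14), 70) # 3 mg/kg q2w x 6
#' @export
dose_regimen <- function(dose_mgkg, days, weight_kg = 70) {
  stopifnot(dose_mgkg > 0, weight_kg > 0, all(days >= 0))
  data.frame(time = as.numeric(days), amount_mg = dose_mgkg * weight_kg)
}

#' Simulate a concentration/occupancy profile under SC dosing
#'
#' Integrates the five-state QE-TMDD system with `lsoda` (stiff-capable;
#' the QE algebra makes the right-hand side locally stiff near receptor
#' saturation). Doses enter the depot as impulse events of
#' `amount_mg * 1000 / mw_mab_kda * F_SC` nmol, i.e. bioavailability is
#' applied to the absorbed amount. Initial conditions are the drug-free
#' steady state: `A3 = BL_SR * V_C`, `A4 = BL_CR * V_C`, all else zero.
#'
#' @param params a [tmdd_params()] object.
#' @param doses `data.frame` with columns `time` (day) and `amount_mg`
#'   (absolute mg), e.g. from [dose_regimen()]. May be `NULL` or empty for a
#'   drug-free run.
#' @param times output time grid (days), starting at or after 0.
#' @param mw_mab_kda antibody molecular weight (kDa).
#' @param use_compiled integrate the compiled C right-hand side (default)
#'   or the R reference [tmdd_rhs()].
#' @param rtol,atol integrator tolerances (relative; absolute in nmol).
#' @return Object of class `tmdd_trajectory`: a `data.frame` with `time`,
#'   the five state amounts, and the QE outputs `CPX1`, `CPX2`, `FAB`,
#'   `FSR`, `FCR`; the parameter set and molecular weight are attached as
#'   attributes.
#' @examples
#' p <- tmdd_params()
#' traj <- simulate_profile(p, dose_regimen(1, 0, 70), times = seq(0, 28, 0.5))
#' observe_free_ro(traj)[traj$time == 14] # free receptor occupancy at day 14
#' @export
simulate_profile <- function(params, doses = NULL,
                             times = seq(0, 98, by = 0.25),
                             mw_mab_kda = MW_MAB_KDA,
                             use_compiled = TRUE,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "tmdd_params"))
  if (is.unsorted(times, strictly = FALSE)) stop("times must be sorted")
  if (mw_mab_kda <= 0) stop("molecular weight must be positive")

  y0 <- c(A1 = 0, A2 = 0,
          A3 = params$BL_SR * params$V_C,
          A4 = params$BL_CR * params$V_C,
          A5 = 0)

  has_doses <- !is.null(doses) && nrow(doses) > 0
  events <- NULL
  if (has_doses) {
    if (!all(c("time", "amount_mg") %in% names(doses))) {
      stop("doses must have columns 'time' and 'amount_mg'")
    }
    if (any(doses$amount_mg <= 0) || any(doses$time < 0)) {
      stop("dose amounts must be positive and times non-negative")
    }
    amt_nmol <- doses$amount_mg * 1000 / mw_mab_kda * params$F_SC
    # a dose at exactly the start goes into the initial depot
    at_start <- doses$time <= times[1]
    y0[["A5"]] <- y0[["A5"]] + sum(amt_nmol[at_start])
    if (any(!at_start)) {
      events <- list(data = data.frame(var = "A5",
                                       time = doses$time[!at_start],
                                       value = amt_nmol[!at_start],
                                       method = "add"))
      times <- sort(unique(c(times, doses$time[!at_start])))
    }
  }

  outnames <- c("CPX1", "CPX2", "FAB", "FSR", "FCR")
  if (use_compiled) {
    pvec <- unlist(params[c("CL_A", "V_C", "V_P", "Q", "k_A", "CL_SR",
                            "CL_C1", "KD1", "CL_CR", "CL_C2", "KD2",
                            "k_syn1", "k_syn2")])
    out <- deSolve::lsoda(y0, times, func = "il7r_derivs", parms = pvec,
                          dllname = "il7rpkpd", initfunc = "il7r_initmod",
                          nout = 5, outnames = outnames,
                          events = events, rtol = rtol, atol = atol)
  } else {
    out <- deSolve::lsoda(y0, times, func = tmdd_rhs, parms = params,
                          events = events, rtol = rtol, atol = atol)
  }
  if (attr(out, "istate")[1] < 0) {
    stop("ODE solver failed; params: ",
         paste(sprintf("%s=%.4g", names(unlist(params)), unlist(params)),
               collapse = ", "))
  }
  traj <- as.data.frame(out)
  names(traj) <- c("time", "A1", "A2", "A3", "A4", "A5", outnames)
  structure(traj, params = params, mw_mab_kda = mw_mab_kda,
            class = c("tmdd_trajectory", "data.frame"))
}

#' TMDD model observables
#'
#' The three observation streams of the PK/target-engagement model:
#' total (free + bound) serum antibody, total (free + bound) soluble
#' receptor -- both as mass concentrations -- and free receptor occupancy on
#' T cells as a percentage of the pre-dose baseline
#' (`100 * FCR(t) / (BL_CR * V_C)`). Setting
#' `reference = "instantaneous"` normalises instead by the current total
#' cellular receptor `A4(t)`.
#'
#' @param traj a `tmdd_trajectory` from [simulate_profile()].
#' @param mw_sr_kda soluble receptor molecular weight (kDa).
#' @param reference baseline (default) or instantaneous normalisation of
#'   free receptor occupancy.
#' @return Numeric vector along `traj$time`: ng/mL for the concentrations,
#'   percent for free RO.
#' @export
observe_total_mab <- function(traj) {
  p <- attr(traj, "params")
  nM_to_ngml(traj$A1 / p$V_C, attr(traj, "mw_mab_kda"))
}

#' @rdname observe_total_mab
#' @export
observe_total_sr <- function(traj, mw_sr_kda = MW_SR_KDA) {
  p <- attr(traj, "params")
  nM_to_ngml(traj$A3 / p$V_C, mw_sr_kda)
}

#' @rdname observe_total_mab
#' @export
observe_free_ro <- function(traj, reference = c("baseline", "instantaneous")) {
  reference <- match.arg(reference)
  p <- attr(traj, "params")
  denom <- switch(reference,
                  baseline = p$BL_CR * p$V_C,
                  instantaneous = traj$A4)
  100 * traj$FCR / denom
}

#' Export a trajectory as a tidy CSV
#'
#' One row per (time, quantity): columns `time_day`, `state`, `value`,
#' `unit`. Amounts are in nmol; the three observables are appended in their
#' reporting units.
#'
#' @param traj a `tmdd_trajectory`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
export_trajectory <- function(traj, path) {
  amounts <- c("A1", "A2", "A3", "A4", "A5", "CPX1", "CPX2",
               "FAB", "FSR", "FCR")
  long <- do.call(rbind, lapply(amounts, function(s) {
    data.frame(time_day = traj$time, state = s, value = traj[[s]],
               unit = "nmol")
  }))
  obs <- rbind(
    data.frame(time_day = traj$time, state = "total_mab",
               value = observe_total_mab(traj), unit = "ng/mL"),
    data.frame(time_day = traj$time, state = "total_sil7r",
               value = observe_total_sr(traj), unit = "ng/mL"),
    data.frame(time_day = traj$time, state = "free_ro",
               value = observe_free_ro(traj), unit = "percent"))
  write.csv(rbind(long, obs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
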