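#' Inter-individual variability specification
#'
#' Log-normal IIV: individual parameters are `P_i = P_hat * exp(eta_i)`
#' with `eta_i ~ N(0, omega^2)`. Variability is specified as a coefficient
#' of variation on the natural scale; the log-scale variance is
#' `omega^2 = log(1 + CV^2)`, so that the empirical CV of draws matches the
#' specification and the median of draws is the typical value.
#'
#' Off-diagonal correlations of the random-effect vector default to zero
#' (the reference analysis estimated a full covariance block but did not
#' report the correlations; none are invented here). A correlation matrix
#' can be supplied.
#'
#' @param cv named numeric vector of fractional CVs (e.g. `0.425` for
#'   42.5\%); names must match parameter names of the model the spec is
#'   applied to.
#' @param corr optional correlation matrix (dimnames matching `names(cv)`).
#' @return Object of class `iiv_spec`.
#' @examples
#' iiv_pk_default()
#' @export
iiv_spec <- function(cv, corr = NULL) {
  stopifnot(is.numeric(cv), !is.null(names(cv)), all(cv >= 0))
  omega2 <- log(1 + cv^2)
  k <- length(cv)
  if (is.null(corr)) corr <- diag(k)
  corr <- as.matrix(corr)
  if (!isTRUE(all.equal(corr, t(corr))) ||
      any(eigen(corr, symmetric = TRUE, only.values = TRUE)$values < -1e-10)) {
    stop("correlation matrix must be symmetric positive semi-definite")
  }
  structure(list(cv = cv, omega2 = omega2, corr = corr), class = "iiv_spec")
}

#' @rdname iiv_spec
#' @export
iiv_pk_default <- function() {
  iiv_spec(c(CL_A = 0.425, V_C = 0.073, k_A = 0.313, BL_SR = 0.351))
}

#' @rdname iiv_spec
#' @export
iiv_tem_default <- function() iiv_spec(c(R0 = 0.41, E_max = 0.21))

#' @rdname iiv_spec
#' @export
iiv_treg_default <- function() iiv_spec(c(R0 = 0.33, E_max = 0.27))

#' Draw individual parameter sets
#'
#' Applies log-normal perturbations to the named elements of a parameter
#' object. Draws that violate the parameter constraints (in practice only
#' `E_max >= 1` for the dose-response model) are redrawn, truncating the
#' log-normal at the admissible boundary; with `cv = 0` every draw equals
#' the typical value exactly.
#'
#' @param typicals a [tmdd_params()] or [dr_params()] object.
#' @param iiv an [iiv_spec()]; names of `iiv$cv` must be fields of
#'   `typicals`.
#' @param n number of subjects to draw.
#' @param emax_cap upper bound enforced on individual `E_max` draws
#'   (dose-response model only).
#' @return A list of `n` parameter objects of the same class as `typicals`.
#'   Uses the current RNG state; seed outside for reproducibility.
#' @export
draw_subject <- function(typicals, iiv, n = 1, emax_cap = 0.99) {
  stopifnot(inherits(iiv, "iiv_spec"), n >= 1)
  nm <- names(iiv$cv)
  if (!all(nm %in% names(typicals))) {
    stop("iiv names not in parameter set: ",
         paste(setdiff(nm, names(typicals)), collapse = ", "))
  }
  sdv <- sqrt(iiv$omega2)
  L <- chol(iiv$corr + diag(1e-12, length(nm)))
  rebuild <- function(vals) {
    p <- unclass(typicals)
    p[nm] <- vals
    if (inherits(typicals, "dr_params")) {
      dr_params(R0 = p$R0, k_out = p$k_out, E_max = p$E_max, ED50 = p$ED50)
    } else {
      do.call(tmdd_params, c(p[c("CL_A", "V_C", "V_P", "Q", "k_A",
                                 "CL_SR", "CL_C1", "KD1", "BL_SR",
                                 "CL_CR", "CL_C2", "KD2", "BL_CR")],
                             list(F_SC = p$F_SC)))
    }
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    for (try in 1:100) {
      eta <- drop(rnorm(length(nm)) %*% L) * sdv
      vals <- unlist(typicals[nm]) * exp(eta)
      if ("E_max" %in% nm && vals[["E_max"]] > emax_cap) next
      out[[i]] <- rebuild(vals)
      break
    }
    if (is.null(out[[i]])) stop("could not draw admissible parameters")
  }
  out
}

#' Residual error specification and application
#'
#' Residual variability follows
#' `C_ij = Chat_ij * (1 + eps_p) + eps_a` with independent normal errors.
#' Defaults (interpreted as standard deviations): PK proportional 0.434,
#' soluble receptor proportional 0.150, free RO additive 18.2 percentage
#' points, TEM proportional 0.11, Treg proportional 0.061.
#'
#' @return `residual_spec()`: a named list (one entry per observation
#'   stream) with elements `prop` and `add`.
#' @export
residual_spec <- function(PK = list(prop = 0.434, add = 0),
                          SIL7R = list(prop = 0.150, add = 0),
                          FREERO = list(prop = 0, add = 18.2),
                          TEM = list(prop = 0.11, add = 0),
                          TREG = list(prop = 0.061, add = 0)) {
  spec <- list(PK = PK, SIL7R = SIL7R, FREERO = FREERO, TEM = TEM, TREG = TREG)
  for (s in names(spec)) {
    spec[[s]] <- modifyList(list(prop = 0, add = 0), spec[[s]])
    if (spec[[s]]$prop < 0 || spec[[s]]$add < 0) stop("sigma must be >= 0")
  }
  structure(spec, class = "residual_spec")
}

#' @rdname residual_spec
#' @param pred vector of model predictions.
#' @param prop,add proportional and additive error standard deviations.
#' @param PK,SIL7R,FREERO,TEM,TREG per-stream error settings
#'   (`list(prop=, add=)`).
#' @return `apply_residual()`: the perturbed observations, negative values
#'   clamped to 0 with a logical `clamped` attribute. Uses the current RNG
#'   state.
#' @export
apply_residual <- function(pred, prop = 0, add = 0) {
  stopifnot(all(is.finite(pred)), prop >= 0, add >= 0)
  n <- length(pred)
  obs <- pred * (1 + rnorm(n, 0, prop)) + rnorm(n, 0, add)
  clamped <- obs < 0
  obs[clamped] <- 0
  attr(obs, "clamped") <- clamped
  obs
}

#' Multiple-ascending-dose trial design
#'
#' Default design: four active cohorts (1, 3, 8 mg/kg every 2 weeks dosed
#' on days 1, 15, 29, 43, 57, 71; 6 mg/kg weekly dosed on days 1-78) plus
#' within-cohort placebo, 36 subjects in total. T-cell counts are sampled
#' in all subjects; the PK/soluble-receptor/receptor-occupancy streams are
#' collected in a subset of active subjects per cohort (`n_tmdd`, default
#' 5/8/8/5 = 26), mirroring the analysis populations of the reference
#' study. PK sampling includes 1 h and 4 h post-dose samples on the first
#' and last dosing day; biomarkers are time-matched to the day-level PK
#' schedule. The PK assay lower limit of quantification is 75 ng/mL.
#'
#' @param cohorts `data.frame` with columns `arm`, `dose_mgkg`, `interval`
#'   ("q2w"/"q1w"), `n_active`, `n_placebo`, `n_tmdd`.
#' @param weight_range body-weight sampling range (kg), drawn uniformly.
#' @param lloq_pk PK lower limit of quantification (ng/mL).
#' @return Object of class `trial_design`.
#' @export
trial_design <- function(cohorts = NULL, weight_range = c(50, 100),
                         lloq_pk = LLOQ_PK_NGML) {
  if (is.null(cohorts)) {
    cohorts <- data.frame(
      arm = c("1mgkg_q2w", "3mgkg_q2w", "8mgkg_q2w", "6mgkg_q1w"),
      dose_mgkg = c(1, 3, 8, 6),
      interval = c("q2w", "q2w", "q2w", "q1w"),
      n_active = c(8, 8, 8, 5),
      n_placebo = c(2, 2, 2, 1),
      n_tmdd = c(5, 8, 8, 5),
      stringsAsFactors = FALSE)
  }
  need <- c("arm", "dose_mgkg", "interval", "n_active", "n_placebo", "n_tmdd")
  stopifnot(all(need %in% names(cohorts)),
            all(cohorts$interval %in% c("q2w", "q1w")),
            all(cohorts$n_tmdd <= cohorts$n_active),
            length(weight_range) == 2, weight_range[1] > 0,
            weight_range[2] >= weight_range[1])
  hr <- function(h) h / 24
  sched <- list(
    q2w = list(
      dose_days = c(1, 15, 29, 43, 57, 71),
      pk = c(1, 1 + hr(1), 1 + hr(4), 3, 8, 15, 29, 43, 57,
             71, 71 + hr(1), 71 + hr(4), 73, 78, 85, 92, 99, 113, 127),
      sil7r = c(1, 1 + hr(1), 3, 8, 15, 29, 43, 57, 71, 78, 85, 99, 127),
      freero = c(1, 3, 8, 15, 29, 43, 57, 71, 78, 85, 99, 127),
      tcell = c(1, 3, 8, 15, 29, 43, 57, 71, 85, 99, 127)),
    q1w = list(
      dose_days = seq(1, 78, by = 7),
      pk = c(1, 1 + hr(1), 1 + hr(4), 3, 8, 15, 29, 43, 57, 71,
             78, 78 + hr(1), 78 + hr(4), 80, 85, 92, 99, 113, 127),
      sil7r = c(1, 1 + hr(1), 3, 8, 15, 29, 43, 57, 71, 80, 85, 99, 127),
      freero = c(1, 3, 8, 15, 29, 43, 57, 71, 80, 85, 99, 127),
      tcell = c(1, 3, 8, 15, 29, 43, 57, 71, 85, 99, 127)))
  structure(list(cohorts = cohorts, schedule = sched,
                 weight_range = weight_range, lloq_pk = lloq_pk),
            class = "trial_design")
}

#' Fortnightly dose intensity of a cohort
#'
#' The dose-response model is driven by dose per 2 weeks: a q2w regimen at
#' `d` mg/kg maps to `d`, a q1w regimen to `2 d` (same cumulative
#' fortnightly dose).
#'
#' @param dose_mgkg nominal dose (mg/kg).
#' @param interval `"q2w"` or `"q1w"`.
#' @return Dose intensity in mg/kg per 2 weeks.
#' @export
dose_per_2wk <- function(dose_mgkg, interval) {
  stopifnot(all(interval %in% c("q2w", "q1w")))
  ifelse(interval == "q1w", 2 * dose_mgkg, dose_mgkg)
}

#' Simulate a complete virtual trial
#'
#' Generates a long-format NONMEM-style dataset combining the TMDD model
#' (PK, total soluble receptor, free receptor occupancy) and the
#' dose-response model (TEM, Treg counts) under the statistical model:
#' log-normal IIV on `CL_A`, `V_C`, `k_A`, `BL_SR` (PK) and on `R0`,
#' `E_max` (each cell population), plus per-stream residual error. Placebo
#' subjects contribute only T-cell rows (baseline + residual noise; no
#' placebo drift term). PK observations below the LLOQ are retained and
#' flagged `BLQ = 1` (M1-style exclusion is applied at fit time, not here).
#'
#' Rows are either dose events (`EVID = 1`, `AMT` in mg, no `DV`) or
#' observations (`EVID = 0`) on one of the five streams. `PRED` holds the
#' population prediction (typical parameters, individual weight/regimen),
#' used by [pcvpc()]. `TIME` is the protocol day (first dose on day 1);
#' dose-response time is measured from the first dose.
#'
#' @param design a [trial_design()].
#' @param tmdd a [tmdd_params()] object (generative typical values).
#' @param dr a [dr_pair()] object.
#' @param iiv list with elements `pk`, `tem`, `treg`, each an
#'   [iiv_spec()]; defaults to the reference CVs. Set CVs to 0 for a
#'   noise-free population.
#' @param residual a [residual_spec()].
#' @param seed integer seed; the output is bit-identical for a fixed seed.
#' @param streams `"all"`, `"tcell"` (skip the ODE-based streams) or
#'   `"tmdd"`.
#' @param mw_mab_kda,mw_sr_kda molecular-weight constants.
#' @return `data.frame` with columns `ID, ARM, TIME, EVID, MDV, AMT, DOSE,
#'   DOSE2WK, WT, STREAM, DV, PRED, BLQ` and a `truth` attribute holding
#'   each subject's generative parameters.
#' @export
simulate_trial <- function(design = trial_design(),
                           tmdd = tmdd_params(),
                           dr = dr_pair(),
                           iiv = list(pk = iiv_pk_default(),
                                      tem = iiv_tem_default(),
                                      treg = iiv_treg_default()),
                           residual = residual_spec(),
                           seed = 1L,
                           streams = c("all", "tcell", "tmdd"),
                           mw_mab_kda = MW_MAB_KDA,
                           mw_sr_kda = MW_SR_KDA) {
  streams <- match.arg(streams)
  stopifnot(inherits(design, "trial_design"), inherits(tmdd, "tmdd_params"),
            inherits(dr, "dr_pair"), inherits(residual, "residual_spec"))
  set.seed(as.integer(seed))

  rows <- list()
  truth <- list()
  id <- 0L
  for (ci in seq_len(nrow(design$cohorts))) {
    co <- design$cohorts[ci, ]
    sch <- design$schedule[[co$interval]]
    d2w <- dose_per_2wk(co$dose_mgkg, co$interval)
    n_sub <- co$n_active + co$n_placebo
    for (si in seq_len(n_sub)) {
      id <- id + 1L
      active <- si <= co$n_active
      with_tmdd <- active && si <= co$n_tmdd && streams != "tcell"
      wt <- runif(1, design$weight_range[1], design$weight_range[2])
      arm <- if (active) co$arm else "placebo"
      sub_dose <- if (active) co$dose_mgkg else 0
      sub_d2w <- if (active) d2w else 0

      p_tem <- draw_subject(dr$tem, iiv$tem)[[1]]
      p_treg <- draw_subject(dr$treg, iiv$treg)[[1]]
      p_pk <- if (with_tmdd) draw_subject(tmdd, iiv$pk)[[1]] else tmdd

      sub_rows <- list()
      if (active) {
        sub_rows$dose <- data.frame(
          ID = id, ARM = arm, TIME = sch$dose_days, EVID = 1L, MDV = 1L,
          AMT = sub_dose * wt, DOSE = sub_dose, DOSE2WK = sub_d2w, WT = wt,
          STREAM = ".", DV = NA_real_, PRED = NA_real_, BLQ = 0L)
      }

      if (streams != "tmdd") {
        for (pop in c("TEM", "TREG")) {
          pp <- if (pop == "TEM") p_tem else p_treg
          tp <- if (pop == "TEM") dr$tem else dr$treg
          tt <- pmax(sch$tcell - 1, 0) # time since first dose
          pred_i <- dr_response(tt, sub_d2w, pp)
          pred_pop <- dr_response(tt, sub_d2w, tp)
          dv <- apply_residual(pred_i, prop = residual[[pop]]$prop,
                               add = residual[[pop]]$add)
          sub_rows[[pop]] <- data.frame(
            ID = id, ARM = arm, TIME = sch$tcell, EVID = 0L, MDV = 0L,
            AMT = 0, DOSE = sub_dose, DOSE2WK = sub_d2w, WT = wt,
            STREAM = pop, DV = as.numeric(dv), PRED = pred_pop, BLQ = 0L)
        }
      }

      if (with_tmdd) {
        obs_t <- sort(unique(c(sch$pk, sch$sil7r, sch$freero)))
        doses <- dose_regimen(co$dose_mgkg, sch$dose_days, wt)
        traj_i <- simulate_profile(p_pk, doses, times = c(0, obs_t),
                                   mw_mab_kda = mw_mab_kda)
        traj_p <- simulate_profile(tmdd, doses, times = c(0, obs_t),
                                   mw_mab_kda = mw_mab_kda)
        pick <- function(traj, fun, days, ...) {
          fun(traj, ...)[match(days, traj$time)]
        }
        pk_i <- pick(traj_i, observe_total_mab, sch$pk)
        dv_pk <- apply_residual(pk_i, prop = residual$PK$prop,
                                add = residual$PK$add)
        sub_rows$PK <- data.frame(
          ID = id, ARM = arm, TIME = sch$pk, EVID = 0L, MDV = 0L,
          AMT = 0, DOSE = sub_dose, DOSE2WK = sub_d2w, WT = wt,
          STREAM = "PK", DV = as.numeric(dv_pk),
          PRED = pick(traj_p, observe_total_mab, sch$pk),
          BLQ = as.integer(dv_pk < design$lloq_pk))

        sr_i <- pick(traj_i, observe_total_sr, sch$sil7r,
                     mw_sr_kda = mw_sr_kda)
        dv_sr <- apply_residual(sr_i, prop = residual$SIL7R$prop,
                                add = residual$SIL7R$add)
        sub_rows$SIL7R <- data.frame(
          ID = id, ARM = arm, TIME = sch$sil7r, EVID = 0L, MDV = 0L,
          AMT = 0, DOSE = sub_dose, DOSE2WK = sub_d2w, WT = wt,
          STREAM = "SIL7R", DV = as.numeric(dv_sr),
          PRED = pick(traj_p, observe_total_sr, sch$sil7r,
                      mw_sr_kda = mw_sr_kda),
          BLQ = 0L)

        ro_i <- pick(traj_i, observe_free_ro, sch$freero)
        dv_ro <- apply_residual(ro_i, prop = residual$FREERO$prop,
                                add = residual$FREERO$add)
        sub_rows$FREERO <- data.frame(
          ID = id, ARM = arm, TIME = sch$freero, EVID = 0L, MDV = 0L,
          AMT = 0, DOSE = sub_dose, DOSE2WK = sub_d2w, WT = wt,
          STREAM = "FREERO", DV = as.numeric(dv_ro),
          PRED = pick(traj_p, observe_free_ro, sch$freero),
          BLQ = 0L)
      }

      rows[[id]] <- do.call(rbind, sub_rows)
      truth[[id]] <- data.frame(
        ID = id, ARM = arm, WT = wt, DOSE2WK = sub_d2w,
        CL_A = p_pk$CL_A, V_C = p_pk$V_C, k_A = p_pk$k_A, BL_SR = p_pk$BL_SR,
        R0_TEM = p_tem$R0, EMAX_TEM = p_tem$E_max,
        R0_TREG = p_treg$R0, EMAX_TREG = p_treg$E_max)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$ID, out$TIME, out$EVID, out$STREAM), ]
  rownames(out) <- NULL
  attr(out, "truth") <- do.call(rbind, truth)
  out
}

#' Prediction-corrected visual predictive check
#'
#' For one observation stream, observations are binned by nominal sampling
#' time and prediction-corrected,
#' `pcY_ij = Y_ij * median(PRED_bin) / PRED_ij`; the empirical 10th, 50th
#' and 90th percentiles of the corrected observations are compared with
#' prediction intervals of the same percentiles computed from `n_sim`
#' simulated replicates of the trial. BLQ-flagged rows are excluded.
#'
#' @param dataset a dataset from [simulate_trial()] (or read with
#'   [read_dataset()]) containing `PRED` values.
#' @param simulate_fn function of one argument (the replicate index)
#'   returning a dataset of the same shape, e.g.
#'   `function(i) simulate_trial(design, seed = 1000 + i)`.
#' @param n_sim number of simulated replicates.
#' @param stream which observation stream to check.
#' @param probs percentiles compared (default 10/50/90).
#' @param band coverage of the simulation band around each percentile
#'   (default the 10th-90th percentile across replicates).
#' @return `data.frame` with one row per (bin, percentile): the bin time,
#'   number of observations, observed percentile `obs`, and band `lo`,
#'   `hi`. Empty bins are dropped with a warning.
#' @export
pcvpc <- function(dataset, simulate_fn, n_sim = 100,
                  stream = "PK", probs = c(0.1, 0.5, 0.9),
                  band = c(0.1, 0.9)) {
  stopifnot(is.function(simulate_fn), n_sim >= 1)

  pc_percentiles <- function(d) {
    d <- d[d$EVID == 0 & d$STREAM == stream & d$BLQ == 0 & !is.na(d$DV), ]
    if (!nrow(d)) return(NULL)
    pred <- pmax(d$PRED, 1e-9)
    med <- tapply(pred, d$TIME, median)
    pcy <- d$DV * med[as.character(d$TIME)] / pred
    agg <- tapply(pcy, d$TIME, quantile, probs = probs, names = FALSE)
    tibble_like <- data.frame(TIME = as.numeric(names(agg)),
                              n = as.integer(tapply(pcy, d$TIME, length)))
    qs <- do.call(rbind, agg)
    colnames(qs) <- paste0("p", probs * 100)
    cbind(tibble_like, qs)
  }

  obs <- pc_percentiles(dataset)
  if (is.null(obs)) stop("no usable observations for stream ", stream)
  empty <- obs$n == 0
  if (any(empty)) {
    warning("dropping empty bins at times ",
            paste(obs$TIME[empty], collapse = ", "))
    obs <- obs[!empty, ]
  }

  sims <- lapply(seq_len(n_sim), function(i) pc_percentiles(simulate_fn(i)))
  pcols <- paste0("p", probs * 100)
  out <- list()
  for (pc in pcols) {
    simmat <- vapply(sims, function(s) s[[pc]][match(obs$TIME, s$TIME)],
                     numeric(nrow(obs)))
    simmat <- matrix(simmat, nrow = nrow(obs))
    out[[pc]] <- data.frame(
      stream = stream, TIME = obs$TIME, n = obs$n, percentile = pc,
      obs = obs[[pc]],
      lo = apply(simmat, 1, quantile, probs = band[1], na.rm = TRUE),
      hi = apply(simmat, 1, quantile, probs = band[2], na.rm = TRUE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("pcvpc", "data.frame"))
}
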