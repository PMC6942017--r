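# Population estimation for the dose-response model and per-subject
# empirical-Bayes estimation for the TMDD model.
#
# The DR fit maximizes a Laplace approximation to the marginal likelihood
# of the nonlinear mixed model
#   y_ij = f(t_ij, D_i; R0 e^{eta1i}, Emax e^{eta2i}) (1 + eps_ij),
# with f the closed-form indirect-response solution, eta ~ N(0, diag(w1^2,
# w2^2)) and proportional residual error. The inner per-subject modes are
# found by a damped Newton iteration that is vectorized across subjects
# (analytic gradient and Hessian), which keeps a full population fit in the
# order of seconds.

# --- internal: data layout for the DR likelihood ------------------------

.dr_stack <- function(dataset, population) {
  d <- dataset[dataset$EVID == 0 & dataset$STREAM == population &
                 !is.na(dataset$DV) & dataset$DV > 0, ]
  if (!nrow(d)) stop("no usable ", population, " observations in dataset")
  ids <- unique(d$ID)
  idx <- match(d$ID, ids)
  list(y = d$DV, t = pmax(d$TIME - min(d$TIME), 0), idx = idx,
       n_sub = length(ids), ids = ids,
       dose = as.numeric(tapply(d$DOSE2WK, idx, function(x) x[1])))
}

# Inner step: penalized NLL, gradient and Hessian blocks at eta, all
# subjects at once. Returns list(g, g1, g2, H11, H12, H22, valid).
.dr_inner_terms <- function(eta1, eta2, st, th) {
  s <- st$dose / (th$ED50 + st$dose)          # per subject
  u <- th$E_max * exp(eta2) * s               # per subject
  b <- 1 - exp(-th$k_out * st$t)              # per obs
  ub <- u[st$idx] * b
  fac <- 1 - ub
  valid <- as.logical(tapply(fac > 1e-10, st$idx, all))
  f <- th$R0 * exp(eta1[st$idx]) * pmax(fac, 1e-12)
  r <- st$y / f
  sig2 <- th$sigma^2
  G <- 1 - r * (r - 1) / sig2
  A <- (2 * r^2 - r) / sig2
  w <- ub / pmax(fac, 1e-12)
  sum_i <- function(x) as.numeric(rowsum(x, st$idx))
  nll <- sum_i(log(th$sigma) + log(f) + (r - 1)^2 / (2 * sig2))
  g <- nll + eta1^2 / (2 * th$w1^2) + eta2^2 / (2 * th$w2^2) +
    log(th$w1) + log(th$w2)
  list(g = ifelse(valid, g, Inf),
       g1 = sum_i(G) + eta1 / th$w1^2,
       g2 = sum_i(-G * w) + eta2 / th$w2^2,
       H11 = sum_i(A) + 1 / th$w1^2,
       H12 = sum_i(-A * w),
       H22 = sum_i(A * w^2 - G * w * (1 + w)) + 1 / th$w2^2,
       valid = valid)
}

# Vectorized damped Newton for the per-subject modes.
.dr_inner_modes <- function(st, th, eta_start = NULL, max_iter = 40L) {
  n <- st$n_sub
  eta1 <- if (is.null(eta_start)) rep(0, n) else eta_start[, 1]
  eta2 <- if (is.null(eta_start)) rep(0, n) else eta_start[, 2]
  tm <- .dr_inner_terms(eta1, eta2, st, th)
  if (any(!is.finite(tm$g))) { # fall back to the prior mode
    eta1 <- rep(0, n); eta2 <- rep(0, n)
    tm <- .dr_inner_terms(eta1, eta2, st, th)
    if (any(!is.finite(tm$g))) return(NULL)
  }
  for (it in seq_len(max_iter)) {
    H11 <- tm$H11; H12 <- tm$H12; H22 <- tm$H22
    det <- H11 * H22 - H12^2
    bad <- !(det > 1e-12 & H11 > 1e-12)
    if (any(bad)) { # Levenberg ridge for non-PD subjects
      ridge <- abs(H11) + abs(H22) + 1
      H11[bad] <- H11[bad] + ridge[bad]
      H22[bad] <- H22[bad] + ridge[bad]
      det <- H11 * H22 - H12^2
    }
    d1 <- (tm$g1 * H22 - tm$g2 * H12) / det
    d2 <- (tm$g2 * H11 - tm$g1 * H12) / det
    step <- rep(1, n)
    for (half in 1:12) {
      new1 <- pmin(pmax(eta1 - step * d1, -6), 6)
      new2 <- pmin(pmax(eta2 - step * d2, -6), 6)
      tn <- .dr_inner_terms(new1, new2, st, th)
      worse <- !is.finite(tn$g) | tn$g > tm$g + 1e-12
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    keep <- is.finite(tn$g) & tn$g <= tm$g + 1e-12
    eta1[keep] <- new1[keep]
    eta2[keep] <- new2[keep]
    if (any(!keep)) {
      # Newton direction failed for some subjects (typically near the
      # positivity barrier u*b -> 1): fall back to steepest descent with
      # backtracking for those subjects only
      gnorm <- sqrt(tm$g1^2 + tm$g2^2)
      s1 <- tm$g1 / pmax(gnorm, 1e-12)
      s2 <- tm$g2 / pmax(gnorm, 1e-12)
      step <- ifelse(keep, 0, 0.25)
      for (half in 1:20) {
        new1 <- pmin(pmax(eta1 - step * s1, -6), 6)
        new2 <- pmin(pmax(eta2 - step * s2, -6), 6)
        tn <- .dr_inner_terms(new1, new2, st, th)
        worse <- !keep & (!is.finite(tn$g) | tn$g > tm$g - 1e-14)
        if (!any(worse)) break
        step[worse] <- step[worse] / 2
      }
      ok <- !keep & is.finite(tn$g) & tn$g <= tm$g
      eta1[ok] <- new1[ok]
      eta2[ok] <- new2[ok]
    }
    tm2 <- .dr_inner_terms(eta1, eta2, st, th)
    done <- max(abs(tm2$g1), abs(tm2$g2)) < 1e-7
    tm <- tm2
    if (done) break
  }
  list(eta = cbind(eta1, eta2), terms = tm,
       grad_norm = max(abs(tm$g1), abs(tm$g2)))
}

.dr_theta <- function(par) {
  list(R0 = exp(par[1]), k_out = exp(par[2]), E_max = plogis(par[3]),
       ED50 = exp(par[4]), w1 = exp(par[5]), w2 = exp(par[6]),
       sigma = exp(par[7]))
}

# Laplace marginal negative log-likelihood (up to additive constants).
# A subject whose inner Hessian is not positive definite has not reached a
# genuine mode; such evaluations are rejected (large value) rather than
# allowed to reward the optimizer with a spurious log-determinant.
.dr_marginal_nll <- function(par, st, cache) {
  th <- .dr_theta(par)
  modes <- .dr_inner_modes(st, th, eta_start = cache$eta)
  if (!is.null(modes) && modes$grad_norm > 1e-4 && !is.null(cache$eta)) {
    modes <- .dr_inner_modes(st, th, eta_start = NULL) # retry cold
  }
  if (is.null(modes) || modes$grad_norm > 1e-4) return(1e10)
  tm <- modes$terms
  det <- tm$H11 * tm$H22 - tm$H12^2
  if (any(tm$H11 <= 0 | det <= 0)) return(1e10)
  val <- sum(tm$g) + 0.5 * sum(log(det))
  if (!is.finite(val)) return(1e10)
  cache$eta <- modes$eta
  val
}

#' Fit the population dose-response model
#'
#' Maximizes a Laplace-type approximate marginal likelihood for one T-cell
#' population: closed-form indirect-response predictions, log-normal
#' inter-individual variability on `R0` and `E_max`, proportional residual
#' error. Structural parameters are optimized on transformed scales
#' (`log R0`, `log k_out`, `logit E_max`, `log ED50`, and log variance
#' components) with a quasi-Newton optimizer and `multi_start` jittered
#' starting points. The per-subject random-effect modes (empirical Bayes
#' estimates) are returned alongside the population estimates.
#'
#' Placebo subjects inform `R0`, `k_out` and the variance components;
#' without any dosed subjects `E_max`/`ED50` are unidentifiable and the fit
#' refuses to run.
#'
#' @param dataset long-format dataset from [simulate_trial()] /
#'   [generate_study()] / [read_dataset()].
#' @param population `"TEM"` or `"TREG"`.
#' @param init a [dr_params()] object used as starting values (defaults to
#'   the reference typical values of the chosen population).
#' @param estimate_variance if `FALSE`, the IIV and residual SDs are fixed
#'   at `init_var` (used for speed inside the bootstrap).
#' @param init_var named vector `c(w_R0=, w_Emax=, sigma=)` of starting
#'   (or fixed) log-normal SDs and residual SD.
#' @param multi_start number of jittered starts (the first start is
#'   `init` itself).
#' @param seed seed for the start jitter.
#' @return Object of class `dr_fit`: estimates, IIV (as \%CV), residual
#'   `sigma`, objective value, convergence flag (0 = converged), and the
#'   per-subject `eta` modes.
#' @export
fit_dr_population <- function(dataset, population = c("TEM", "TREG"),
                              init = NULL, estimate_variance = TRUE,
                              init_var = c(w_R0 = 0.35, w_Emax = 0.2,
                                           sigma = 0.1),
                              multi_start = 3L, seed = 1L) {
  population <- match.arg(population)
  st <- .dr_stack(dataset, population)
  if (all(st$dose == 0)) {
    stop("identifiability failure: no dosed subjects; E_max and ED50 ",
         "cannot be estimated from a placebo-only dataset")
  }
  if (is.null(init)) {
    init <- if (population == "TEM") dr_params_tem() else dr_params_treg()
  }
  stopifnot(inherits(init, "dr_params"))

  par0 <- c(log(init$R0), log(init$k_out), qlogis(init$E_max),
            log(init$ED50), log(init_var[["w_R0"]]),
            log(init_var[["w_Emax"]]), log(init_var[["sigma"]]))
  lower <- c(-Inf, log(1e-5), -8, log(1e-4), log(1e-4), log(1e-4), log(1e-4))
  upper <- c(Inf, log(10), 8, log(1e3), log(3), log(3), log(3))
  free <- if (estimate_variance) 1:7 else 1:4

  set.seed(as.integer(seed))
  jitters <- rbind(0, matrix(rnorm((multi_start - 1) * length(free), 0, 0.3),
                             ncol = length(free)))
  best <- NULL
  for (k in seq_len(multi_start)) {
    pk <- par0
    pk[free] <- pmin(pmax(pk[free] + jitters[k, ], lower[free]), upper[free])
    cache <- new.env(parent = emptyenv())
    cache$eta <- NULL
    obj <- function(p) {
      full <- par0
      full[free] <- p
      .dr_marginal_nll(full, st, cache)
    }
    fit <- tryCatch(
      nlminb(pk[free], obj, lower = lower[free], upper = upper[free],
             control = list(iter.max = 400, eval.max = 800,
                            rel.tol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective)) {
      best <- fit
      best$cache_eta <- cache$eta
    }
  }
  if (is.null(best)) stop("dose-response fit failed from all starts")

  parfin <- par0
  parfin[free] <- best$par
  th <- .dr_theta(parfin)
  final_modes <- .dr_inner_modes(st, th, eta_start = best$cache_eta)
  if (is.null(final_modes)) {
    stop("dose-response fit failed: no admissible random-effect modes at ",
         "the returned estimates")
  }
  eta <- final_modes$eta
  rownames(eta) <- st$ids
  colnames(eta) <- c("eta_R0", "eta_Emax")
  structure(list(
    population = population,
    estimates = dr_params(R0 = th$R0, k_out = th$k_out, E_max = th$E_max,
                          ED50 = th$ED50),
    iiv_cv = c(R0 = sqrt(exp(th$w1^2) - 1), E_max = sqrt(exp(th$w2^2) - 1)),
    sigma = th$sigma,
    objective = best$objective,
    convergence = best$convergence,
    message = best$message,
    eta = eta,
    n_subjects = st$n_sub,
    n_obs = length(st$y),
    estimate_variance = estimate_variance),
    class = "dr_fit")
}

#' @export
print.dr_fit <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("Population DR fit (%s), %d subjects, %d observations\n",
              x$population, x$n_subjects, x$n_obs))
  cat(sprintf("  R0 = %.3g cells/uL, k_out = %.4g /day, E_max = %.3g, ED50 = %.3g mg/kg/2wk\n",
              e$R0, e$k_out, e$E_max, e$ED50))
  cat(sprintf("  IIV %%CV: R0 %.1f, E_max %.1f; residual prop SD %.3g\n",
              100 * x$iiv_cv[["R0"]], 100 * x$iiv_cv[["E_max"]], x$sigma))
  cat(sprintf("  -2LL/2 (Laplace) = %.4f, convergence = %d\n",
              x$objective, x$convergence))
  invisible(x)
}

#' Per-subject empirical-Bayes TMDD parameter estimation
#'
#' Penalized least squares for one subject's PK, soluble-receptor and
#' (optionally) free-RO records: log-scale residuals for the two
#' concentration streams (weighted by the log-normal equivalents of the
#' proportional residual SDs), raw-scale residuals for free RO (weighted by
#' its additive SD), plus a log-normal shrinkage penalty
#' `sum(eta_k^2 / (2 omega_k^2))` toward the population typical values with
#' the reference IIV as penalty weights. Only `CL_A`, `V_C`, `k_A` and
#' `BL_SR` are free; all other parameters stay at their typical values.
#' BLQ-flagged PK rows are excluded (M1); a subject needs at least
#' `min_pk` quantifiable PK points.
#'
#' @param records dataset rows of a single subject (dose events plus
#'   observations).
#' @param typicals a [tmdd_params()] object (population typical values).
#' @param iiv an [iiv_spec()] giving the penalty weights for the free
#'   parameters.
#' @param residual a [residual_spec()].
#' @param use_ro include free-RO records in the objective.
#' @param min_pk minimum number of quantifiable PK observations.
#' @param mw_mab_kda,mw_sr_kda molecular-weight constants.
#' @return List: `estimates` (named vector of the four free parameters),
#'   `eta`, `objective`, `convergence`, `n_pk`.
#' @export
fit_subject_tmdd <- function(records, typicals = tmdd_params(),
                             iiv = iiv_pk_default(),
                             residual = residual_spec(),
                             use_ro = TRUE, min_pk = 4L,
                             mw_mab_kda = MW_MAB_KDA,
                             mw_sr_kda = MW_SR_KDA) {
  stopifnot(length(unique(records$ID)) == 1)
  free <- names(iiv$cv)
  pk <- records[records$EVID == 0 & records$STREAM == "PK" &
                  records$BLQ == 0 & !is.na(records$DV) & records$DV > 0, ]
  if (nrow(pk) < min_pk) {
    stop("subject has fewer than ", min_pk,
         " quantifiable PK observations; refusing to fit")
  }
  sr <- records[records$EVID == 0 & records$STREAM == "SIL7R" &
                  !is.na(records$DV) & records$DV > 0, ]
  ro <- if (use_ro) {
    records[records$EVID == 0 & records$STREAM == "FREERO" &
              !is.na(records$DV), ]
  } else records[0, ]
  dose_rows <- records[records$EVID == 1, ]
  if (!nrow(dose_rows)) stop("no dose events in subject records")
  doses <- data.frame(time = dose_rows$TIME, amount_mg = dose_rows$AMT)

  obs_t <- sort(unique(c(pk$TIME, sr$TIME, ro$TIME)))
  sd_log_pk <- sqrt(log(1 + residual$PK$prop^2))
  sd_log_sr <- sqrt(log(1 + residual$SIL7R$prop^2))
  sd_ro <- max(residual$FREERO$add, 1e-6)
  omega <- sqrt(iiv$omega2)

  objective <- function(eta) {
    p <- unclass(typicals)
    p[free] <- unlist(typicals[free]) * exp(eta)
    pars <- tmdd_params(CL_A = p$CL_A, V_C = p$V_C, V_P = p$V_P, Q = p$Q,
                        F_SC = p$F_SC, k_A = p$k_A, CL_SR = p$CL_SR,
                        CL_C1 = p$CL_C1, KD1 = p$KD1, BL_SR = p$BL_SR,
                        CL_CR = p$CL_CR, CL_C2 = p$CL_C2, KD2 = p$KD2,
                        BL_CR = p$BL_CR)
    traj <- tryCatch(
      simulate_profile(pars, doses, times = c(0, obs_t),
                       mw_mab_kda = mw_mab_kda),
      error = function(e) NULL)
    if (is.null(traj)) return(1e10)
    val <- 0
    prd <- observe_total_mab(traj)[match(pk$TIME, traj$time)]
    if (any(prd <= 0)) return(1e10)
    val <- val + sum((log(pk$DV) - log(prd))^2) / (2 * sd_log_pk^2)
    if (nrow(sr)) {
      prd <- observe_total_sr(traj, mw_sr_kda)[match(sr$TIME, traj$time)]
      if (any(prd <= 0)) return(1e10)
      val <- val + sum((log(sr$DV) - log(prd))^2) / (2 * sd_log_sr^2)
    }
    if (nrow(ro)) {
      prd <- observe_free_ro(traj)[match(ro$TIME, traj$time)]
      val <- val + sum((ro$DV - prd)^2) / (2 * sd_ro^2)
    }
    val + sum(eta^2 / (2 * omega^2))
  }

  fit <- nlminb(rep(0, length(free)), objective,
                lower = rep(-4, length(free)), upper = rep(4, length(free)),
                control = list(rel.tol = 1e-9, iter.max = 200))
  est <- unlist(typicals[free]) * exp(fit$par)
  list(estimates = setNames(est, free),
       eta = setNames(fit$par, free),
       objective = fit$objective,
       convergence = fit$convergence,
       n_pk = nrow(pk))
}

#' Nonparametric bootstrap of the dose-response models
#'
#' Resamples subjects with replacement, stratified by arm (so the dose
#' design is preserved), and refits the TEM and Treg models to each
#' replicate; both models are fit independently to the same resample so
#' that replicate-wise ratio curves can be formed. Replicates that fail to
#' converge are dropped and counted.
#'
#' @param dataset long-format dataset with both T-cell streams.
#' @param n_boot number of bootstrap replicates.
#' @param seed resampling seed.
#' @param init named list with `TEM` and `TREG` entries ([dr_params()] or
#'   `dr_fit` objects) used to initialize every replicate fit; defaults to
#'   a fit of the full dataset.
#' @param estimate_variance passed to [fit_dr_population()]; replicates
#'   default to structural parameters only, with variance components held
#'   at the full-data estimates, which is much faster.
#' @param resample_fn optional override of the resampling rule: a function
#'   `(ids_by_arm, replicate_index)` returning the vector of subject IDs in
#'   the replicate (used to test the identity resample).
#' @return Object of class `dr_bootstrap`: `replicates` data.frame (one
#'   row per replicate x population), seeds, and convergence counts.
#' @export
bootstrap_dr <- function(dataset, n_boot = 200L, seed = 1L, init = NULL,
                         estimate_variance = FALSE, resample_fn = NULL) {
  obs <- dataset[dataset$EVID == 0 & dataset$STREAM %in% c("TEM", "TREG"), ]
  sub <- unique(obs[, c("ID", "ARM")])
  ids_by_arm <- split(sub$ID, sub$ARM)

  if (is.null(init)) {
    init <- list(TEM = fit_dr_population(dataset, "TEM"),
                 TREG = fit_dr_population(dataset, "TREG"))
  }
  get_init <- function(x) if (inherits(x, "dr_fit")) x$estimates else x
  get_var <- function(x, pop) {
    if (inherits(x, "dr_fit")) {
      c(w_R0 = sqrt(log(1 + x$iiv_cv[["R0"]]^2)),
        w_Emax = sqrt(log(1 + x$iiv_cv[["E_max"]]^2)),
        sigma = x$sigma)
    } else {
      c(w_R0 = 0.35, w_Emax = 0.2, sigma = 0.1)
    }
  }

  set.seed(as.integer(seed))
  draws <- lapply(seq_len(n_boot), function(b) {
    if (is.null(resample_fn)) {
      unlist(lapply(ids_by_arm, function(v) sample(v, length(v),
                                                   replace = TRUE)),
             use.names = FALSE)
    } else {
      resample_fn(ids_by_arm, b)
    }
  })

  reps <- list()
  n_fail <- 0L
  for (b in seq_len(n_boot)) {
    pieces <- lapply(seq_along(draws[[b]]), function(k) {
      d <- dataset[dataset$ID == draws[[b]][k] & dataset$EVID == 0 &
                     dataset$STREAM %in% c("TEM", "TREG"), ]
      d$ID <- k
      d
    })
    bd <- do.call(rbind, pieces)
    for (pop in c("TEM", "TREG")) {
      fit <- tryCatch(
        fit_dr_population(bd, pop, init = get_init(init[[pop]]),
                          estimate_variance = estimate_variance,
                          init_var = get_var(init[[pop]], pop),
                          multi_start = 1L, seed = seed + b),
        error = function(e) NULL)
      if (is.null(fit) || fit$convergence != 0) {
        if (is.null(fit)) {
          n_fail <- n_fail + 1L
          next
        }
      }
      e <- fit$estimates
      reps[[length(reps) + 1L]] <- data.frame(
        rep = b, population = pop, R0 = e$R0, k_out = e$k_out,
        E_max = e$E_max, ED50 = e$ED50, convergence = fit$convergence)
    }
  }
  structure(list(replicates = do.call(rbind, reps),
                 n_boot = n_boot, seed = seed, n_failed = n_fail),
            class = "dr_bootstrap")
}

#' Bootstrap uncertainty bands for the dose-response curves
#'
#' Evaluates the steady-state TEM and Treg responses and their ratio on a
#' dose grid for every bootstrap replicate and returns percentile bands.
#'
#' @param boot a `dr_bootstrap` object with both populations.
#' @param dose_grid doses (mg/kg per 2 weeks).
#' @param probs lower/upper band percentiles (default 5th/95th).
#' @return `data.frame` with columns `dose`, `quantity` (`TEM`, `TREG`,
#'   `ratio`), `lo`, `median`, `hi`.
#' @export
dr_uncertainty_bands <- function(boot, dose_grid = seq(0, 16, by = 0.1),
                                 probs = c(0.05, 0.95)) {
  stopifnot(inherits(boot, "dr_bootstrap"))
  r <- boot$replicates
  both <- intersect(r$rep[r$population == "TEM"],
                    r$rep[r$population == "TREG"])
  if (!length(both)) stop("no replicate has both populations fitted")
  curves <- lapply(both, function(b) {
    pt <- r[r$rep == b & r$population == "TEM", ]
    pr <- r[r$rep == b & r$population == "TREG", ]
    tem <- dr_steady_state(dose_grid,
                           dr_params(pt$R0, pt$k_out, pt$E_max, pt$ED50))
    trg <- dr_steady_state(dose_grid,
                           dr_params(pr$R0, pr$k_out, pr$E_max, pr$ED50))
    cbind(TEM = tem, TREG = trg, ratio = trg / tem)
  })
  out <- list()
  for (q in c("TEM", "TREG", "ratio")) {
    m <- vapply(curves, function(cv) cv[, q], numeric(length(dose_grid)))
    m <- matrix(m, nrow = length(dose_grid))
    out[[q]] <- data.frame(
      dose = dose_grid, quantity = q,
      lo = apply(m, 1, quantile, probs = probs[1]),
      median = apply(m, 1, median),
      hi = apply(m, 1, quantile, probs = probs[2]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
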