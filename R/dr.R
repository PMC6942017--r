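#' Indirect-response dose-response model: response over time
#'
#' Closed-form solution of the turnover model in which drug dose inhibits
#' the zero-order input rate through an Emax function:
#' \deqn{R(t) = R_0\left\{e^{-k_{out}t} +
#'   \left(1 - \frac{E_{max}\,D}{ED_{50}+D}\right)(1-e^{-k_{out}t})\right\}}
#' with `R(0) = R0` and monotone approach to the steady state of
#' [dr_steady_state()]. Dose is the fortnightly dose intensity
#' (mg/kg per 2 weeks); a weekly regimen at `d` mg/kg corresponds to
#' `2 d` on this scale.
#'
#' @param t time since start of treatment (day); vectorised.
#' @param dose dose intensity (mg/kg per 2 weeks), scalar or same length
#'   as `t`.
#' @param p a [dr_params()] object.
#' @return Cell count (cells/uL).
#' @export
dr_response <- function(t, dose, p) {
  stopifnot(inherits(p, "dr_params"), all(t >= 0), all(dose >= 0))
  e <- exp(-p$k_out * t)
  inh <- 1 - p$E_max * dose / (p$ED50 + dose)
  p$R0 * (e + inh * (1 - e))
}

#' Steady-state response and Treg:TEM ratio
#'
#' `dr_steady_state()` is the closed-form limit of [dr_response()],
#' \eqn{R(\infty) = R_0 (1 - E_{max} D / (ED_{50} + D))}, strictly
#' decreasing in dose. `dr_ratio_curve()` is the ratio of regulatory to
#' effector-memory steady states; because the TEM population is far more
#' dose-sensitive (lower ED50), the ratio rises over low doses and declines
#' again as the Treg effect catches up, giving a non-monotone curve with an
#' interior maximum.
#'
#' @param dose dose intensity (mg/kg per 2 weeks); vectorised.
#' @param p a [dr_params()] object.
#' @return Cell count (cells/uL) or unitless ratio.
#' @examples
#' pair <- dr_pair()
#' dr_ratio_curve(0, pair) # predicted baseline ratio, ~0.73
#' @export
dr_steady_state <- function(dose, p) {
  stopifnot(inherits(p, "dr_params"), all(dose >= 0))
  p$R0 * (1 - p$E_max * dose / (p$ED50 + dose))
}

#' @rdname dr_steady_state
#' @param pair a [dr_pair()] object.
#' @export
dr_ratio_curve <- function(dose, pair) {
  stopifnot(inherits(pair, "dr_pair"))
  dr_steady_state(dose, pair$treg) / dr_steady_state(dose, pair$tem)
}

#' Dose maximising the steady-state Treg:TEM ratio
#'
#' Coarse grid scan (step 0.01 mg/kg/2wk) followed by golden-section
#' refinement to `tol`. If the curve is flat over the interval (e.g. both
#' populations share Emax and ED50, so the ratio is constant), the lower
#' bound is returned with a warning.
#'
#' @param pair a [dr_pair()] object.
#' @param lower,upper search interval (mg/kg per 2 weeks), within the
#'   studied range `[0, 16]`.
#' @param tol absolute refinement tolerance on the dose.
#' @return The maximising dose (mg/kg per 2 weeks).
#' @examples
#' dr_argmax_dose(dr_pair()) # ~3 mg/kg q2w
#' @export
dr_argmax_dose <- function(pair, lower = 0, upper = 16, tol = 1e-4) {
  stopifnot(inherits(pair, "dr_pair"), lower >= 0, upper <= 16, lower < upper)
  grid <- seq(lower, upper, by = 0.01)
  vals <- dr_ratio_curve(grid, pair)
  if (diff(range(vals)) < 1e-12 * max(abs(vals))) {
    warning("ratio curve is flat over the search interval; returning lower bound")
    return(lower)
  }
  i <- which.max(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- optimize(function(d) dr_ratio_curve(d, pair),
                  interval = c(lo, hi), maximum = TRUE, tol = tol)
  opt$maximum
}

#' Numerical ODE reference for the indirect-response model
#'
#' Integrates \eqn{dR/dt = k_{in}(1 - E_{max}D/(ED_{50}+D)) - k_{out}R}
#' from `R(0) = R0` and returns the solution at the requested times.
#' Exists purely to verify the closed form of [dr_response()]; it is not
#' used by any analysis path.
#'
#' @param t output times (day).
#' @param dose dose intensity (mg/kg per 2 weeks), scalar.
#' @param p a [dr_params()] object.
#' @return Cell count (cells/uL) at each `t`.
#' @export
dr_ode_reference <- function(t, dose, p) {
  stopifnot(inherits(p, "dr_params"), length(dose) == 1L, dose >= 0)
  times <- sort(unique(c(0, t)))
  inh <- 1 - p$E_max * dose / (p$ED50 + dose)
  out <- deSolve::lsoda(c(R = p$R0), times,
                        function(tt, y, parms) list(p$k_in * inh - p$k_out * y),
                        parms = NULL, rtol = 1e-10, atol = 1e-10)
  out[match(t, out[, "time"]), "R"]
}
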