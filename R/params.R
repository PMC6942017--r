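#' Structural TMDD model parameters
#'
#' Constructor for the parameter set of the two-compartment
#' quasi-equilibrium TMDD model with two receptor forms. Defaults are the
#' population typical values of the reference analysis of the anti-IL-7Ralpha
#' antibody in adults with type 1 diabetes; intercompartmental clearance
#' (`Q = 1.1` L/day) and subcutaneous bioavailability (`F = 0.5`) are the
#' values fixed from healthy-volunteer data.
#'
#' The receptor synthesis rates are not free parameters: they are forced by
#' the drug-free steady state, `k_syn1 = CL_SR * BL_SR` and
#' `k_syn2 = CL_CR * BL_CR` (nmol/day with amounts in nmol and the baseline
#' concentrations in nM), so that the system is stationary before the first
#' dose.
#'
#' @param CL_A free antibody clearance (L/day).
#' @param V_C central volume of distribution (L).
#' @param V_P peripheral volume of distribution (L).
#' @param Q intercompartmental clearance (L/day).
#' @param F_SC subcutaneous bioavailability (fraction in (0, 1]).
#' @param k_A first-order absorption rate (1/day).
#' @param CL_SR clearance of the free soluble receptor (L/day).
#' @param CL_C1 clearance of the mAb:soluble-receptor complex (L/day).
#' @param KD1 dissociation constant, mAb:soluble receptor (nM).
#' @param BL_SR baseline soluble-receptor concentration (nM).
#' @param CL_CR clearance of the free cellular receptor (L/day).
#' @param CL_C2 clearance of the mAb:cellular-receptor complex (L/day);
#'   defaults to `CL_CR` (the two are not separately identifiable).
#' @param KD2 dissociation constant, mAb:cellular receptor (nM).
#' @param BL_CR baseline cellular-receptor concentration (nM).
#' @return An object of class `tmdd_params` (named list) including the
#'   derived `k_syn1`, `k_syn2`.
#' @examples
#' p <- tmdd_params()
#' p$V_C + p$V_P # steady-state volume of distribution, ~6.4 L
#' @export
tmdd_params <- function(CL_A = 0.999, V_C = 1.10, V_P = 5.28, Q = 1.1,
                        F_SC = 0.5, k_A = 0.211,
                        CL_SR = 2.24, CL_C1 = 0.196, KD1 = 0.779, BL_SR = 0.45,
                        CL_CR = 10.4, CL_C2 = CL_CR, KD2 = 0.450, BL_CR = 1.37) {
  p <- list(CL_A = CL_A, V_C = V_C, V_P = V_P, Q = Q, F_SC = F_SC, k_A = k_A,
            CL_SR = CL_SR, CL_C1 = CL_C1, KD1 = KD1, BL_SR = BL_SR,
            CL_CR = CL_CR, CL_C2 = CL_C2, KD2 = KD2, BL_CR = BL_CR)
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                            is.finite(x) && x > 0, logical(1))]
  if (length(bad)) stop("non-positive or non-scalar parameter(s): ",
                        paste(bad, collapse = ", "))
  if (F_SC > 1) stop("F_SC must be a fraction in (0, 1]")
  p$k_syn1 <- CL_SR * BL_SR
  p$k_syn2 <- CL_CR * BL_CR
  structure(p, class = "tmdd_params")
}

#' Indirect-response dose-response parameters for one T-cell population
#'
#' Turnover model with zero-order input `k_in` inhibited by an Emax
#' function of dose and first-order loss `k_out`. The input rate is forced
#' by the baseline: `k_in = R0 * k_out` (cells/uL/day), so the drug-free
#' system sits at `R0`.
#'
#' @param R0 baseline cell count (cells/uL).
#' @param k_out first-order disappearance rate (1/day).
#' @param E_max maximum fractional inhibition of the input rate (0-1).
#' @param ED50 dose achieving half-maximal inhibition (mg/kg per 2 weeks).
#' @return Object of class `dr_params` (named list) including derived `k_in`.
#' @examples
#' dr_params_tem()$k_in # ~4.2 cells/uL/day
#' log(2) / dr_params_treg()$k_out # turnover half-life, ~22.5 days
#' @export
dr_params <- function(R0, k_out, E_max, ED50) {
  stopifnot(R0 > 0, k_out > 0, ED50 > 0)
  if (E_max <= 0 || E_max >= 1) stop("E_max must lie strictly in (0, 1)")
  structure(list(R0 = R0, k_out = k_out, E_max = E_max, ED50 = ED50,
                 k_in = R0 * k_out),
            class = "dr_params")
}

#' @rdname dr_params
#' @export
dr_params_tem <- function() dr_params(R0 = 63.1, k_out = 0.0665,
                                      E_max = 0.715, ED50 = 0.353)

#' @rdname dr_params
#' @export
dr_params_treg <- function() dr_params(R0 = 46.2, k_out = 0.0308,
                                       E_max = 0.700, ED50 = 7.06)

#' Pair of dose-response models (TEM + Treg)
#'
#' @param tem,treg `dr_params` objects for the effector-memory and
#'   regulatory populations. Defaults are the reference typical values.
#' @return Object of class `dr_pair`.
#' @export
dr_pair <- function(tem = dr_params_tem(), treg = dr_params_treg()) {
  stopifnot(inherits(tem, "dr_params"), inherits(treg, "dr_params"))
  structure(list(tem = tem, treg = treg), class = "dr_pair")
}

#' @export
print.tmdd_params <- function(x, ...) {
  cat("Quasi-equilibrium TMDD model parameters\n")
  v <- unlist(x)
  print(round(v, 4))
  cat(sprintf("Vss = V_C + V_P = %.3g L\n", x$V_C + x$V_P))
  invisible(x)
}

#' @export
print.dr_params <- function(x, ...) {
  cat(sprintf(
    "Indirect-response DR parameters: R0 = %.3g cells/uL, k_out = %.3g /day\n",
    x$R0, x$k_out))
  cat(sprintf("  E_max = %.3g, ED50 = %.3g mg/kg/2wk, k_in = %.3g cells/uL/day\n",
              x$E_max, x$ED50, x$k_in))
  invisible(x)
}
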