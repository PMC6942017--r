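#' Quasi-equilibrium binding: solve the coupled complex equations
#'
#' Given the total antibody amount `A1`, total soluble receptor `A3` and
#' total cellular receptor `A4` in the central compartment (all nmol), the
#' quasi-equilibrium approximation determines the two antibody:receptor
#' complexes algebraically. Each complex satisfies a quadratic
#' mass-action/mass-balance relation in which the *other* complex appears,
#'
#' \deqn{CPX_1 = \tfrac12\big[(K_{D1}V_C + A_1 + A_3 - CPX_2) -
#'   \sqrt{(K_{D1}V_C + A_1 + A_3 - CPX_2)^2 - 4(A_1 - CPX_2)A_3}\big]}
#'
#' and symmetrically for `CPX2` with `KD2`, `A4`. The pair is solved by a
#' damped fixed-point iteration from `CPX1 = CPX2 = 0`; if the iteration
#' fails to converge it falls back on [free_ligand_oracle()], whose scalar
#' root bracketing is unconditionally convergent for valid inputs.
#'
#' State is carried in amounts (nmol): the `KD * Vc` terms only balance
#' dimensionally when `A` and `CPX` are amounts.
#'
#' @param A1 total antibody amount in the central compartment (nmol).
#' @param A3 total soluble receptor (nmol).
#' @param A4 total cellular receptor (nmol).
#' @param KD1 dissociation constant mAb:soluble receptor (nM).
#' @param KD2 dissociation constant mAb:cellular receptor (nM).
#' @param Vc central volume (L).
#' @param tol relative convergence tolerance of the fixed-point iteration.
#' @param max_iter maximum number of fixed-point iterations.
#' @return Object of class `complex_solution`: list with `CPX1`, `CPX2`,
#'   `FAB` (free antibody), `FSR` (free soluble receptor), `FCR` (free
#'   cellular receptor), all in nmol, plus the iteration count.
#' @seealso [free_ligand_oracle()] for the independent scalar-root solution.
#' @examples
#' solve_complex_pair(A1 = 100, A3 = 0.495, A4 = 1.507,
#'                    KD1 = 0.779, KD2 = 0.450, Vc = 1.10)
#' @export
solve_complex_pair <- function(A1, A3, A4, KD1, KD2, Vc,
                               tol = 1e-12, max_iter = 200L) {
  .check_binding_inputs(A1, A3, A4, KD1, KD2, Vc)
  scale <- max(A1, A3, A4, 1e-30)

  quad_root <- function(Atot, Rtot, KDV) {
    # smaller root of x^2 - (KDV + Atot + Rtot) x + Atot*Rtot = 0
    b <- KDV + Atot + Rtot
    rad <- b * b - 4 * Atot * Rtot
    if (rad < 0) {
      if (rad < -1e-9 * b * b) {
        stop("negative radicand in QE quadratic: inconsistent binding inputs")
      }
      rad <- 0
    }
    0.5 * (b - sqrt(rad))
  }

  cpx1 <- 0
  cpx2 <- 0
  damp <- 0.7
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    new1 <- quad_root(max(A1 - cpx2, 0), A3, KD1 * Vc)
    new2 <- quad_root(max(A1 - new1, 0), A4, KD2 * Vc)
    new1 <- (1 - damp) * cpx1 + damp * new1
    new2 <- (1 - damp) * cpx2 + damp * new2
    delta <- max(abs(new1 - cpx1), abs(new2 - cpx2))
    cpx1 <- new1
    cpx2 <- new2
    if (delta <= tol * scale) {
      converged <- TRUE
      break
    }
  }

  if (!converged) {
    return(free_ligand_oracle(A1, A3, A4, KD1, KD2, Vc))
  }
  .complex_solution(A1, A3, A4, cpx1, cpx2, iter)
}

#' Independent oracle: scalar free-ligand mass balance
#'
#' Solves the single-unknown form of the quasi-equilibrium system: the free
#' antibody concentration `c` (nM) satisfies the mass balance
#' \deqn{A_1/V_c = c + c\,\frac{A_3/V_c}{K_{D1}+c} + c\,\frac{A_4/V_c}{K_{D2}+c},}
#' whose left-hand side is strictly increasing in `c`, so a bracketing root
#' search on `[0, A1/Vc]` finds the unique solution. The complexes are then
#' back-computed from the binding isotherms. Used as an independent
#' cross-check of [solve_complex_pair()] and as its fallback.
#'
#' @inheritParams solve_complex_pair
#' @return Object of class `complex_solution` (see [solve_complex_pair()]).
#' @export
free_ligand_oracle <- function(A1, A3, A4, KD1, KD2, Vc) {
  .check_binding_inputs(A1, A3, A4, KD1, KD2, Vc)
  if (A1 <= 0) {
    return(.complex_solution(A1, A3, A4, 0, 0, 0L))
  }
  a1 <- A1 / Vc
  a3 <- A3 / Vc
  a4 <- A4 / Vc
  f <- function(conc) {
    conc * (1 + a3 / (KD1 + conc) + a4 / (KD2 + conc)) - a1
  }
  if (A3 == 0 && A4 == 0) {
    conc <- a1
  } else {
    conc <- uniroot(f, lower = 0, upper = a1, tol = 1e-15 * max(a1, 1))$root
  }
  cpx1 <- A3 * conc / (KD1 + conc)
  cpx2 <- A4 * conc / (KD2 + conc)
  .complex_solution(A1, A3, A4, cpx1, cpx2, 0L)
}

.check_binding_inputs <- function(A1, A3, A4, KD1, KD2, Vc) {
  vals <- c(A1 = A1, A3 = A3, A4 = A4, KD1 = KD1, KD2 = KD2, Vc = Vc)
  if (!all(is.finite(vals))) stop("binding inputs must be finite")
  if (any(vals[c("A1", "A3", "A4")] < 0)) stop("amounts must be >= 0")
  if (KD1 <= 0 || KD2 <= 0) stop("dissociation constants must be > 0")
  if (Vc <= 0) stop("central volume must be > 0")
  invisible(TRUE)
}

.complex_solution <- function(A1, A3, A4, cpx1, cpx2, iter) {
  cpx1 <- min(max(cpx1, 0), A3, A1)
  cpx2 <- min(max(cpx2, 0), A4, A1)
  structure(list(CPX1 = cpx1, CPX2 = cpx2,
                 FAB = max(A1 - cpx1 - cpx2, 0),
                 FSR = A3 - cpx1,
                 FCR = A4 - cpx2,
                 iterations = iter),
            class = "complex_solution")
}

#' @export
print.complex_solution <- function(x, ...) {
  cat("QE complex solution (nmol):\n")
  print(round(unlist(x[c("CPX1", "CPX2", "FAB", "FSR", "FCR")]), 6))
  invisible(x)
}
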