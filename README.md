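# il7rpkpd

Mechanism-based PK/PD modelling of a subcutaneously dosed IgG1 monoclonal
antibody against the interleukin-7 receptor alpha chain (IL-7Rα), a target
of interest in type 1 diabetes because IL-7 signalling sustains the
effector-memory T cells (T<sub>EM</sub>) implicated in beta-cell
destruction. The antibody binds two forms of its target — a circulating
soluble receptor and the membrane receptor on T cells — which produces
target-mediated drug disposition (TMDD): nonlinear elimination that is
fastest at low drug concentrations, when most antibody is target-bound.

The package is written for pharmacometricians and trial statisticians who
want to simulate, diagnose and refit this class of model on
multiple-ascending-dose (MAD) trial designs without access to clinical
data: a seeded synthetic-trial generator reproduces the full statistical
structure (five observation streams, log-normal inter-individual
variability, additive/proportional residual error, LLOQ censoring), so
every stage of the analysis pipeline is testable end to end.

## Models

**Quasi-equilibrium TMDD.** Five amount states: central total antibody
A₁, peripheral antibody A₂, total soluble receptor A₃, total cellular
receptor A₄ and an SC depot A₅, with first-order absorption (k_A),
two-compartment disposition (CL_A, V_C, V_P, Q), receptor turnover
(k_syn = CL·BL at baseline) and separate elimination of the free species
and the two complexes (CL_SR, CL_CR, CL_C1, CL_C2). Binding is assumed at
quasi-equilibrium, so the complexes solve the coupled quadratics

    CPX₁ = ½[(K_D1·V_C + A₁ + A₃ − CPX₂) − √((K_D1·V_C + A₁ + A₃ − CPX₂)² − 4(A₁ − CPX₂)A₃)]

(and symmetrically for CPX₂), solved by damped fixed-point iteration with
an independent bracketing-root oracle as cross-check and fallback.
Observables: total serum antibody (ng/mL), total soluble receptor
(ng/mL), and free receptor occupancy on T cells as a percent of baseline.

**Indirect-response dose-response.** T<sub>EM</sub> and regulatory T cells
(T<sub>reg</sub>) follow turnover models whose zero-order input is
inhibited by an Emax function of the fortnightly dose D:

    R(t) = R₀·{e^(−k_out·t) + (1 − E_max·D/(ED₅₀+D))·(1 − e^(−k_out·t))}

The T<sub>EM</sub> population is ~20-fold more dose-sensitive than
T<sub>reg</sub> (ED₅₀ 0.353 vs 7.06 mg/kg/2wk), so the steady-state
T<sub>reg</sub>:T<sub>EM</sub> ratio is non-monotone in dose, with an
interior maximum — the model-based rationale for dose selection.

On top sit population simulation, prediction-corrected VPCs, a
Laplace-type marginal-likelihood fitter for the dose-response model,
per-subject empirical-Bayes PK estimation and a stratified nonparametric
bootstrap. See the methods vignette (`vignettes/il7r-pkpd-model.Rmd`) for
the statistical detail and design choices.

## Worked example

```r
library(il7rpkpd)

# Dose that maximizes the steady-state Treg:TEM ratio
pair <- dr_pair()                       # reference estimates
dr_argmax_dose(pair)                    # 3.02 mg/kg q2w
round(dr_ratio_curve(c(0, 3, 12), pair), 3)  # 0.732 1.608 1.341

# Typical-subject occupancy after a single 1 mg/kg SC dose (70 kg)
p <- tmdd_params()
traj <- simulate_profile(p, dose_regimen(1, 0, 70), times = seq(0, 14, 0.25))
round(observe_free_ro(traj)[traj$time == 14], 1)  # 70.8 (% free RO)

# Simulate a full virtual MAD trial and refit the TEM dose-response model
study <- generate_study(generator_config(seed = 1), streams = "tcell")
fit_dr_population(study$data, "TEM")
#> Population DR fit (TEM), 36 subjects, 396 observations
#>   R0 = 64.4 cells/uL, k_out = 0.06553 /day, E_max = 0.675, ED50 = 0.312 mg/kg/2wk
#>   IIV %CV: R0 43.7, E_max 19.9; residual prop SD 0.114
#>   -2LL/2 (Laplace) = 898.3887, convergence = 0
```

The ratio values say that the balance between regulatory and pathogenic
effector-memory cells roughly doubles from baseline (0.73) at ~3 mg/kg
q2w and partially reverts at higher doses; the refit shows that a single
simulated 36-subject trial recovers the generating E_max (0.715) and ED₅₀
(0.353) to within sampling error.

A thin command-line front end (`exec/il7rpkpd`) exposes
`generate`, `simulate`, `dr-curve`, `fit-dr`, `bootstrap` and `vpc`
subcommands; every run writes a JSON manifest next to its outputs.

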