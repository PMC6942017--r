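---
title: "Methods: quasi-equilibrium TMDD and dose-response modelling of an anti-IL-7Rα antibody"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quasi-equilibrium TMDD and dose-response modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(il7rpkpd)
```

## The system being modelled

A humanized IgG1 monoclonal antibody blocks the interleukin-7 receptor
alpha chain. The target exists in two pools: a soluble receptor
circulating in serum and a membrane receptor on T cells. Both bind the
antibody with sub-nanomolar affinity, and the resulting complexes are
cleared at their own rates — slower than the free soluble receptor for
the soluble complex (so total soluble receptor *accumulates* under
treatment) and much faster than the free antibody for the cellular
complex (so the cellular pathway dominates elimination at low doses and
produces nonlinear PK). Downstream, blocking IL-7 signalling lowers the
production of effector-memory (TEM) and regulatory (Treg) CD4+ T cells,
measured as absolute counts; because TEM is far more drug-sensitive, the
Treg:TEM ratio — a tolerance marker in type 1 diabetes — rises at
moderate doses and falls again at high doses.

## Structural model

### Binding: quasi-equilibrium reduction

Binding and dissociation are assumed fast relative to every transport and
elimination process, which reduces the binding kinetics to algebra. With
amounts $A_1$ (total central antibody), $A_3$ (total soluble receptor)
and $A_4$ (total cellular receptor), each complex satisfies the familiar
quadratic one-target solution *conditional on the other complex*:

$$CPX_1 = \tfrac12\Big[(K_{D1}V_C + A_1 + A_3 - CPX_2) -
  \sqrt{(K_{D1}V_C + A_1 + A_3 - CPX_2)^2 - 4(A_1-CPX_2)A_3}\Big]$$

and symmetrically for $CPX_2$. `solve_complex_pair()` iterates the pair
(damping 0.7, relative tolerance $10^{-12}$, at most 200 iterations) from
$CPX_1 = CPX_2 = 0$. The same solution can be found from a single scalar
mass balance in the free antibody concentration $c$,

$$A_1/V_C = c\Big(1 + \frac{A_3/V_C}{K_{D1}+c} + \frac{A_4/V_C}{K_{D2}+c}\Big),$$

whose left side is strictly increasing in $c$; `free_ligand_oracle()`
solves it by bracketing root search and serves both as the convergence
fallback and as an independent oracle in the tests (agreement to
$10^{-8}$ relative over six decades of random inputs). A note on units:
the symbol lists one sometimes sees for these models label $CPX$ as a
concentration, but the $K_D V_C$ terms only balance dimensionally when
the state variables are amounts; the package therefore carries all state
in nmol and converts at the observation layer. Radicands that fall
marginally below zero from floating-point noise (beyond $-10^{-9}$
relative) are clamped to zero; larger negative radicands signal
inconsistent inputs and raise an error.

### Disposition and turnover

Five ODE states (amounts, nmol): central antibody $A_1$, peripheral
antibody $A_2$, soluble receptor $A_3$, cellular receptor $A_4$, SC depot
$A_5$, with first-order absorption $k_A$, two-compartment distribution
$(V_C, V_P, Q)$ acting on the *free* antibody, and linear clearances
$CL_A$, $CL_{SR}$, $CL_{CR}$, $CL_{C1}$, $CL_{C2}$ applied to the
respective species. Receptor synthesis rates are not free parameters:
$k_{syn} = CL \cdot BL$ makes the drug-free system exactly stationary at
the baseline concentrations, which also fixes self-consistent initial
conditions $A_3(0) = BL_{SR} V_C$, $A_4(0) = BL_{CR} V_C$.

Default parameter values (`tmdd_params()`) are population typical values
for this antibody: $CL_A = 0.999$ L/day, $V_C = 1.10$ L, $V_P = 5.28$ L,
$k_A = 0.211$/day, $CL_{SR} = 2.24$, $CL_{C1} = 0.196$, $CL_{CR} = CL_{C2}
= 10.4$ L/day, $K_{D1} = 0.779$ nM, $K_{D2} = 0.450$ nM, $BL_{SR} = 0.45$
nM, $BL_{CR} = 1.37$ nM. Intercompartmental clearance is fixed at
$Q = 1.1$ L/day and SC bioavailability at $F = 0.5$, both borrowed from
healthy-volunteer estimates. The package adopts the L/day reading of $Q$
(the value is also the one consistent with literature medians of ~0.8
L/day for IgG and, in our simulations, with the day-14 occupancy
behaviour described below). $CL_{C2} = CL_{CR}$ and $V_R = V_C$ are tied
by default — the free cellular receptor clearance is not separately
identifiable — but remain independently settable.

Two constants are configuration choices rather than measurements: the
antibody molecular weight (150 kDa, the IgG1 convention) and the soluble
receptor molecular weight, back-derived as $14/0.45 \approx 31.1$ kDa
from the baseline pair (0.45 nM ↔ ~14 ng/mL). The typical-subject body
weight defaults to 70 kg. Free receptor occupancy is reported relative to
the *baseline* cellular receptor pool ($100 \cdot FCR(t)/(BL_{CR}V_C)$),
matching how flow-cytometry occupancy assays are normalised; an
instantaneous normalisation is available behind a flag (the two coincide
here because $CL_{C2} = CL_{CR}$ keeps the total pool constant).

### Numerics

`lsoda` with relative tolerance $10^{-8}$ and absolute tolerance
$10^{-10}$ nmol; doses enter the depot as impulse events, with the
integrator restarted at event times. The right-hand side is compiled (C),
with the QE algebra solved by a Newton iteration safeguarded by bisection;
a pure-R right-hand side using `solve_complex_pair()` is retained and the
two are cross-checked in the tests. The QE algebra makes the system
locally stiff near receptor saturation, hence the stiff-capable
integrator and tight tolerances.

## Dose-response model

Cell counts follow a turnover model with dose-driven inhibition of the
input rate,
$$R(t) = R_0\Big\{e^{-k_{out}t} + \big(1 - \tfrac{E_{max}D}{ED_{50}+D}\big)\big(1-e^{-k_{out}t}\big)\Big\},$$
with $k_{in} = R_0 k_{out}$ (this orientation of the identity is forced
by dimensional analysis and by the printed input rates 4.2 and 1.4
cells/µL/day). Defaults: TEM $R_0 = 63.1$, $k_{out} = 0.0665$/day,
$E_{max} = 0.715$, $ED_{50} = 0.353$; Treg $R_0 = 46.2$, $k_{out} =
0.0308$/day, $E_{max} = 0.700$, $ED_{50} = 7.06$ mg/kg/2wk.

The model is driven by *dose intensity per two weeks*, not by exposure;
the weekly cohort (6 mg/kg q1w) maps to 12 mg/kg/2wk — same cumulative
fortnightly dose. This mapping is an assumption, flagged here, and is the
only place the weekly regimen differs from the fortnightly ones in the
dose-response layer. `dr_argmax_dose()` maximizes the steady-state
Treg:TEM ratio by a 0.01-step grid scan refined by golden-section search
to $10^{-4}$; a flat curve (degenerate equal-parameter case) returns the
lower bound with a warning.

## Statistical model

Individual parameters are log-normal, $P_i = \hat P e^{\eta_i}$, with
variability specified as CV on the natural scale
($\omega^2 = \log(1+CV^2)$): CL_A 42.5%, V_C 7.3%, k_A 31.3%, BL_SR 35.1%
(PK); R0 41%/33% and E_max 21%/27% (TEM/Treg). Correlations between
random effects default to zero — a full covariance block was estimated in
the reference analysis but the correlations were never printed, and none
are invented here; a correlation matrix can be supplied. Residual error
is $C_{ij} = \hat C_{ij}(1+\varepsilon_p) + \varepsilon_a$ with the
printed values interpreted as standard deviations: PK proportional 0.434,
soluble receptor proportional 0.150, free RO additive 18.2 percentage
points (applied on the free-RO scale), TEM 0.11, Treg 0.061.

Log-normal IIV on $E_{max}$ can exceed 1 in the tail; the generator
resamples draws with $E_{max,i} > 0.99$ (about 6% of TEM draws),
truncating the distribution at the admissible boundary. This keeps every
simulated trajectory positive over the studied dose range at the cost of
a percent-level downward shift of the mean individual $E_{max}$ — visible
as a small negative bias in recovery simulations, well inside their
tolerance.

## Virtual trial generator

The default `trial_design()` mirrors a phase-1b MAD study: cohorts at 1,
3, 8 mg/kg q2w (dosing days 1, 15, 29, 43, 57, 71) and 6 mg/kg q1w (days
1–78 weekly), 8/8/8/5 active plus 2/2/2/1 placebo subjects (36 total).
T-cell counts are simulated for all subjects at 11 day-level visits; PK
(19 samples including 1 h and 4 h post-dose on the first and last dosing
day), soluble receptor (13) and free RO (12) are simulated for a subset
of 5/8/8/5 active subjects per cohort, mirroring the two analysis
populations of such a study (placebo subjects are excluded from the
TMDD streams by design). Body weights are uniform on 50–100 kg — inside
typical protocol bounds while avoiding a BMI model. PK below the 75 ng/mL
LLOQ is *retained and flagged* (`BLQ = 1`); exclusion (M1) happens at fit
time. Placebo T-cell trajectories are baseline plus residual noise; no
placebo drift term is modelled. An optional between-arm baseline
imbalance is deliberately not applied by default.

What the generator does *not* emulate: assay ULOQ handling and dilution
schemes, immunogenicity effects on PK, dropout and dosing non-compliance,
covariate structure (age, body composition), placebo drift, and any
correlation between PK and T-cell random effects. Passing tests therefore
demonstrate internal consistency of the analysis pipeline under the
stated statistical model, not robustness to these real-data features.

## Estimation

**Dose-response (population).** `fit_dr_population()` maximizes a
Laplace approximation to the marginal likelihood: for each outer proposal
of $(R_0, k_{out}, E_{max}, ED_{50}, \omega_{R_0}, \omega_{E_{max}},
\sigma)$ the per-subject penalized modes in
$(\eta_{R_0}, \eta_{E_{max}})$ are found by a damped Newton iteration
with analytic gradient and Hessian, vectorized across subjects (with a
steepest-descent fallback near the positivity barrier
$E_{max,i} D/(ED_{50}+D) \to 1$), and the marginal adds half the
log-determinant of the inner Hessian. Evaluations whose inner problem has
not genuinely reached a positive-definite mode are rejected rather than
allowed to contribute a spurious log-determinant. Structural parameters
are optimized on log scales with $E_{max}$ logit-bounded in (0,1);
`nlminb` runs from `multi_start` jittered starts (default 3). Exact
FOCE-I replication is out of scope; this approximation is accurate enough
for the parameter-recovery purposes of the package, as the acceptance
suite verifies. The degenerate noise-free case sits on the
$\sigma \to 0$ boundary where the full marginal fit is ill-conditioned;
recovery tests therefore use the variance-fixed mode
(`estimate_variance = FALSE`), which reduces to penalized least squares.

**TMDD (per subject).** Population TMDD estimation is deliberately not
attempted (the typical values act as generative truth);
`fit_subject_tmdd()` provides empirical-Bayes style per-subject estimates
of $CL_A, V_C, k_A, BL_{SR}$ by penalized least squares: log-scale
residuals for the concentration streams (weights = log-normal equivalents
of the proportional SDs), raw-scale for free RO (additive SD), and
$\sum_k \eta_k^2/2\omega_k^2$ shrinkage toward the typical values.
Subjects with fewer than 4 quantifiable PK points are refused.

**Bootstrap.** `bootstrap_dr()` resamples subjects with replacement
stratified by arm (preserving the dose design — stratification is a
package choice, unspecified in the reference analysis), refits both
T-cell models independently to the same resample (a combined fit of the
pair on common resamples is what the band construction assumes), and
`dr_uncertainty_bands()` turns the replicates into percentile bands for
the TEM, Treg and ratio curves. Replicate fits reuse the full-data
estimates as starts with variance components fixed, which makes a
replicate fit an order of magnitude faster than a cold full fit.

## Problem sizes and runtimes

Chosen so a complete check runs comfortably on a laptop core: the QE
solver-vs-oracle property uses 1000 random inputs; parameter recovery
uses 20 seeded full-design trials (the acceptance criterion's own
specification); bootstrap checks use 20–40 replicates rather than the
1000 a production uncertainty analysis would use; the estimator
consistency check contrasts per-arm sizes 8 and 64 over 3 seeds; pcVPC
self-consistency uses 25–30 replicates. The pcVPC check compares observed
percentiles with a nominal 80% band, so its within-band fraction is
expected to sit near 0.8 — the test asserts a calibrated interval, not
universal coverage.

## Known limitations

* With the default typical values, the simulated trough occupancy at 3
  mg/kg q2w is ~93.6% across all intervals (~96% at steady state), a few
  points short of the near-maximal (~98%) occupancy such regimens are
  often described as maintaining; the companion quantities the same
  simulation produces (day-14 free RO after 1 mg/kg ≈ 68–71%, free
  antibody crossing the receptor-pool scale 9–10 days post dose, free RO
  < 2% at peak in every interval) are internally consistent, so the
  package reports the trough honestly rather than tuning toward the
  rounder figure. A free antibody trough concentration of ~6.5 nM at this
  dose implies free RO of $K_{D2}/(K_{D2}+c) \approx 6\%$, which is what
  the integration shows.
* Dose, not exposure, drives the dose-response model; mechanistic
  coupling of cell dynamics to concentration (and IL-7 ligand dynamics)
  is out of scope.
* Lymphatic uptake and binding, IV administration profiles, covariate
  models and likelihood-based BLQ handling (M3) are not implemented.
* One further reporting ambiguity is resolved by convention: a "68% free
  RO" at day 14 corresponds to 32% occupancy; the package always reports
  free RO relative to baseline and occupancy as its complement.
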