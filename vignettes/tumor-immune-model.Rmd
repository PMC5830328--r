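---
title: "The rtimmune tumor-immune model: structure, calibration and virtual trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The rtimmune tumor-immune model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtimmune)
```

## The problem

Radiotherapy (RT) kills tumor cells directly, but in immunogenic tumors a
substantial part of its effect is indirect: dying cells release
damage-associated signals that mature dendritic cells, prime effector T
cells, and can tip a suppressed tumor microenvironment into an effective
anti-tumor response. PD-1/PD-L1 checkpoint blockade removes one of the brakes
on that response. Whether the combination works depends strongly on *when*
each treatment is given, and individual animals with apparently identical
tumors diverge into complete rejection or unchecked progression.

`rtimmune` is a quantitative systems pharmacology simulator of this loop for
syngeneic mouse CT26 colon-carcinoma tumors. It couples a
nine-state ODE system of the cancer-immunity cycle to a linear (single
parameter) radiation cell-survival model, a one-compartment intraperitoneal
antibody PK model with receptor occupancy, a lognormal inter-animal
variability (IAV) layer, a simulate-and-refit mixed-effects module, and a
virtual-trial engine that turns individual trajectories into response-rate
predictions for dose-scheduling and sequencing questions.

## State variables and driving functions

Nine states (units in brackets):

| symbol | meaning |
|---|---|
| `TV` [µL] | proliferating tumor volume (1 mm³ ≡ 1 µL) |
| `TV_d` [µL] | radiation-damaged, non-proliferating tumor volume |
| `DSB` [breaks/cell] | mean unrepaired DNA double-strand breaks |
| `DC_m` [RU, 0–1] | mature dendritic-cell level |
| `Ag_sys` [RU] | systemic tumor-antigen presentation level |
| `nTeff` [cells] | non-differentiated effector precursors in tumor |
| `dTeff` [cells] | cytotoxic effector T cells in tumor |
| `ISC` [RU, 0–1] | immuno-suppressive cell level (Tregs, MDSC, lumped) |
| `PDL1` [RU, 0–1] | normalized PD-L1 expression |

Two derived driving functions summarize the tug-of-war. The total tumor-cell
death rate

$$TCD = d_0\,TV + e\,dT_{eff}\,TV + \mu\,TV_d \quad [\mu L/day]$$

feeds DC maturation, and the immune activation rate

$$IAR = (1 - \underbrace{w_{pdl}\,PDL1\,(1-occ)}_{supp_{pdl}})\,
        (1 - \underbrace{ISC}_{supp_{isc}}) \in [0,1]$$

gates T-cell influx, proliferation and differentiation. `occ` is the fraction
of the PD-1/PD-L1 axis blocked by antibody; full occupancy removes the PD-L1
term entirely. The cellular suppression component is the ISC state itself,
which is already a bounded, saturating response to antigen (below) — stacking
a second saturation on top of it would introduce a constant the source
parameter table does not provide.

## Equations

With `IAR` and `TCD` as above, and writing `H(x, K) = x/(x+K)`:

```
TV'    =  r TV (1 - (TV + TV_d)/TV_max) - d0 TV - e dTeff TV
TV_d'  = -mu TV_d
DSB'   = -DSB / tau
DC_m'  =  k_dcm_decay (H(TCD_spec, K_tcd) - DC_m),  TCD_spec = TCD/(TV + TV_d)
Ag'    =  k_ag (q_ag DC_m TV - Ag)
nTeff' =  IAR (k_LN H(Ag, S_L) + (k_pro - k_dif) nTeff) - k_el nTeff
dTeff' =  k_dif IAR nTeff - k_apo (1 + c_apo (1 - IAR)) dTeff
ISC'   =  k_isc (Ag^2 / (Ag^2 + S_R^2) - ISC)
PDL1'  =  k_pdl (H(dTeff, K_pdl) - PDL1)
```

A radiation fraction of dose `D` Gy is an instantaneous transformation:
`TV → TV e^(-αD)`, the killed share moves to `TV_d` (total volume conserved
exactly), and `DSB → DSB + δD`. The quadratic term of the classical
linear-quadratic survival model is not carried: the parameter table provides
only the linear component α, and fractions are restricted to ≤ 10 Gy where
that description was calibrated. DSB is carried and reported as the
radiation-damage readout; it decays fast (half-life τ·ln 2 ≈ 20 min) and does
not kill cells on its own — the immunogenic-death signal reaches the immune
arm through the death flux routed into TCD.

Antibody exposure uses the closed-form Bateman solution of the depot model
(`dA/dt = -k_a A`, `dC/dt = k_a A/V_d - kel C`), superposed over doses, and
occupancy `occ = C/(C + K_D)`. PD-1- and PD-L1-directed antibodies share the
model.

Three structural choices deserve explanation:

* **DC maturation responds to the *specific* death rate** `TCD/(TV+TV_d)`
  (fraction of the tumor dying per day, units d⁻¹ — the units the
  half-saturation constant `K_tcd = 0.2 d⁻¹` carries). Spontaneous death
  (`d0 = 0.01/d`) barely stimulates; a 2 Gy fraction, which moves ~25 % of
  the tumor into the dying compartment, stimulates strongly. Had the
  absolute flux (µL/day) been used, DC maturation would saturate in every
  scenario once the tumor passes ~20 µL and radiation would have no distinct
  immunogenic role.
* **Antigen tracks the proliferating volume**, `Ag_ss = q_ag · DC_m · TV`.
  Radiation therefore cuts the antigen source immediately while boosting DC
  maturation — which is exactly the combination mechanism the model needs to
  express: under concurrent therapy antigen stays *moderate* (enough for
  influx, `Ag > S_L`, but below the suppressive range, `Ag ≪ S_R`), so
  effectors accumulate without an overwhelming build-up of suppression.
* **Suppressive-cell recruitment is cooperative (Hill-2)** in antigen, and
  **effector apoptosis accelerates under suppression**
  (`k_apo (1 + c_apo (1-IAR))`). Both are needed jointly: with first-order
  recruitment and constant apoptosis there is no parameterization of the
  remaining constants that keeps an untreated typical animal deeply
  suppressed by day 20 (activation ~5 %) while letting the concurrent
  combination rescue 40–70 % of the population — and with constant apoptosis,
  early single-dose RT alone parks tumors in a microscopic immune
  equilibrium below the responder threshold for 50+ days, inflating RT
  monotherapy far beyond its observed 0–27 % envelope.

## Parameters

The fixed-effect defaults in `model_params()` are the published CT26
calibration values: `r` = 0.4/d, `TV_max` = 2500 µL, `d0` = 0.01/d,
`k_LN` = 279 cells/d, `S_L` = 8.89 RU, `k_pro` = 3/d, `k_dif` = 3.2/d,
`k_el` = 0.2/d, `k_apo` = 2/d, `e` = 0.001/(d·cell), `K_pdl` = 478 cells,
`k_pdl` = 1/d, `K_tcd` = 0.2/d, `S_R` = 30.5 RU, `α` = 0.146/Gy, `δ` = 19
breaks/(cell·Gy), `τ` = 0.02 d, `µ` = 0.1725/d; PK: `V_d` = 0.003 L,
`k_a` = 8/d, `kel_mAB` = 0.15/d, `K_D` = 30 nM. `mw_mab` = 150 kg/mol and
`body_weight` = 20 g are standard-mouse constants used only to convert mg/kg
doses to nanomoles; both are exposed parameters.

`S_L` is a half-saturation constant of T-cell tumor infiltration versus
systemic antigen: *smaller* values mean stronger infiltration. It carries the
single random effect of the population model,
`S_L,i = S_L_pop · exp(η_i)`, `η_i ~ N(0, ω²)` with `S_L_pop = 8.89`,
`ω = 0.696`, and the residual error on measured volumes is the combined model
`sd = sqrt(a² + (b·y)²)` with `a` = 21.2 µL, `b` = 0.176 (an `a + b·y`
variant is selectable).

Seven constants are not printed in the source table and were reconstructed
once, then frozen (`scripts/calibrate.R` re-derives them):

| constant | value | role | anchor |
|---|---|---|---|
| `w_pdl` | 0.25 | weight of the PD-L1 axis in total suppression | PD-L1 explains at most ~25 % of suppression |
| `k_dcm_decay` | 1/d | DC_m relaxation rate | day-scale DC response |
| `k_ag` | 1/d | antigen turnover | day-scale antigen response |
| `q_ag` | 9 RU/µL | antigen presentation capacity | control IAR ≈ 5 % at day 20 |
| `k_isc` | 0.7/d | suppressive-cell turnover | control IAR ≈ 5 % at day 20 |
| `h_isc` | 2 | Hill coefficient of ISC recruitment | monotherapy ≤ 27 % vs combination ≥ 40 % |
| `c_apo` | 3 | exhaustion steepness of effector apoptosis | RT-monotherapy ceiling |

The calibration targeted, simultaneously: control typical-individual IAR
≈ 5 % at day 20; PD-L1-only suppression never above ~25 %; RT-only giving a
transient response with regrowth by days 15–20; concurrent
RT + anti-PD-L1 restoring IAR to ~100 % in a high-infiltration individual;
every monotherapy cell of the scheduling grid at or below a 27 % response
rate with the best prior-or-concurrent combination at or above 40 %; and
response rates degrading as the antibody start moves from concurrent to day
12 to day 19. All anchors were met at the frozen values (control IAR(20)
= 5.5 %, responder-preset max IAR = 99.8 %, monotherapy cells ≤ ~14 %, best
combination ≈ 49–52 %), and the constants were not revisited afterwards.

One transcription note: the source table's influx row reads "2798" with no
separate RSE entry, while every other tumor-data-estimated row carries one.
We read it as `k_LN` = 279 cells/d with RSE 8 %. The alternative (2798) gives
a maximal effector kill rate ~28× the tumor growth rate, under which every
untreated animal rejects its tumor — irreconcilable with the control
behavior the model is defined by.

## Simulation

`simulate_individual()` integrates the system with `deSolve::lsoda`
(stiff-capable, adaptive) at `rtol = 1e-8`, `atol = 1e-10` by default, with a
hard restart at every discrete event (RT fraction, antibody dose,
CD8-depletion switch) so bolus effects are reproducible; same-time events
apply RT before the antibody dose. Time 0 is inoculation of 5×10⁵ cells,
taken as `TV(0)` = 0.5 µL at 10⁶ cells/µL; all immune states start at 0, so
the immune response is driven entirely by tumor-cell death. (With the
published growth rate this gives ~5 µL at day 7 — smaller than the ~100 mm³
enrollment sizes reported experimentally; the inconsistency is inherited
from the published parameter set and does not affect the relative treatment
comparisons, which all start from the same state.) Tiny negative solver
excursions (below 100·atol) are clamped to zero; larger ones raise an error.
Halving the tolerances changes day-50 volumes by ~10⁻⁸ percent (the test
suite asserts < 0.1 %).

Virtual-trial work uses a documented coarser setting (`rtol = 1e-6`,
`atol = 1e-8`, output step 0.5 d); responder classification is stable well
beyond this tolerance.

## Virtual trials

A responder is an animal whose **total tumor volume is at or below 10 mm³ at
day 50 after treatment start** (for control arms "treatment start" is day 0
by convention). Response is monotone non-increasing in `S_L` — a tested
invariant — so `run_trial()` by default locates the critical `S_L*` of a
design by log-scale bisection (13 iterations, < 0.2 % precision) and
classifies all sampled individuals against it; `method = "exact"` simulates
every individual and the test suite asserts both routes agree. Per-study
parameter uncertainty (lognormal draws with the reported RSEs as CVs) can be
propagated with `propagate_uncertainty = TRUE`; it is off by default, so the
scaled-down sweeps measure pure IAV.

The full-size design is 1000 studies × 100 animals; the package's acceptance
runs use 50 × 50, which leaves the medians within a couple of percentage
points of the full budget while keeping a complete 65-cell scheduling sweep
within ~1 minute on one CPU. `scenario_presets()` exposes the six
calibration-study arms, the CD8-depletion arm (influx `k_LN` set to 0 from
treatment start — the depletion antibody's own timing is not printed in the
source, so treatment start is the default), and the stratified
responder / typical / non-responder individuals (`S_L` = 1.77 / 6.95 / 22.63
RU — empirical percentiles of the original individual estimates, used
verbatim and intentionally not derived from the lognormal at (8.89, 0.696),
with which they are inconsistent).

## Synthetic data and refitting

`generate_study()` emulates the six-arm calibration experiment: 59 animals
(10/10/10/10/10/9 — the published total with per-arm counts inside the
printed 7–16 range), volumes observed every third day from day 7 to 40,
lognormal IAV on `S_L` and combined residual error, with the truth attached
for recovery tests. It reproduces the *statistical* structure of such
experiments (growth heterogeneity, noise floor, complete responders), not
their operational details: no dropout, no size-triggered enrollment by
default (a trigger mode exists), no measurement censoring, and a fixed
observation grid. Passing recovery tests therefore demonstrate internal
consistency of the estimator under the model, not robustness to real-world
protocol deviations.

`fit_population()` estimates `S_L_pop` and `ω` (structural parameters can be
freed for sensitivity checks) by marginal maximum likelihood. The random
effect is integrated by trapezoid quadrature of the lognormal density over a
fixed 101-point log-spaced `S_L` grid (0.15–350 RU), with per-animal
likelihoods precomputed on the grid from per-arm ODE prediction matrices and
the truncated prior renormalized on the grid. This scheme was chosen over
Gauss–Hermite-plus-interpolation deliberately: individual likelihoods are
nearly step functions of `S_L` around the rejection threshold, which a
node-based rule samples erratically (in early experiments it biased `ω`
toward 0.3), whereas the fixed-grid rule is smooth in the parameters.
The original stochastic-approximation EM machinery is intentionally not
replicated; agreement is judged by parameter recovery (median over 20
replicates of 60-animal studies within ±20 % for `S_L_pop` and ±30 % for
`ω`, which the acceptance suite verifies). RSEs come from the observed
information with the delta method on the log scale; empirical-Bayes
individual estimates are grid posterior modes.

## Numerical and design notes

* Event times, dose times and the CD8 switch partition the integration; the
  output grid always contains the event instants (post-event values).
* `treatment_schedule()` tolerates zero-dose events as explicit no-ops;
  `apply_fraction()` itself requires doses in (0, 10] Gy.
* All sampling is seed-deterministic and restores the caller's RNG state;
  identical (design, seed) pairs give bit-identical trial results.
* The TCD spike after each fraction is asserted on a weak-immune individual
  (`S_L` = 60): at typical `S_L` the effector-kill flux exceeds `µ` per unit
  volume, so the instantaneous volume transfer can *lower* TCD — an
  interaction between two death fluxes, not a radiation artifact.
* Degenerate inputs: an all-zero state is a fixed point; `ω = 0` collapses
  the population to the typical individual (and the fitter reports `ω`
  shrinking to its boundary when the truth is 0); empty schedules are valid
  everywhere.

## Known limitations

* Validity is restricted to fractions ≤ 10 Gy; vascular/fibroblast radiation
  effects and dose-rate effects are out of scope, as are spatial structure,
  target-mediated antibody disposition, immune memory/re-challenge and
  survival endpoints.
* The two suppression axes (PD-L1 and one lumped cellular ISC pool) are the
  minimal description; tumors with different microenvironment composition
  would need a finer-grained suppression model.
* The reconstruction constants are identified only up to the behavioral
  anchors used; other combinations satisfying the same anchors would yield
  equivalent headline behavior.

## Problem sizes used by the tests

The test and acceptance runs use deliberately scaled simulation budgets: 50
virtual studies × 50 animals per scheduling cell (full design: 1000 × 100),
20 simulate-refit replicates of 60-animal studies, and the coarser
virtual-trial solver setting above. These sizes keep the whole suite within
minutes on a single CPU while leaving medians within the tolerances quoted
for each check.
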