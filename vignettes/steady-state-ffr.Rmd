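---
title: "Steady-state multiscale computation of coronary FFR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state multiscale computation of coronary FFR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coroffr)
```

## The problem

Fractional flow reserve (FFR) is the ratio of the pressure distal to a
coronary stenosis (Pd) to the aortic pressure (Pa) under maximal
pharmacological hyperemia; a value at or below 0.80 marks a lesion as
ischemia-causing. Measuring it requires an invasive pressure wire, which
motivates computing it from anatomy instead. `coroffr` computes FFR on a
centerline description of a coronary tree with a *steady-state geometric
multiscale* model: a spatially resolved vascular-domain solve coupled to
lumped-parameter (0D) models of the microcirculation behind every outlet.
The premise of the steady formulation is that the time-average of a
pulsatile coronary solution equals the steady solution driven by the mean
pressure, so one steady solve replaces a transient one at a small fraction
of the cost.

## Boundary conditions

All patient-specific inputs are four routine measurements.

* **Inlet.** The mean aortic pressure from the heart-rate-corrected cuff
  formula,
  `Pa = DBP + (1/3 + 0.0012 HR) (SBP − DBP)` (mmHg).
* **Coronary outlets.** At rest the coronary tree is allotted 4% of
  cardiac output. That budget is split across outlets by Murray's law
  (weights `r_i^3 / Σ r_j^3` on the terminal radii, exponent
  configurable), and each outlet's microcirculatory resistance is the Ohm
  ratio `R_i = (Pa − Pv) / Q_i`. Maximal hyperemia is modelled as every
  coronary `R` falling to 24% of its resting value — the single switch
  that turns a baseline solve into an FFR solve. Resistances are always
  derived from the healthy-tree budget, never from a stenosed solve, so a
  lesion cannot distort its own boundary condition.
* **Systemic outlet.** The remaining 96% of cardiac output drains through
  one lumped resistance `Rdoa = Pa / (0.96 CO)` at the distal end of the
  aortic stub.
* Each outlet model carries an inertance `L = 0.05` for fidelity to the
  lumped circuit it represents; at steady state `dQ/dt = 0` and it has no
  effect, which `solve_0d()` reflects by ignoring it.

Key defaults, all exposed in `bc_config()`: coronary share of CO 0.04,
Murray exponent 3, hyperemia factor 0.24, venous reference pressure
0 mmHg. Blood is incompressible and Newtonian with density 1050 kg/m³ and
viscosity 0.0035 Pa·s (`blood_properties()`).

## The vascular domain

The domain solver is a steady reduced-order nonlinear network standing
behind the same interface contract a 3D CFD solver would honour (inlet
pressure and outlet pressures in, interface flows out), so the coupling
loop is agnostic to how the domain is discretized. Each centerline
segment with linearly tapering radius contributes its exact Poiseuille
resistance

`R_visc = 8 μ L (r0⁻³ − r1⁻³) / (3 π (r1 − r0))`,

and each focal stenosis adds an empirical viscous-plus-expansion loss

`ΔP = Rv q + Kt (ρ/2) (A0/As − 1)² q |q| / A0²`,

with `As = A0 (1 − severity)²`, `Rv` the Poiseuille resistance of the
throat, and `Kt = 1.52` by default. This Young–Tsai-type loss model is the
principal modelling substitution for resolving lesions with 3D CFD, and
`Kt` is deliberately configurable. Per segment the pressure drop is then
`Δp = A q + B q|q|` with `A > 0`, `B ≥ 0` — strictly monotone, so the
nodal mass-balance system has a unique solution. It is solved by damped
Newton iteration on the free nodal pressures (the Jacobian is a weighted
graph Laplacian); the closed-form inverse of `Δp(q)` keeps every residual
evaluation exact. Mass balance is driven below 1e-12 of the largest flow
when arithmetic allows and is guaranteed below 1e-9; near machine
precision the limiting factor is that the pressure drop along a wide
aortic segment is ~1e-8 of the absolute pressure level.

## 0D–domain coupling

`couple()` implements the partitioned fixed point: the domain is solved
with the current outlet pressures, the resulting interface flows are
handed to the 0D models, and the returned pressures `Pv + R Q` become the
next outlet boundary conditions. Convergence is declared when the largest
relative change of both interface pressure and interface flow falls below
`ε = 1e-4` (a flow floor of 1e-6 mL/s guards the division); the exact
residual norm behind the published tolerance is a documented choice of
this package.

A plainly under-relaxed exchange is numerically stiff here: outlet
resistances exceed the epicardial vessel resistances by one to four
orders of magnitude, so the fixed-point gain is far above 1 (about 1e4 at
the systemic interface), and sibling outlets are strongly cross-coupled
through shared upstream segments. The update is therefore accelerated by
Anderson mixing of the exchanged pressure vector — history depth equal to
the number of interfaces plus two, column-normalized and rank-filtered
least squares, with the configured relaxation factor (default 0.5) as the
mixing parameter. For the nearly affine interface map this behaves like a
secant quasi-Newton method and converges in roughly 15–30 exchanges
across the severity and state grid; a fixed scalar relaxation either
diverges or would need ω < 2e-4.

`solve_monolithic()` folds the outlet resistances into the network as
extra edges to their venous reference and solves the whole system in one
Newton pass. It shares the fixed point of the partitioned loop without
any partitioning and serves as the independent verification oracle: on
randomized synthetic trees the two agree on all interface pressures and
flows to well within 10·ε.

## FFR extraction

`compute_ffr()` divides every nodal pressure by Pa; the inlet value is
exactly 1 by construction. Per-lesion FFR is sampled, by default, at the
distal node of the stenosed segment — deterministic and conservative,
since the true wire position is unknowable from anatomy; a sampling
distance distal to the throat (`lesion_offset_mm`) is available and
interpolates the within-segment pressure profile. Classification is
inclusive: `FFR ≤ 0.80` is positive, matching the convention used when
the threshold is quoted.

Under this model FFR is monotone non-increasing in stenosis severity and
is lower under hyperemia than at rest (more flow, more trans-lesion
loss); both are enforced as tests. A stenosis-free tree under hyperemia
shows distal FFR around 0.95–0.98 — not 1.0 — because maximal flow
through 1–2 mm vessels legitimately costs a few mmHg; this matches
invasive experience in angiographically normal arteries.

## Synthetic data

`generate_synthetic_tree()` emulates a CTA-derived centerline tree: an
aortic stub with a systemic outlet, main branches (LAD, LCX, RCA) whose
root radii are drawn from 1.5–2.0 mm, segment lengths of 8–14 parent
radii, within-segment taper factors of 0.87–0.93, and bifurcations built
by splitting the parent's `r³` with a flow fraction drawn from
0.35–0.5, so Murray's law holds exactly by construction. Three
generations (the default) give 7 coronary outlets, the package's choice
for a realistic desk-scale tree. Focal stenoses are placed on the root
segment of a named branch; severities of 0.95 or more are rejected as
outside the loss model's validity. `sample_patient_parameters()` draws
SBP/DBP/HR/CO from normal distributions with stable-angina population
means and SDs (128±10 / 85±9 mmHg, 72±12.76 bpm, 5.26±2.6 L/min
truncated below 2), with rejection sampling enforcing `SBP > DBP > 0`.

What the generator does *not* emulate: real lumen irregularity, eccentric
or diffuse disease, side branches below the 0.5 mm radius retention rule,
collaterals, and the anatomic variability of real cohorts. Passing tests
on synthetic trees therefore validate the numerics and the internal
consistency of the model — they say nothing about agreement with invasive
FFR in patients, which requires clinical data this package does not ship.

## Numerical choices and degenerate inputs

* Internal computation is SI throughout; mmHg, mm and mL/s exist only at
  the API boundary (cardiac output alone is quoted in L/min).
* Newton on the domain: linear (`B = 0`) solve as the initial guess,
  backtracking line search on the mass-balance norm, stall acceptance
  only below the 1e-9 conservation bound.
* Zero pulse pressure, zero flow budgets and occlusive severities are
  rejected at construction; sub-resolution coronary radii (< 0.5 mm,
  mirroring the ≥ 1 mm diameter retention rule of CTA reconstruction)
  warn rather than error so stress tests can cross the rule deliberately.
* Tree serialization is versioned (`coro-ffrss-tree/1`), exact to 15
  significant digits, and idempotent (write–read–write is
  byte-identical). The systemic outlet is optional in the schema so that
  minimal coronary-only trees are expressible; solvers attach `Rdoa` only
  when one is present.
* Diagnostics: the ischemic class is `FFR ≤ 0.80` everywhere; the Youden
  index is reported at full precision and truncated to two decimals (the
  quoting convention); AUC confidence intervals use DeLong, Pearson
  intervals use Fisher's z; the ROC-optimal cut-off is the observed
  computed-FFR value maximizing sensitivity + specificity with ties
  resolved toward 0.80.

## Problem sizes

The test suite and the acceptance checks run on trees of 3–15 segments
(1–4 generations), 20-seed partitioned-versus-monolithic comparisons, a
five-point severity sweep in both physiological states, and Monte-Carlo
draws of up to 10,000 patients — sizes chosen so the full suite completes
in well under two minutes on one CPU while still exercising every code
path at the fidelity the model supports.

## Limitations

The domain is a reduced-order network, not 3D CFD: secondary flows,
curvature and post-stenotic jet details enter only through the lumped
`Kt`. The hyperemia factor 0.24 is a population constant, not a
patient-specific microvascular measurement. Lesion FFR depends on the
sampling convention when lesions sit far from a node. None of the
clinical agreement statistics shipped in `diagnostics` can be reproduced
without paired invasive measurements.
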