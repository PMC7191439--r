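---
title: "Aerodynamic evaluation of staged tracheal stenosis correction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aerodynamic evaluation of staged tracheal stenosis correction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The clinical question and its computational surrogate

Multisegmental congenital tracheal stenosis leaves a surgeon with a staging
decision: when two discrete narrowings (call them S1 and S2) cannot be
resected in one operation without excessive anastomotic tension and long
cardiopulmonary bypass, which one should be corrected first? Airflow
mechanics offers a quantitative handle. Correcting a segment changes the
pressure drop, the wall shear stress (WSS) on the airway epithelium, and the
mechanical energy the ventilator must supply - and because the two stenoses
sit in series in the same airstream, correcting one changes the aerodynamic
load on the other.

`airflowsim` implements this evaluation as a desk-scale pipeline. Instead of
a patient CT reconstruction (which is not publicly deposited for this kind of
study), the airway is an **axisymmetric parametric lumen**: a radius profile
$R(s)$ along the tracheal axis, with stenoses expressed as smooth
constrictions and "virtual surgery" as the exact removal of a constriction.
All of the quantities of interest - the stenosis ratio, pressure drops, WSS,
the energy-loss rate - are defined on cross-sections and walls, so the
axisymmetric reduction preserves the full metric set while making a
from-scratch finite-volume solution tractable on one CPU. What is lost is
genuinely three-dimensional structure: the C-shaped tracheal curvature, the
carina, and bifurcation secondary flows. The left/right flow distribution,
which lives in that lost geometry, is recovered by a calibrated lumped
bronchial resistance network instead.

## Geometry: parametric lumen and virtual surgery

The lumen is stored as samples $(s_i, R_i)$ with a reference (healthy)
radius $R_0$. A stenosis with target severity $r$ is a raised-cosine radius
dip over an extent $[c-\ell/2,\, c+\ell/2]$ whose throat radius satisfies
$R_\mathrm{min} = R_0\sqrt{1-r}$, so the standard area-based stenosis ratio

$$ r = \frac{S_{TE} - S_{SP}}{S_{TE}} \times 100\% $$

(entrance area $S_{TE}$, minimal stenotic area $S_{SP}$) is met by
construction. The dip is $C^1$-smooth at both ends. Application and
correction are *additive inverses on the radius samples*, which gives three
exact invariants the tests rely on: apply-then-correct round-trips to the
input profile, corrections of distinct stenoses commute, and correcting
every stenosis reproduces the healthy lumen to machine precision.

Free parameters the study case does not pin down are set once, as defaults,
and are flagged as synthetic in every emitted config:

| parameter | default | why |
|---|---|---|
| healthy diameter $2R_0$ | 6 mm | a typical infant trachea at ~5 months |
| S1 position / severity | proximal third, $r = 68.7\%$ | severity is the study value; position is a default |
| S2 position / severity | distal third, $r = 86.5\%$ | severity is the study value; position is a default |
| stenosis extents | 20% of tracheal length each | jointly >30% of the trachea, the threshold for a generalized multisegmental lesion |
| tracheal length | 45 mm | infant-scale default |

The four surgical variants are the subsets of $\{S1, S2\}$ corrected: M1
(none), M2 (S1), M3 (S2), M4 (both).

For the flow solution the domain is extended by straight ducts of 20
diameters upstream and 40 diameters downstream, so the inlet plug profile
develops before the trachea and the zero-pressure outlet sits far from the
jet; metrics are evaluated only on the anatomical segment.

## Flow model

Steady incompressible RANS for air under mechanical ventilation
($\rho = 1.161\ \mathrm{kg/m^3}$, $\mu = 1.864\times 10^{-5}$ kg/(m s),
body forces omitted), with the Wilcox $k$-$\omega$ closure:

$$ \mu_T = \frac{\rho k}{\omega}, \qquad
   \tau_{ij} = 2\mu_T S_{ij} - \tfrac{2}{3}\rho k \delta_{ij}, $$

with transport of $k$ (production $\tau_{ij}\partial u_i/\partial x_j$,
destruction $\beta^*\rho k\omega$, diffusivity $\mu + \sigma^*\mu_T$) and of
$\omega$ (production $\alpha\frac{\omega}{k}\tau_{ij}\partial u_i/\partial x_j$,
destruction $\beta\rho\omega^2$, diffusivity $\mu + \sigma\mu_T$), closure
coefficients $\alpha = 5/9$, $\beta = 3/40$, $\beta^* = 9/100$,
$\sigma = \sigma^* = 1/2$. The transient terms serve only as pseudo-time
relaxation; a steady state is sought. At the study flow of 3 L/min the bulk
tracheal Reynolds number is about 660 and the severe throat reaches about
1800 - the transitional jet regime in which stenotic flows are conventionally
treated with a turbulence closure.

### Discretization and solution

* Axisymmetric swirl-free finite volumes on a structured body-fitted grid in
  $(x, r)$, with exact revolution metrics: Pappus cell volumes and conical
  face areas. Green-Gauss gradients carry the axisymmetric metric correction
  so that constant fields have exactly zero gradient.
* Collocated variables with SIMPLE pressure-velocity coupling and Rhie-Chow
  momentum-interpolated face fluxes (checkerboard suppression).
* Convection: second-order upwind via deferred correction (first-order
  upwind kept in the implicit operator); central diffusion with over-relaxed
  non-orthogonality correction. The turbulence scalars use first-order
  convection for robustness.
* Walls: no-slip, low-Reynolds integration to the wall. The wall-adjacent
  $\omega$ is pinned to the smooth-wall asymptote
  $\omega_1 = 6\mu/(\rho\beta y_1^2)$; $k$ is zero at the wall. The viscous
  wall flux uses a one-sided quadratic gradient (deferred), which keeps wall
  shear - and with it the Poiseuille pressure drop - second-order accurate.
* Inner linear solves: alternating line-TDMA sweeps for momentum and
  turbulence; Jacobi-preconditioned conjugate gradients for the symmetric
  pressure-correction operator.
* The in-loop pressure correction is solved to a 2% *relative* residual
  reduction. This choice matters: a loose absolute tolerance lets the stored
  pressure drift away from the momentum-consistent field (the velocity and
  wall shear stay right while $\mathrm{d}p/\mathrm{d}x$ goes wrong), while an
  over-tight in-loop solve destabilizes the stenotic-jet cases. After the
  outer iteration converges, one tightly solved pressure pass (absolute
  residual $10^{-13}$ of the inlet flux) makes the returned face fluxes
  discretely conservative in every cell.
* Convergence is declared when the relative inter-iteration variation of
  every field ($u, v, p, k, \omega$; $L_1$ norms against field-scale
  references) falls below $10^{-5}$. The reference scales are the inlet
  velocity, its dynamic pressure, and the inlet turbulence quantities; the
  choice of norm is ours, since only "relative variation below $10^{-5}$" is
  specified by the study conditions.

### Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| inlet flow | 3 | L/min | constant volume-controlled ventilation |
| outlet pressure | 0 | Pa | gauge datum, fixed |
| inlet turbulence intensity | 5 | % | unstated in the study; sensitivity is mild because the 20D extension re-equilibrates the inflow |
| inlet turbulence length scale | 10% of inlet diameter | - | conventional duct estimate |
| under-relaxation $u$/$p$/$k\omega$ | 0.7 / 0.3 / 0.8 | - | standard SIMPLE practice |
| patient-suite under-relaxation | 0.4 / 0.2 | - | the 86.5% jet limit-cycles at 0.7/0.3 on the default mesh; 0.4/0.2 and 0.3/0.15 agree to <1% in every metric |
| first layer height | $10^{-5}$ | m | wall-resolving ($y^+ \lesssim 1$ in every case run here); the 0.0022 mm value used with the original patient mesh is available as a config preset, not the default, since it is unusually small for this regime |
| BL growth ratio / layers | 1.2 / 3 | - | geometric wall stack |
| cells (patient case) | ~7-8k | - | axisymmetric reduction needs far fewer cells than a 3D tetra/prism mesh of ~0.5M elements for comparable wall resolution |

## Meshing

Radial node distributions follow the local radius: a geometric stack of
`n_bl_layers` cells starting at `first_layer_height` and growing by
`growth_ratio`, then a smoothly graded interior to the axis (the grading
ratio is solved per station so the nodes always fill $[0, R(s)]$ exactly).
Axial spacing is uniform across the anatomical segment and geometrically
stretched (ratio 1.15, capped at 8x) through the extensions. Refinement for
grid studies multiplies both counts and divides the first-layer height, so
every spacing shrinks at the refinement ratio. Geometric conservation is
testable: the mesh volume equals the revolved volume of its own
piecewise-linear wall to machine precision, and converges to the profile's
revolved volume at second order.

## Metrics

* **Wall shear stress**: $|\mu\, \partial u_t/\partial n|$ at the wall from a
  one-sided quadratic fit through the first two cell centers. Maxima are
  reported per stenotic region (point-wise over the wall patch, since the
  patch-averaged alternative is not better specified).
* **Pressure drop**: area-averaged *static* pressure difference between
  stations one reference diameter upstream and downstream of each stenotic
  extent (clamped to the anatomical segment). Station placement is a design
  choice - the study does not state one - and for corrected cases the same
  regions of the uncorrected pathology are used, so residual drops at former
  stenotic sites are still reported. A total-pressure variant
  ($p + \tfrac12\rho|u|^2$, mass-flux averaged) is computed alongside.
* **Energy flux and loss rate**: $E(s) = \sum_j (p_f + \tfrac12\rho|u_f|^2)
  Q_f$ over a cross-section, evaluated with the conservative face fluxes;
  $EL = E_\mathrm{in} - E_\mathrm{out}$ over the anatomical segment and
  $\lambda = 1 - E_\mathrm{out}/E_\mathrm{in}$, which holds as an identity by
  construction. $\lambda$ is computed over the anatomical trachea; its
  *absolute* value is therefore not comparable to a whole-airway patient
  model, in which most of the inlet energy flux is recoverable kinetic
  energy at the bronchial outlets and the loss rate is correspondingly
  small. Orderings across M1-M4 are the meaningful comparison, and they are
  what the acceptance suite asserts.
* **Throat Reynolds number**: $\rho U D/\mu$ at the minimal-area station of
  each region.

## Bronchial network and flow split

The left/right distribution is computed on a lumped resistance tree: each
branch carries a Poiseuille term $128\mu L/(\pi D^4)$ plus a minor-loss term
$K\rho Q/(2A^2)$, flows distribute in inverse proportion to equivalent
subtree resistances (exact junction conservation by construction), and the
flow-dependent resistances are iterated to a $10^{-12}$ fixed point. The
tracheal CFD result enters as a secant resistance $\Delta P/Q$ in series at
the root - which is also why the split is (correctly) insensitive to the
surgical variant: a series resistance at a fixed inlet flow cannot move a
downstream parallel split, mirroring the reported finding that the
distribution stayed nearly identical across all four models.

The default branch dimensions are **calibrated, not measured**: the
right-dominant preset reproduces a split near 7:3 for the uncorrected case
(emulating the left-bronchus compression of a pulmonary-artery sling), and a
healthy-infant preset reproduces 56.57:43.43. The outlet label set
(LSL/LML/LIL, RSL/RML/RIL under LMB/RMB) follows the seven-label outlet
convention of the source material, including the anatomically odd "left
middle lobe", kept as a configurable label.

## What the synthetic suite does and does not emulate

The generator reproduces the study *conditions*: two stenoses of severity
68.7% and 86.5%, 3 L/min constant inspiratory flow, the stated air
properties, zero-pressure outlets, 20D/40D extensions, and the four
correction variants. It does not emulate CT noise, surface irregularity,
tracheal curvature, the carina, compliant walls, or unsteady ventilation
waveforms. Passing tests therefore demonstrate that the *method* - solver,
metrics, and comparison logic - behaves correctly and reproduces the
qualitative surgical-interaction findings on a faithful stand-in; they do
not certify patient-specific absolute values, which depend on the
unavailable 3D geometry.

Two qualitative findings deserve a note on robustness:

* *Correcting S1 raises the pressure drop at S2.* This reproduces strongly
  (about +14 Pa of ~90 Pa): with both stenoses present the S1 jet is still
  concentrated when it reaches S2 (the throats are ~4.5 jet diameters
  apart), and its unrecovered head depresses the upstream station of S2.
* *Correcting S2 lowers the pressure drop at S1.* This reproduces in
  direction but with a small margin (~0.04 Pa of ~17 Pa): in an axisymmetric
  model the upstream influence of a constriction is short-range, so at one
  diameter upstream the suction of S2 is nearly gone. The pipeline is
  deterministic, so the sign is stable, but the magnitude should not be
  over-interpreted.

## Numerical choices and degenerate inputs

* Severities are validated to $[0, 1)$; overlapping stenoses are rejected;
  a boundary-layer stack thicker than 90% of the local radius raises an
  infeasible-mesh error naming the axial station.
* Zero inlet flow returns the exact rest state (zero velocity, uniform
  pressure).
* $k$ and $\omega$ are floored at tiny positive values after each iteration;
  clip counts are reported on the flow state.
* Ties in station lookup resolve to the nearest face column; stations are
  snapped to faces so energy fluxes always use conservative face fluxes.

## Problem sizes

The validation and acceptance runs use: a three-level Poiseuille study
(640 to 10,240 cells), a 60-diameter pipe at $Re = 10^4$ (3,840 cells), a
four-point severity sweep (~4,700 cells each), and the four patient-like
variants (~7,800 cells each, converging in 300-1,800 SIMPLE iterations).
These sizes were chosen so the whole suite solves in a few minutes on one
CPU while every oracle-backed tolerance (2% on Hagen-Poiseuille, 15% on
Blasius, 3% on laminar WSS) is met with margin; refining further changes
the reported metrics by well under those tolerances (the grid-sensitivity
driver documents this per case).

## Known limitations

* Axisymmetry excludes curvature-driven secondary flows, the carina jet
  impingement, and any genuinely 3D interaction; the flow split is a
  calibrated network result, not a CFD prediction.
* The steady RANS ansatz suppresses jet unsteadiness; the severe-stenosis
  cases need heavier under-relaxation precisely because the underlying flow
  is near the steady/unsteady boundary.
* The Wilcox closure is used in the transitional regime, as in the original
  evaluation; no transition model is applied.
* Rigid walls and constant inspiratory flow; fluid-structure interaction and
  ventilation waveforms are out of scope.
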