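---
title: "Windkessel-coupled aortic hemodynamics: models, numerics and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windkessel-coupled aortic hemodynamics: models, numerics and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortohemo)
```

## The problem

Peak systolic pressure (PSP) and peak systolic velocity (PSV) are core
quantities in the workup of congenital heart disease: pressure gradients
across the aortic isthmus grade coarctation, and Doppler velocities grade
stenoses. Catheterization measures pressure directly but is invasive;
echocardiography measures velocity but not pressure. Simulation offers a
noninvasive route: reconstruct the aortic geometry, impose a measured
inflow, model the downstream circulation at each outlet, solve the
incompressible Navier-Stokes equations, and read PSP/PSV/wall shear stress
from the solved fields. This package implements that pipeline end to end on
*synthetic* aortic geometries, together with the method-agreement
statistics (Bland-Altman limits of agreement, correlation and fitting,
normality-gated paired tests) used to judge such a pipeline against
clinical reference measurements, and a seeded virtual-patient cohort
generator so the whole chain runs and is testable without any clinical
data.

## The three-element Windkessel outlet model

Each outlet (brachiocephalic BA, left common carotid LCCA, left subclavian
LSA, descending aorta DAo) is closed by a three-element Windkessel: a
characteristic resistance $R_1$ in series with a parallel peripheral
resistance $R_2$ and compliance $C$, relating outlet pressure $P$ (mmHg)
to outlet flow $Q$ (ml/s):

$$P + R_2 C \frac{dP}{dt} = (R_1 + R_2)\,Q + R_1 R_2 C \frac{dQ}{dt}.$$

Time stepping uses backward Euler with $\beta = R_2 C/\Delta t$:

$$P_{n+1} = \frac{(R_1+R_2+R_1\beta)\,Q_{n+1} - R_1\beta\,Q_n + \beta P_n}{1+\beta}.$$

The steady limit is $P = (R_1+R_2)Q$, the zero-flow response decays as
$\exp(-t/R_2C)$, and the update has a strict fixed point at the steady
state; the test suite checks all three plus first-order convergence
against an independent RK4 integration of the ODE. The packaged parameter
set (`wk_params("BA")` etc.) is the reference table used throughout:

```{r}
wk_params("BA")
```

Clinical units (mmHg, ml/s) are native on the 0D side; conversion to SI
(1 mmHg = 133.322 Pa) happens only at the 3D coupling boundary.

## Synthetic geometry

`aorta_spec()` parameterizes an idealized aorta: a straight ascending
segment (inlet at $z=0$, normal $+z$), a semicircular arch in the $x$–$z$
plane carrying three vertical branch vessels, and a descending segment
returning to the $z=0$ plane, with a linear taper from the ascending to
the isthmus (AI) and descending (DAo) diameters and an optional smooth,
compactly supported narrowing at the isthmus (`ai_stenosis_factor`). All
outlet caps are therefore axis-aligned planes on the domain boundary.
Branches leave the arch vertically rather than radially so that their
outlet caps are flat $z$-planes; for attachment angles near the top of
the arch the two directions are close, and the choice keeps boundary
conditions exact on a Cartesian grid.

Diameters at the named probe planes (`AscAo`, `AI`, `DAo`) equal the spec
values exactly at the analytic level; the diameter convention everywhere
is the equivalent-circle diameter $2\sqrt{A/\pi}$ of the cross-section,
which remains robust for voxelized and polygonal sections.

`voxelize()` rasterizes the geometry on an isotropic cell-centered grid
(indices map to centers at `origin + (i + 0.5) h`). A cell is fluid when
its center lies inside the lumen. Classification against the tapered
centerline chain uses the nearest *frustum* (interior axis projection)
and falls back to the capsule ball only in the wedge regions outside
bends that no frustum sees; the ball-joint-only rule would thicken every
tapered run by $\approx r\,(dr/ds)^2/2$ and leave a resolution-independent
volume bias. The lateral grid origin is offset by a fixed fraction of $h$
so vessel axes never coincide with cell corners (alignment freezes the
rasterization error across refinement levels). The voxelizer requires at
least 8 cells across the smallest lumen diameter and warns below 10, and
every fluid cell must be reachable from the inlet.

Each fluid cell carries an anatomical region label (AscAo, arch, AI, DAo,
branch) from its nearest centerline point, and main-vessel cells carry a
wall-quadrant label — outer `O`/inner `I` along the local curvature
direction of the arch plane, left `L`/right `R` along $\pm y$ — which is
how wall shear stress extrema are localized anatomically.

## Flow solver

The incompressible Navier-Stokes equations
$\rho(\partial_t u + u\!\cdot\!\nabla u) = -\nabla p + \mu \nabla^2 u$,
$\nabla\!\cdot\!u = 0$ (blood as a Newtonian fluid, $\rho = 1050$
kg/m$^3$, $\mu = 0.004$ Pa s, no body force, rigid walls, no
fluid-structure interaction) are solved with a classical projection
scheme on a staggered (MAC) grid: explicit first-order upwind advection
and explicit diffusion form a provisional velocity; a pressure Poisson
solve (Jacobi-preconditioned conjugate gradients on the masked 7-point
Laplacian, warm-started from the previous step) enforces continuity; the
corrected velocity is discretely divergence-free to the solver tolerance
in every fluid cell at every step.

Boundary conditions:

* **Inlet**: plug velocity on the inlet cap, scaled so the volumetric
  inflow matches the waveform exactly on the voxelized cap area.
* **Walls**: stair-step immersed no-slip. Wall-normal velocities vanish
  on solid faces; tangential components use a mirror ghost ($-u$) across
  the wall face, which places the no-slip surface on the stair face
  itself. Without the mirror the effective lumen widens by $h/2$ per
  side — a straight-tube test then yields a centerline-to-mean ratio of
  1.82 instead of 2 and doubles the wall shear stress.
* **Outlets**: uniform Dirichlet pressure at the cap face (half a cell
  from the adjacent center), supplied by the Windkessel models. Coupling
  is explicit: the flux measured through each outlet cap at one step
  drives `wk_step()`, whose pressure (converted to Pa) is applied at the
  next step. The recorded outlet pressure trace therefore replays
  *exactly* through the 0D stepper run offline on the recorded flux
  trace, which the suite asserts to round-off.

The time step is adaptive: `min(cfl * h / u_max, rho h^2/(6 mu), T/200)`
with CFL 0.4 by default, landing exactly on the peak-systole instant
(defined as the time of maximum inflow) and on cycle boundaries. Runs
start from rest with outlet pressures at the Windkessel steady values for
cycle-mean flow, simulate `n_cycles` (3 by default, 2 for the coarse
qualitative case below) and analyze the last; a cycle-to-cycle
periodicity metric on the outlet pressures is recorded and a warning is
attached when it exceeds its tolerance — never silently.

Numerical accuracy is validated against analytic limits rather than
against any particular commercial solver: at 16 cells per diameter a
steady tube run reproduces the Poiseuille centerline-to-mean ratio of 2
within 5%, wall shear within 15%, the Windkessel-plus-Poiseuille inlet
pressure within 10%, and conserves mass to 0.1%. Upwind advection adds
numerical diffusion at high cell Reynolds numbers; in developed
unidirectional flow the advective term vanishes, so these limits are
insensitive to it, but transitional secondary flows in the arch are
smoothed at coarse $h$ — a known limitation of the desk-scale setting.

## Postprocessing

**Wall shear stress** uses the first-order one-sided closure $\tau = \mu
u_t/\Delta n$ per wall face. The tangential speed is the near-wall
cell-center velocity projected onto the analytic surface normal (stored by
the voxelizer), and $\Delta n$ is the distance from the cell center to the
analytic surface, clamped to $[0.25h, 1.25h]$: cells closer than about
half a cell to the surface have their velocity controlled by the
stair-step face half a cell away, so the effective no-slip distance is
bounded below. The clamp was calibrated once against the analytic
Poiseuille wall shear on a voxelized cylinder (the band average is then
within ~2% at both tested resolutions) and frozen. Peak-systolic WSS (PSWSS) maps are taken at the
peak-systole instant; `pswss_extrema()` reports the global extrema with
region and quadrant tags, excluding faces within two cells of the
inlet/outlet cap planes (entrance/exit artifacts of the truncated
domain) and, by default, the walls of the branch tubes beyond their
ostia — those straight tubes are outflow extensions of the truncated
anatomy, conventionally excluded from reported wall-shear maps (ostium
faces are kept; branch-ostium tags apply within two branch radii of the
attachment points). The extreme *values* are the true global extrema;
their anatomical *location* is the modal region/quadrant of the nine
most extreme faces, because the single-face argmin of a near-stagnation
stress field is voxel-level noise while a reader of the map judges a
neighborhood.

**Probes** mirror what the clinical modalities measure: PSV is the
maximum over the cycle of the largest velocity magnitude on the
ascending-aorta plane (the fastest jet a Doppler beam would sample, in
cm/s); PSP is the maximum of the area-averaged pressure on the isthmus
plane (a catheter-like lumped reading, in mmHg).

**Helicity**: localized normalized helicity LNH $= u\cdot\omega /
(|u||\omega|) \in [-1, 1]$ per cell, set to 0 where $|u|$ or $|\omega|$
falls below $10^{-10}$ (SI) to avoid 0/0; vorticity by central
differences of cell-centered velocity. Streamlines integrate the
normalized velocity with fixed-step spatial RK4 ($h/2$ per step) under
trilinear interpolation until they exit the fluid.

## Virtual cohort generator

The generator emulates the statistical structure of a 25-infant reference
cohort; it is the package's replacement for clinical data, and its
defaults are fixed study conditions, not tuning knobs:

* **Diameters**: independent truncated Gaussians — AscAo 19.2 ± 6.0 mm,
  AI 12.1 ± 3.5 mm, DAo 10.9 ± 2.6 mm, truncated above 3 mm and with
  AI, DAo below 0.95 × AscAo (joint resampling, bounded retries). The
  reference tables do not constrain the correlation structure between
  sites, so independence is a documented simplification.
* **Inlet waveform**: half-sine systole (`make_inlet_waveform()`), zero
  diastolic flow, systolic fraction 0.35, heart rate uniform in 95–140
  bpm — the waveform shape itself is a modeling choice since only
  summary velocities are available as targets.
* **Velocity and pressure targets**: each case samples a peak
  ascending-aorta velocity (truncated Gaussian 110 ± 35 cm/s on
  [55, 200]) from which the stroke volume follows via the lumen area, and
  a target PSP (105 ± 15.4 mmHg on [75, 140]). The reference outlet
  impedances are scaled per case — $R_1, R_2$ up and $C$ down by a common
  factor $\gamma$, which preserves every time constant and scales the
  pressure solution exactly linearly at fixed flow — so the lumped
  network reproduces the sampled pressure target exactly. Fixed
  population-level parameters cannot span the reference cohort's PSP and
  PSV ranges simultaneously; per-case impedance scaling is the standard
  practice for matching an outlet model to a measured pressure.
* **Measurement noise**: additive Gaussian on the "TTE" velocity and
  "catheter" pressure, SDs defaulting to the reference
  limits-of-agreement half-widths divided by 1.96 (11.6 cm/s, 4.4 mmHg).
  A single master seed fans out to per-case substreams through a counter
  scheme, so enlarging a cohort never reshuffles existing cases.

`run_cohort()` fills the simulated truth per case. The default
`method = "lumped"` drives the per-case Windkessel network with the case
waveform through a single aortic pressure node (`simulate_case_lumped()`):
PSP is the node's cycle maximum and PSV is the peak mean velocity times a
profile factor of 1.3 (a partially developed inlet-region profile). This
reduced-order surrogate preserves exactly the quantities the validation
statistics operate on and runs in milliseconds per case, which is what
makes 25-case end-to-end runs and multi-cohort panels testable at desk
scale; `method = "cfd"` runs the full 3D pipeline per case when the cost
is warranted. What the lumped surrogate does *not* emulate — spatial
velocity skew, secondary/helical flow, wall shear — is exercised separately
on the cohort-mean 3D case.

## What the tests do and do not show

The suite validates: the 0D model against closed forms and an RK4 oracle;
the geometry against exact analytic diameters and volumes; the 3D solver
against rest-state, mass-conservation, Galilean-offset and Poiseuille
limits; the probes against constructed fields with known answers; the
statistics against textbook-formula oracles on seeded data and against
the packaged reference tables to printed precision; and the cohort chain
as a noise-recovery experiment (bias within half the configured noise SD,
limits-of-agreement half-width within 25% of 1.96 × SD at n = 25, with a
10-cohort panel checked in aggregate — per-cohort bands at n = 25 would
reject a correct generator by sampling noise alone).

On the coarse cohort-mean aorta (h = 0.8 mm, two cycles, relaxed pressure
tolerance 10^-6) the suite asserts *qualitative* flow features: the PSWSS
maximum at the arch outer wall or brachiocephalic ostium, the minimum at
the right ascending wall or inner isthmus, and higher |LNH| in the arch
than in the straight descending segment. Absolute PSWSS magnitudes of any
specific patient group are not reproducible from synthetic geometry, and
no such values are asserted.

Known limitations: first-order space/time accuracy at walls and in
advection; no fluid-structure interaction, non-Newtonian rheology or
turbulence model; plug (not patient-specific) inlet profiles; independent
diameter sampling; and the reduced-order cohort truth described above.
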