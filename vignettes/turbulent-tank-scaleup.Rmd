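---
title: "Turbulent flow analysis of reciprocating-impeller bioreactors: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Turbulent flow analysis of reciprocating-impeller bioreactors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`turbtank` models cylindrical cell-culture tanks stirred by flat discs
reciprocating vertically on a central shaft. The quantities it exists to
compute are the volume-averaged turbulent energy and shear stress that
govern platelet release from cultured megakaryocytes, and the volume of
the *defective turbulent flow space* — the part of the tank that never
experiences active turbulence during a stroke cycle — which is what
degrades production efficiency when the process is scaled up at constant
turbulence targets. This vignette is the package's own account of the
models, the parameter choices, and what the tests do and do not
demonstrate.

## Flow model

The solver integrates the steady incompressible Reynolds-averaged
Navier–Stokes equations with a finite-volume discretisation on a uniform,
cell-centred 2D axisymmetric (r, z) grid. Specifics:

* **Pressure–velocity coupling**: SIMPLE, with Rhie–Chow face
  interpolation on the collocated grid and implicit under-relaxation
  (defaults 0.7 momentum, 0.3 pressure, 0.5 for k and ε).
* **Convection**: hybrid central/upwind switching at cell Peclet 2;
  diffusion is central. Formal accuracy is second order in
  diffusion-dominated regions and first order where convection dominates.
* **Closure**: realizable k–ε. Turbulent viscosity μ_t = C_μ ρ k²/ε with
  the variable C_μ = 1/(A₀ + A_s U* k/ε), A₀ = 4.04 (a constant
  C_μ = 0.09 mode is available and is used in the worked scalar
  examples); production P_k = μ_t γ̇² capped at 10 ρ ε;
  C₁ = max(0.43, η/(η+5)) with η = γ̇ k/ε; dissipation destruction
  ρ C₂ ε²/(k + √(νε)) with C₂ = 1.9, σ_k = 1.0, σ_ε = 1.2. A variant
  with √(με) in the denominator is selectable for comparison with texts
  that print it that way, but it is not dimensionally homogeneous and is
  not the default.
* **Near-wall treatment**: standard equilibrium wall functions — the
  log-law with a viscous/log switch at y⁺ = 11.06, wall shear
  coefficients built from C_μ^{1/4}√k, and ε fixed to
  C_μ^{3/4} k^{3/2}/(κ y) in wall-adjacent cells. Blended two-layer
  near-wall formulations used by commercial codes resolve the buffer
  layer more gracefully; on the deliberately coarse grids used here the
  equilibrium treatment is the reproducible choice.
* **Boundaries**: the liquid surface is a shear-free slip plane with zero
  normal velocity (no free-surface deformation), the axis is a symmetry
  line, all other boundaries are no-slip walls.

### Impellers as quasi-steady moving walls

The reciprocating discs are not resolved as a moving mesh. The stroke
cycle is sampled at `n_snapshots` phases (default 2: top of stroke moving
down, bottom of stroke moving up) and one steady RANS problem is solved
per phase with the disc cells held at the instantaneous wall velocity
(triangular waveform: the constant set speed; sinusoidal: π/2 × set speed
at mid-stroke). Discs thinner than one cell are represented by a single
cell layer, the zero-thickness moving-wall limit. Cell-centred pressure
gradients never difference across disc cells (they fall back to one-sided
stencils at disc surfaces), which keeps the discretisation exactly
fore–aft symmetric: in a symmetric vessel the two stroke extremes produce
mirror-image fields to solver tolerance, a property the test suite
checks.

The quasi-steady reduction is the method's main modelling approximation.
It cannot represent stroke-reversal transients, so turbulence generated
by the deceleration/acceleration of the fluid column that travels with
the discs is absent. Fluid trapped between two co-moving discs
consequently appears quieter than it would be in a transient simulation;
the defective-space results below inherit that bias, which is why they
are read as trends across geometries rather than as absolute volumes.

## Tank presets and the open geometry choices

The reactor line's published operating points fix the working volumes
(2.4, 8 and 45 L), the 60 mm stroke, and the motion speeds (150 mm/s for
the smaller tanks; 200/300/400 mm/s candidates at 45 L). The tank
drawings are not public, so the presets make three explicit choices, all
overridable:

* **Aspect ratio 1.2** (liquid height / diameter), typical of stirred
  vessels.
* **Disc radius = half the tank radius**, thickness 5 mm.
* **Impeller placement**: two discs at 1/4 and 3/4 of the liquid height —
  one serving each half-column — and the three-disc variant adds the
  middle disc (1/4, 1/2, 3/4). The alternative of mounting the pair at
  1/3 and 2/3 was rejected because, with the fixed 60 mm stroke, it gives
  the two-disc tank nearly the same sweep coverage as the three-disc
  one, leaving the added impeller nothing to fix; the quarter-height
  layout leaves the mid-column gap that the third impeller then fills,
  which is the design logic the three-impeller proposal embodies.
* **Phase**: all discs move in phase, as they would on a single drive
  shaft. Antiphase motion is available (`motion_spec(in_phase = FALSE)`)
  but is geometrically impossible for the 2.4 L preset, where the disc
  separation is smaller than the stroke.

Every preset keeps the 60 mm stroke at every scale. Because the tanks are
geometrically similar while the stroke is fixed hardware, the swept
fraction of the liquid column shrinks as the tank grows — this is the
mechanism by which the defective space grows with scale, and it is a
deliberate property of the study conditions, not an artefact.

## Defective turbulent flow space

A cell is *active* in a snapshot when the classification field (default:
turbulent kinetic energy k) is at or above the threshold; the default
criterion is relative — 10 % of the volume-averaged k over the snapshot
ensemble — so it is invariant to overall intensity and comparable across
scales. Cells the disc occupies or sweeps through during the stroke are
always active: the impeller passes through them every cycle. The
defective space is the strict intersection of the inactive sets over all
snapshots; its volume (litres) and fraction of working volume are always
reported together with the criterion and the absolute cutoff it resolved
to, because the number is meaningless without them. No published numeric
value exists for this cutoff; 10 % is this package's convention.

Two exact properties anchor the implementation and are tested as such:
adding a snapshot can only shrink the defective space (intersection), and
raising the threshold can only grow it (monotone classification).

## Cross-scale speed matching

The published summary tables give volume-averaged turbulent energy and
shear stress per tank and speed. `match_speed()` formalizes the narrative
selection of an operating speed: each candidate row is scored by
`w_k·|Δk|/k_ref + w_τ·|Δτ|/τ_ref` (equal weights by default), the
minimal score wins, ties go to the lower speed (gentler shear is the
biologically conservative choice), and a candidate is "within band" when
both relative deviations are ≤ 10 %. On the printed rows this selects
300 mm/s for the 45 L two-impeller tank (deviations 3.5 % and 3.3 %) and
accepts the three-impeller tank at 200 mm/s (0.9 % and 1.8 %). The
`real_speed()` calibration maps commanded to measured impeller speeds by
monotone piecewise-linear interpolation with end-clamping, reflecting the
drive's plateau under load.

## Numerical choices

* **Floors**: k ≥ 10⁻¹⁰ m²/s², ε ≥ 10⁻¹² m²/s³; clipping events are
  counted in the diagnostics. A quiescent tank (zero impeller speed) is
  the exact fixed point: zero velocity with both fields at their floors.
* **Initialization** is deterministic: velocity and pressure zero,
  k₀ = 10⁻³ U² and ε₀ = C_μ^{3/4} k₀^{3/2} / (0.07 R) from the impeller
  speed U and tank radius R. There is no randomness anywhere in the
  solver; seeds appear only in the synthetic-data generator's patch
  jitter.
* **Convergence** is declared when all normalized residuals (continuity,
  both momenta, k, ε) fall below the tolerance (default 10⁻⁵); residual
  norms are scaled against a reference built from the velocity and
  turbulence scales so that quiescent and low-speed problems do not
  divide by zero. Divergence (non-finite fields or sustained residual
  growth) raises an error carrying the residual history.
* **Linear systems** are solved directly (sparse LU via `Matrix`), which
  is exact and fast at the problem sizes used (≤ a few thousand cells).
* **Degenerate inputs** are rejected up front: non-positive volumes,
  impellers whose stroke envelope leaves the liquid column, grids too
  coarse to resolve a disc, non-monotone speed calibrations.

## Verification

The solver is verified, not validated: analytic and manufactured
solutions check that the discretisation solves the intended equations at
the intended order.

* **Channel flows**: plane Couette and Poiseuille on a 64-cell gap are
  recovered to well under 1 % (Couette to machine precision, since the
  linear profile is in the discrete solution space).
* **Manufactured solutions**: smooth trigonometric fields for u, w, p, k,
  ε on the unit square, with source terms derived by symbolic
  differentiation (`stats::D`) of the ansatz through the full model —
  including μ_t(k, ε), the production term, and the ε sink. A
  high-order (fourth-order stencil) numerical substitution independently
  confirms the symbolic sources to ~10⁻¹⁰ relative. Driving the solver
  with these sources, the L2 errors of k and ε fall at close to second
  order between 16² and 32² grids, as do u and w for the laminar momentum
  variant. Manufactured-solution parameters are chosen to keep k and ε
  positive, η below the C₁ switch (so the source stays smooth), the
  production limiter inactive, and cell Peclet numbers below the hybrid
  switch.
* **Symmetry and scaling**: mirror-image stroke extremes in a symmetric
  vessel, and linear velocity scaling with impeller speed in the Stokes
  regime, both hold to tight tolerances.

## Problem sizes

The end-to-end defective-space comparisons run the four presets on
20 × 36 cell grids with two snapshots each; at these sizes a full
four-tank comparison completes in a few minutes on one core, and the
qualitative conclusions (see below) were checked to be unchanged on
16 × 28 and 24 × 44 grids before the sizes were frozen. These grids are
far coarser than engineering practice for quantitative predictions;
they are chosen so that the full analysis is reproducible at desk scale.

## What the synthetic generator does and does not emulate

`make_field()` produces analytic velocity fields (uniform, solid-body
rotation, simple shear, stream-function vortex) with closed-form strain
rate and vorticity, and piecewise-constant "patchy" k/ε fields whose
active patches are snapped to grid faces so their volumes are exact under
the annular cell weighting. These exercise every post-processing stage
cell-exactly. They do not emulate realistic turbulence: no spectra, no
intermittency, no wall layers. Passing the synthetic tests therefore
demonstrates the correctness of the derived-field algebra, the mask
logic, and the volume accounting — not the fidelity of the RANS fields
themselves, which rests on the verification cases above and on the
closure's known domain of validity.

## Known limitations

* 2D axisymmetry suppresses azimuthal structure; swirl is absent because
  the discs do not rotate, but real tanks develop non-axisymmetric
  instabilities that the model cannot see.
* The quasi-steady snapshot reduction under-represents turbulence between
  co-moving discs and ignores stroke-reversal transients (above).
* k–ε closures over-produce turbulent energy at stagnation points (the
  region under the free surface where the upward jet turns); the
  production limiter bounds but does not remove this.
* Absolute defective volumes depend on the 10 % criterion and on the
  preset geometry; only their ordering across scales and configurations
  is treated as a result.
* The published per-tank averages (e.g. 0.0113 m²/s² at 8 L working
  volume) come from transient 3D simulations of the true, undisclosed
  geometry; this package's coarse axisymmetric fields are not expected to
  reproduce them numerically, and the speed-matching results are computed
  from the published rows, not from re-simulation. Relatedly, the
  published Kolmogorov column is not consistent with applying
  λ = (ν³/ε)^¼ to the published dissipation column (ε = 0.062 m²/s³
  gives 144 μm where 201 μm is printed), so the averaging order behind
  those tables is unknown; both averaging orders are implemented
  (`average-of-field`, `field-of-average`) and neither is claimed to
  reproduce the printed λ. The same applies to the shear-stress scale:
  the printed τ values are two orders of magnitude above μ·γ̇ at the
  printed shear rates, which is why the default stress mode is the
  turbulence-augmented (μ + μ_t)·γ̇, with the literal molecular product
  available as `mode = "molecular"`.
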