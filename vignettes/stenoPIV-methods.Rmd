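---
title: "Echo PIV of stenotic phantoms: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Echo PIV of stenotic phantoms: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

stenoPIV is a fully synthetic testbed for ultrasound particle image
velocimetry (Echo PIV) of pulsatile flow through stenosed vessel phantoms.
The chain it implements is: a parametric stenosis geometry; a rigid-wall
incompressible Navier-Stokes reference solver; a microbubble image generator
whose tracer motion is known exactly; a multi-pass cross-correlation PIV
engine; and shear-stress / wall-shear-stress (WSS) extraction, compared
between the PIV measurement and the reference solution across stenosis
severities.  This vignette records the models, the tunable parameters, the
numerical choices and the limitations.

## Phantom geometry

The lumen is a straight tube of radius $R_0$ (default 2.5 mm, i.e. a 5 mm
inner diameter) carrying one axisymmetric plaque-like constriction of axial
extent $L_p$ (default 8 mm) centred at $x = 0$.  The half-width follows a
raised-cosine taper,
$$h(x) = R_0 - (R_0 - r_t)\,\tfrac12\!\left(1 + \cos\tfrac{2\pi x}{L_p}\right),
\qquad |x| < L_p/2,$$
which is $C^1$ at the plaque edges — the solver metric terms and the wall
normals need a continuous slope, and a mould rod with "progressively
decreasing diameters" is well idealised by a smooth bump.

**Severity basis.** A quoted stenosis percentage can mean area or diameter
reduction.  We default to **area** ($r_t = R_0\sqrt{1-s}$): with a 16 L/h
cycle-mean inflow, continuity then puts throat velocities in the
tens-to-low-hundreds of cm/s, the physiologically and experimentally familiar
range, whereas a 70 % *diameter* reduction would demand a mean throat
velocity above 2.5 m/s.  The basis is configurable
(`severityBasis = "diameter"`).

`bumpSide = "one_sided"` is available for image realism (clinical plaques are
eccentric); the solver requires the symmetric variant, since its formulation
exploits the axis/centreline symmetry.

## Fluid, pump waveform and the viscosity discrepancy

The working fluid is Newtonian with $\rho = 1000$ kg/m$^3$ and
$\mu = 0.0087$ Pa s by default — the nominal figure for the phantom
experiments this testbed emulates.  That value is ten times the viscosity of
water at 26 °C, and it matters: the laminar entrance length
$L = 0.06\,\mathrm{Re}\,D$ for a 5 mm tube at 45 cm/s reaches the quoted
"at least 70 cm" only with $\mu \approx 8.7\times10^{-4}$ Pa s.  We treat
the factor-of-ten as a probable transcription slip but do not silently
correct it: the default stays 0.0087 (which conveniently keeps the inlet
Reynolds number near 130–260, safely inside the solver's laminar comfort
zone), and `FluidProperties(viscosity = 8.7e-4)` reproduces the entrance
length statement.

The pump waveform is a stylised surrogate (the real recorded waveforms are
not available numerically): a raised-cosine systolic pulse over the first
35 % of a 2 s cycle on a constant diastolic baseline, scaled in closed form
so the cycle mean is exactly 16 L/h and the systolic peak is
`peakFactor` times the mean.  The default `peakFactor = 2` makes the
systolic-peak mean velocity about 45 cm/s, reconciling the quoted mean
velocity with the quoted cycle-mean flow (which alone gives 22.6 cm/s).

Pulsatility is handled **quasi-steadily**: at 30 cycles/min the Womersley
number of a 5 mm tube is small, so each sampled phase is an independent
steady solve at the instantaneous flow rate (`quasiSteadyCycle`).  A full
transient arbitrary-Lagrangian-Eulerian run is out of scope, as is any
moving-wall coupling — the grid velocity in the momentum balance is
identically zero.

## The reference solver

`solveStenoticSteady` integrates steady incompressible flow in
stream-function-vorticity form on a wall-fitted grid
$(\xi = x,\ \eta = r/h(x))$, so the wall is a coordinate line and
continuity is satisfied identically: the volumetric flux through *every*
cross-section equals $2\pi(\psi_w - \psi_0)$ exactly by construction (the
basis of the `sectionFlux(method = "stream")` check).  The default mode is
axisymmetric (Stokes stream function); a planar channel mode exists and
matches the axisymmetric mean inlet velocity.

Numerics, in brief:

* Diffusion and the metric cross-terms: central differences; convection:
  first-order upwind.  Upwinding is diffusive but unconditionally robust on
  the coarse desk-scale grids used here; the straight-tube verification
  (≤ 1 % L2 against the analytic parabola) is unaffected because the exact
  solution has no cross-stream convection.
* Boundary conditions: parabolic inflow, zero-gradient outflow, symmetry on
  the axis, no slip on the wall via a Thom-type wall-vorticity condition
  generalised to the mapped grid,
  $\omega_w = -\frac{1+h'^2}{h^2}\,\frac{2(\psi_{N-1}-\psi_w)}{\Delta\eta^2}\,h^{-\alpha}$.
* The nonlinear system is iterated with under-relaxed Picard steps; each
  step solves the two linear systems by sparse LU (Matrix).  The wall
  vorticity is relaxed at 0.4 times the interior factor — the Thom feedback
  loop is the stiffest mode and diverges at equal relaxation.  When the
  residual stalls in a limit cycle (seen on finer grids), the relaxation is
  halved automatically and iteration continues.
* Defaults: `relax = 0.3`, `tol = 1e-6` (relative vorticity change),
  `maxIter = 2000`, grid 161 × 41.  Non-convergence raises an error carrying
  the residual history.  An inlet Reynolds number above 500 is flagged in
  the provenance (attached to every solved field) — beyond that the steady
  laminar assumption itself becomes doubtful.

## Synthetic microbubble images

The generator's aim is exact ground truth, not acoustic realism.  Tracers
are seeded uniformly over the lumen with Poisson-distributed count
(`particleDensity` per mm²), advected through the bilinearly interpolated
velocity field by classical RK4 (velocities vanish outside the lumen, so
tracers cannot cross walls), and rendered as isotropic Gaussian blobs
(`psfSigma = 1.5` px) at sub-pixel positions with additive Gaussian noise
and 16-bit clipping.  Out-of-plane loss is modelled as i.i.d. per-frame
dropout with re-seeding; tracers leaving downstream are recycled upstream,
and the seeded region extends an axial margin beyond the field of view so
that inflow carries real tracers — without that margin, edge windows
correlate against voids and produce spurious vectors.

Two parameters deserve comment:

* **`particleDensity` (default 40/mm²).**  At the default 0.02 mm/px pitch a
  32 px window covers 0.41 mm², so 40/mm² gives the classical 15–20 tracers
  per window needed for robust correlation peaks.  (The bulk 3-D bubble
  concentration of a real experiment does not map uniquely onto a 2-D image
  density; this is an imaging-plane choice.)
* **`interframeScale` (default 1).**  At 150 fps a 1 m/s jet moves tracers
  hundreds of pixels between frames — untrackable with 32 px windows, and
  how a real high-frame-rate acquisition achieves trackable displacements is
  not modelled here.  The scale is an explicit surrogate for a shorter
  effective inter-frame interval: displacement per frame is
  `v * interframeScale / frameRate`.  `generateStack` warns when the
  expected maximum displacement exceeds 8 px, and `runSweep` reduces the
  scale automatically (targeting 6 px/frame) and records the value used.

What the generator does **not** emulate: speckle statistics, bubble
oscillation and disruption, depth-dependent point-spread functions, scan
conversion, clutter.  Passing tests therefore demonstrate the correctness of
the algorithmic chain on idealised images, not performance on clinical
B-mode data.

## The PIV engine

One vector per interrogation window (default 32 px, 50 % overlap) per frame
pair:

1. **Correlation.**  Zero-mean normalised cross-correlation evaluated at
   every lag within ± (window/2 − 1) px.  The coefficient is computed over
   the per-lag *overlap region* of the two windows (zero-padded linear
   correlation with overlap means and variances, all via FFT).  Plain
   circular correlation with global normalisation biases the peak toward
   zero lag by roughly 0.2 px at half-pixel shifts; the overlap-normalised
   form removes that bias and keeps values in [−1, 1], invariant to affine
   intensity changes.  Ties are broken deterministically toward the
   smallest-magnitude lag.  Windows without texture are flagged rejected.
2. **Sub-pixel estimation.**  Three-point Gaussian peak fit per axis,
   $\delta = \frac{\ln c_- - \ln c_+}{2\ln c_- - 4\ln c_0 + 2\ln c_+}$,
   exact for samples of any Gaussian.  Non-positive samples or an off-centre
   maximum degrade that axis to integer precision; a peak at the edge of the
   searched lag range falls back to the integer lag.
3. **Validation.**  Each vector is compared per component against the median
   of its 3 × 3 neighbourhood (borders use the available neighbours) and
   rejected when the deviation exceeds
   $\max(\texttt{filterFloor}, \texttt{filterK}\cdot\mathrm{MAD})$;
   rejected vectors are replaced by the neighbourhood median, flagged, and
   keep their original estimate.  The median/MAD form is used because a
   mean-based surround test is contaminated by the very outlier being
   tested; a mean variant remains available (`filterStat = "mean"`).  Known
   weakness: on strong uniform gradients the MAD of a small border
   neighbourhood can collapse to zero and good edge vectors get replaced by
   their neighbours' median; such vectors are flagged `replaced`, so
   downstream consumers can weight them accordingly.
4. **Multi-pass window deformation.**  Pass schedule 2w → w → w (default
   64/32/32): early passes capture large displacements, later passes warp
   the second frame by the smoothed, bilinearly interpolated predictor field
   and only measure the residual, which is what makes strong velocity
   gradients tractable.  Each pass ends with validation.

`toVelocity` converts px/frame to cm/s via the pixel pitch, frame rate and
`interframeScale`, mapping window centres to mm; `phaseAverage` pools
repeated cycles at matched phase using valid and replaced vectors only and
retains the across-cycle SD per vector.  `maskToLumen` is the
region-of-interest step (replacing a manual ROI): vectors outside the lumen
— whose windows contain only noise — are masked out.

## Shear stress and wall shear stress

The stress field is the planar shear component
$\tau = \mu\left(\partial v/\partial x + \partial u/\partial y\right)$,
evaluated with central differences inside the lumen mask and second-order
one-sided differences at mask boundaries, so exterior values never enter a
stencil.  This component (rather than the full traction vector) is the
primary definition for fidelity with how such measurements are usually
reported; it is exact on affine fields and underestimates the true wall
traction on steeply inclined walls, which is why a wall-normal
tangential-gradient option exists (`method = "normal"`, using the no-slip
condition as the wall sample: $\partial u_t/\partial n \approx
(4u_1 - u_2)/2\delta$, exact for quadratic profiles).

Wall series sample one grid step inside the wall along the inward normal and
by default linearly extrapolate the one- and two-step samples back to the
wall — exact for the linear near-wall stress of developed flow.  For PIV
fields the first sample is taken **two vector spacings** inside
(`offsetSteps = 2`): windows that straddle the wall see only lumen tracers
and overestimate near-wall velocity, so samples must clear the half-window
contamination zone.  With that offset the Poiseuille closed form
$\tau_w = 4\mu\bar v/R$ is recovered within a few percent end-to-end.
Magnitudes are reported; series are split upstream/downstream at the throat.

## Pipeline, metrics and problem sizes

`runSweep` orchestrates the severity sweep (defaults 30/50/70 %): steady
reference solve at the systolic peak, a short burst of frames at that phase
per pump cycle with fresh tracer seeding (cycles are then independent
realisations, giving the mean ± SD reporting), multi-pass PIV on the burst
pairs, phase averaging, and WSS extraction from both sources.  Reference
fields are interpolated to the coarser PIV grid, never the reverse.
Agreement is quantified by bias, RMSE, normalised RMSE and peak-velocity
ratio rather than a significance test: with synthetic replicates a p-value
would test the generator, not the measurement chain.

The default verification sizes were chosen to resolve the relevant gradients
while keeping a laptop-class run: solver grids 97 × 25 to 193 × 49,
300 × 500 px frames for the straight-tube chain, 240 × 480 px for the sweep,
two PIV pairs per cycle over three cycles.  Under these conditions the
package's own acceptance checks hold: straight-tube L2 error ≤ 1 %, flux
conservation at the 10⁻⁶ level, known-shift recovery below 0.1 px, solver
and PIV wall shear within 5 % and 10 % of $4\mu\bar v/R$, strictly
increasing peak velocity and maximum WSS across 30/50/70 %, upstream WSS
maxima at least the downstream maxima on solver fields, and bit-identical
reports under a fixed seed.  Of note, the PIV-derived maximum WSS is
systematically below the solver's at the higher severities — the vector
grid cannot resolve the throat's thin shear layer — mirroring the familiar
observation that Echo PIV underestimates WSS relative to CFD.

## Limitations

* Rigid walls: no fluid-structure interaction, no diameter expansion; the
  known softening effect of elastic walls on velocities and WSS is outside
  the model.
* Newtonian fluid; no shear-thinning rheology.
* Quasi-steady pulsatility; no transient inertia, no turbulence model (the
  solver warns above Re ≈ 500).
* The waveform, tracer density and inter-frame scaling are explicit
  surrogates; quantitative peak velocities and WSS from the original phantom
  experiments are not reproducible from published information, so
  cross-severity *orderings* and closed-form limits are the verifiable
  content.
* Oscillatory shear index, stress phase angle and wall shear gradient are
  not computed.
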