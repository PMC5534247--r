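# stenoPIV

Hemodynamic shear stress is a key determinant of where atherosclerotic
plaques form and whether they rupture, and ultrasound particle image
velocimetry (Echo PIV) is one of the few ways to measure it non-invasively:
contrast microbubbles are imaged at high frame rate and their displacements
recovered by windowed cross-correlation.  Validating such a measurement
chain is hard, because the true velocity field inside a real vessel or
phantom is never known exactly.

stenoPIV is an R package that closes that loop synthetically, end to end,
for pulsatile flow through stenosed carotid-style phantoms (5 mm lumen, 8 mm
plaque, 30/50/70 % severity, 16 L/h cycle-mean flow at 30 cycles/min with a
35/65 systole/diastole split):

* **Geometry** — a parametric stenosis phantom with raised-cosine plaque,
  wall curves and lumen masks (`StenosisPhantom`, `wallCurves`,
  `lumenMask`);
* **Reference flow** — a pulsatile pump waveform and a rigid-wall
  incompressible Navier–Stokes solver in stream-function–vorticity form on
  a wall-fitted grid, so mass conservation is exact by construction
  (`PulsatileWaveform`, `solveStenoticSteady`, `quasiSteadyCycle`);
* **Synthetic imaging** — microbubble image stacks with exact ground-truth
  motion: Poisson seeding, RK4 advection, Gaussian point-spread rendering,
  noise and out-of-plane dropout (`generateStack`);
* **Echo PIV** — multi-pass, window-deformation cross-correlation with
  overlap-normalised ZNCC, three-point Gaussian sub-pixel peak fitting and
  robust median/MAD vector validation (`pivMultipass`, `znccMap`,
  `gaussianSubpixel`, `validateVectors`);
* **Shear stress** — the planar shear component
  τ = μ(∂v/∂x + ∂u/∂y) and wall-shear-stress series along the plaque
  (`shearField`, `wallShear`, `wssSummary`), for Poiseuille flow recovering
  the closed form τ_w = 4 μ v̄ / R;
* **Pipeline** — a deterministic severity sweep comparing PIV against the
  solver with bias/RMSE/peak-ratio metrics, transect profiles, WSS tables,
  CSV/TIFF/JSON artifacts and figures (`runSweep`), plus a thin CLI in
  `inst/cli/stenopiv.R`.

## Worked example

```r
library(stenoPIV)

## entrance length needed for developed flow: 5 mm tube, 45 cm/s, water 26 C
entranceLength(5e-3, 0.45, FluidProperties(viscosity = 8.7e-4))
#> [1] 0.7758621        # metres -> the quoted "at least 70 cm"

## a severity sweep at desk scale (about half a minute)
cfg <- SweepConfig(
  severities = c(0.3, 0.5, 0.7), nCycles = 3L, seed = 11L,
  imaging = ImagingConfig(fovDepth = 6, fovWidth = 12, imageRows = 240L,
                          imageCols = 480L, particleDensity = 40),
  solver  = list(nAxial = 97L, nRadial = 25L))
rep <- runSweep(cfg, pairsPerCycle = 2L)
for (e in rep$severities)
  cat(sprintf("%.0f%%: solver peak %5.1f cm/s | PIV %5.1f +- %4.2f | max WSS %5.1f (solver) %5.1f (PIV) Pa\n",
      100 * e$severity, e$peakVelocitySolver_cm_s,
      e$peakVelocityPIV_cm_s$mean, e$peakVelocityPIV_cm_s$sd,
      e$maxWSSSolver_pa, e$maxWSSPIV_pa))
#> 30%: solver peak 103.6 cm/s | PIV 102.4 +- 0.42 | max WSS  19.3 (solver)  11.4 (PIV) Pa
#> 50%: solver peak 127.5 cm/s | PIV 126.3 +- 0.65 | max WSS  40.3 (solver)  17.4 (PIV) Pa
#> 70%: solver peak 192.8 cm/s | PIV 192.0 +- 0.46 | max WSS  88.5 (solver)  29.4 (PIV) Pa
```

Reading the output: peak velocity at the systolic peak rises steeply with
severity (the Venturi effect through the narrowing throat), the PIV
measurement tracks the reference within about a percent with a small
across-cycle spread, and the maximum wall shear stress rises with severity
for both sources.  The PIV-derived WSS sits well below the solver's — the
32 px vector grid cannot resolve the thin shear layer at the throat — the
same systematic underestimate familiar from comparisons of Echo PIV against
CFD.  On solver fields the WSS maximum sits just *upstream* of the throat,
on the accelerating face of the plaque.

The pump waveform, tracer density and inter-frame displacement scaling are
explicit surrogates for unavailable experimental detail; see the methods
vignette (`vignettes/stenoPIV-methods.Rmd`) for every model, parameter and
limitation.

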