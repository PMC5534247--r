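# Shared fixtures, all generated in code at test time.

# Small imaging configuration for fast PIV tests (0.02 mm/px pitch).
fixImaging <- function(rows = 128L, cols = 128L, ...) {
  args <- list(fovDepth = rows * 0.02, fovWidth = cols * 0.02,
               imageRows = rows, imageCols = cols,
               noiseSigma = 0, dropoutRate = 0, particleDensity = 40)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(ImagingConfig, args)
}

# A particle ensemble filling the (frame + margin) region uniformly.
fixEnsemble <- function(imaging, seed = 1L, marginFrac = 0.15) {
  set.seed(seed)
  xw <- imaging@fovWidth / 2 * (1 + marginFrac)
  yw <- imaging@fovDepth / 2 * (1 + marginFrac)
  n <- round(imaging@particleDensity * 4 * xw * yw)
  new("ParticleEnsemble", x = stats::runif(n, -xw, xw),
      y = stats::runif(n, -yw, yw),
      intensity = stats::runif(n, 0.5, 1), seed = as.integer(seed))
}

# Render a frame pair in which every tracer moves by exactly (dxPx, dyPx).
fixShiftedPair <- function(dxPx, dyPx, imaging = fixImaging(), seed = 1L) {
  ens1 <- fixEnsemble(imaging, seed = seed)
  p <- pixelPitch(imaging)
  ens2 <- new("ParticleEnsemble", x = ens1@x + dxPx * p, y = ens1@y + dyPx * p,
              intensity = ens1@intensity, seed = ens1@seed)
  list(a = renderFrame(ens1, imaging), b = renderFrame(ens2, imaging))
}

# Frame pair with a linear horizontal-displacement shear du/dy (px/px).
fixShearPair <- function(slope, imaging = fixImaging(cols = 256L), seed = 3L) {
  ens1 <- fixEnsemble(imaging, seed = seed)
  p <- pixelPitch(imaging)
  ypx <- (ens1@y + imaging@fovDepth / 2) / p - 0.5
  mid <- (imaging@imageRows - 1) / 2
  ens2 <- new("ParticleEnsemble", x = ens1@x + slope * (ypx - mid) * p,
              y = ens1@y, intensity = ens1@intensity, seed = ens1@seed)
  list(a = renderFrame(ens1, imaging), b = renderFrame(ens2, imaging),
       truth = function(field) {
         matrix(rep(slope * (field@yPx - mid), each = length(field@xPx)),
                length(field@xPx))
       })
}

# Cached end-to-end Poiseuille measurement (stack -> multipass PIV -> cm/s),
# shared between the property and acceptance suites.
.poiseuille_cache <- new.env()
fixPoiseuillePIV <- function() {
  if (!is.null(.poiseuille_cache$res)) return(.poiseuille_cache$res)
  fluid <- FluidProperties()
  phantom <- StenosisPhantom(severity = 0)
  Q <- 16e-3 / 3600
  truth <- poiseuilleField(Q, phantom, nx = 201, ny = 81)
  imaging <- ImagingConfig(fovDepth = 6, fovWidth = 10, imageRows = 300L,
                           imageCols = 500L, interframeScale = 0.04,
                           noiseSigma = 0.02, dropoutRate = 0.02,
                           particleDensity = 40)
  stack <- generateStack(phantom, truth, imaging, nCycles = 1,
                         period = 4 / 150, seed = 7)
  cfg <- PIVConfig()
  fields <- lapply(seq_len(nFrames(stack) - 1), function(k)
    pivMultipass(frames(stack)[[k]], frames(stack)[[k + 1]], cfg))
  avg <- phaseAverage(fields, framesPerCycle = 1L)[[1]]
  vel <- maskToLumen(toVelocity(avg, imaging), phantom)
  .poiseuille_cache$res <- list(
    fluid = fluid, phantom = phantom, Q = Q, truth = truth,
    imaging = imaging, fields = fields, avg = avg, vel = vel,
    vbar = Q / (pi * 2.5e-3^2),
    tauExact = 4 * fluid@viscosity * (Q / (pi * 2.5e-3^2)) / 2.5e-3)
  .poiseuille_cache$res
}

# Cached solver severity sweep at the systolic-peak flow (small grid).
.sweep_cache <- new.env()
fixSolverSweep <- function() {
  if (!is.null(.sweep_cache$res)) return(.sweep_cache$res)
  fluid <- FluidProperties()
  qPeak <- 2 * 16e-3 / 3600
  res <- lapply(c(0.3, 0.5, 0.7), function(s) {
    ph <- StenosisPhantom(severity = s)
    f <- solveStenoticSteady(NavierStokesProblem(
      ph, fluid = fluid, flowRate = qPeak, nAxial = 97L, nRadial = 25L))
    list(severity = s, phantom = ph, field = f,
         walls = wallCurves(ph, 201L))
  })
  .sweep_cache$res <- list(fluid = fluid, qPeak = qPeak, runs = res)
  .sweep_cache$res
}
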