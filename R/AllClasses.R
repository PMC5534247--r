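#' @import methods
NULL

.enum_ok <- function(x, choices) length(x) == 1L && !is.na(x) && x %in% choices

#' Parametric stenosed-vessel phantom geometry
#'
#' Describes the lumen of a straight vessel phantom carrying a single
#' plaque-like constriction centred at the axial origin.  The lumen half-width
#' equals \code{inletRadius} outside the plaque extent and tapers smoothly
#' (raised cosine) to the throat value at \code{x = 0}.  Severity is the
#' fractional lumen reduction at the throat, interpreted on an area basis by
#' default (throat radius \eqn{= R_0\sqrt{1-s}}) or a diameter basis
#' (\eqn{R_0(1-s)}).
#'
#' Coordinates are millimetres: \code{x} axial (positive downstream, origin at
#' the throat), \code{y} transverse.
#'
#' @slot inletRadius unobstructed lumen radius, mm.
#' @slot wallThickness phantom wall thickness, mm (metadata only).
#' @slot plaqueLength axial extent of the constriction, mm.
#' @slot severity fractional lumen reduction at the throat, in [0, 1).
#' @slot severityBasis \code{"area"} or \code{"diameter"}.
#' @slot bumpSide \code{"symmetric"} (both walls indent) or \code{"one_sided"}
#'   (upper wall only).
#' @slot domainLength axial extent of the modelled domain, mm, throat-centred.
#' @export
setClass("StenosisPhantom",
  representation(
    inletRadius   = "numeric",
    wallThickness = "numeric",
    plaqueLength  = "numeric",
    severity      = "numeric",
    severityBasis = "character",
    bumpSide      = "character",
    domainLength  = "numeric"
  ),
  prototype(
    inletRadius = 2.5, wallThickness = 1.0, plaqueLength = 8.0,
    severity = 0, severityBasis = "area", bumpSide = "symmetric",
    domainLength = 40
  ),
  validity = function(object) {
    msg <- character()
    if (!(object@inletRadius > 0)) msg <- c(msg, "inletRadius must be > 0")
    if (!(object@plaqueLength > 0)) msg <- c(msg, "plaqueLength must be > 0")
    if (!(object@severity >= 0 && object@severity < 1))
      msg <- c(msg, "severity must lie in [0, 1)")
    if (!.enum_ok(object@severityBasis, c("area", "diameter")))
      msg <- c(msg, "severityBasis must be 'area' or 'diameter'")
    if (!.enum_ok(object@bumpSide, c("symmetric", "one_sided")))
      msg <- c(msg, "bumpSide must be 'symmetric' or 'one_sided'")
    if (!(object@domainLength > object@plaqueLength))
      msg <- c(msg, "domainLength must exceed plaqueLength")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname StenosisPhantom-class
#' @param inletRadius,wallThickness,plaqueLength,severity,severityBasis,bumpSide,domainLength
#'   see the corresponding slots.
#' @return a validated \code{StenosisPhantom}.
#' @examples
#' StenosisPhantom(severity = 0.7)
#' @export
StenosisPhantom <- function(inletRadius = 2.5, wallThickness = 1.0,
                            plaqueLength = 8.0, severity = 0,
                            severityBasis = c("area", "diameter"),
                            bumpSide = c("symmetric", "one_sided"),
                            domainLength = 40) {
  new("StenosisPhantom",
      inletRadius = inletRadius, wallThickness = wallThickness,
      plaqueLength = plaqueLength, severity = severity,
      severityBasis = match.arg(severityBasis),
      bumpSide = match.arg(bumpSide), domainLength = domainLength)
}

#' Newtonian fluid properties
#'
#' @slot density kg/m^3.
#' @slot viscosity dynamic viscosity, Pa s.
#' @export
setClass("FluidProperties",
  representation(density = "numeric", viscosity = "numeric"),
  prototype(density = 1000, viscosity = 0.0087),
  validity = function(object) {
    if (!(object@density > 0)) return("density must be > 0")
    if (!(object@viscosity > 0)) return("viscosity must be > 0")
    TRUE
  }
)

#' @rdname FluidProperties-class
#' @param density,viscosity see slots.
#' @export
FluidProperties <- function(density = 1000, viscosity = 0.0087)
  new("FluidProperties", density = density, viscosity = viscosity)

#' Pulsatile pump waveform
#'
#' A stylised periodic flow waveform: a raised-cosine systolic pulse over the
#' systolic fraction of the cycle on top of a constant diastolic baseline,
#' scaled so the cycle-mean flow equals \code{meanFlow} and the systolic peak
#' equals \code{peakFactor * meanFlow}.
#'
#' @slot period cycle period, s.
#' @slot systolicFraction fraction of the cycle spent in systole.
#' @slot meanFlow cycle-mean volumetric flow rate, m^3/s.
#' @slot peakFactor ratio of the systolic-peak flow to the cycle mean.
#' @export
setClass("PulsatileWaveform",
  representation(period = "numeric", systolicFraction = "numeric",
                 meanFlow = "numeric", peakFactor = "numeric"),
  prototype(period = 2.0, systolicFraction = 0.35,
            meanFlow = 16e-3 / 3600, peakFactor = 2.0),
  validity = function(object) {
    msg <- character()
    if (!(object@period > 0)) msg <- c(msg, "period must be > 0")
    if (!(object@systolicFraction > 0 && object@systolicFraction < 1))
      msg <- c(msg, "systolicFraction must lie in (0, 1)")
    if (!(object@meanFlow >= 0)) msg <- c(msg, "meanFlow must be >= 0")
    if (!(object@peakFactor >= 1))
      msg <- c(msg, "peakFactor must be >= 1 (peak cannot fall below the mean)")
    # baseline must stay non-negative
    f <- object@systolicFraction
    qd <- (1 - f * object@peakFactor / 2) / (1 - f / 2)
    if (qd < 0)
      msg <- c(msg, "peakFactor too large: diastolic baseline would be negative")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname PulsatileWaveform-class
#' @param period,systolicFraction,meanFlow,peakFactor see slots.
#' @export
PulsatileWaveform <- function(period = 2.0, systolicFraction = 0.35,
                              meanFlow = 16e-3 / 3600, peakFactor = 2.0)
  new("PulsatileWaveform", period = period, systolicFraction = systolicFraction,
      meanFlow = meanFlow, peakFactor = peakFactor)

#' Planar velocity field on a regular grid
#'
#' The shared currency between the reference solver, the PIV engine and the
#' shear-stress module.  \code{u} and \code{v} are the axial and transverse
#' velocity components in cm/s, stored as matrices of dimension
#' \code{c(length(x), length(y))}; both are zero outside the lumen mask.
#'
#' @slot x,y grid axes, mm.
#' @slot u,v velocity components, cm/s, dim \code{c(length(x), length(y))}.
#' @slot time phase time stamp, s.
#' @slot mask logical lumen-interior matrix, same dim as \code{u}.
#' @export
setClass("VelocityField",
  representation(x = "numeric", y = "numeric", u = "matrix", v = "matrix",
                 time = "numeric", mask = "matrix"),
  validity = function(object) {
    d <- c(length(object@x), length(object@y))
    msg <- character()
    if (!identical(dim(object@u), as.integer(d)) ||
        !identical(dim(object@v), as.integer(d)) ||
        !identical(dim(object@mask), as.integer(d)))
      msg <- c(msg, "u, v and mask must have dim c(length(x), length(y))")
    if (!all(is.finite(object@u)) || !all(is.finite(object@v)))
      msg <- c(msg, "u and v must be finite everywhere")
    if (length(msg) == 0 &&
        (any(object@u[!object@mask] != 0) || any(object@v[!object@mask] != 0)))
      msg <- c(msg, "velocity must vanish outside the lumen mask")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname VelocityField-class
#' @param x,y,u,v,time,mask see slots; \code{mask} defaults to all-interior.
#' @export
VelocityField <- function(x, y, u, v = NULL, time = 0, mask = NULL) {
  if (is.null(v)) v <- matrix(0, length(x), length(y))
  if (is.null(mask)) mask <- matrix(TRUE, length(x), length(y))
  u[!mask] <- 0; v[!mask] <- 0
  new("VelocityField", x = as.numeric(x), y = as.numeric(y),
      u = u, v = v, time = time, mask = mask)
}

#' Rigid-wall steady Navier-Stokes problem definition
#'
#' Inputs for \code{\link{solveStenoticSteady}}: geometry, fluid, inflow and
#' discretisation / iteration controls for the stream-function-vorticity
#' solver.  The grid velocity and body force of the general moving-mesh
#' momentum balance are fixed at zero (rigid wall).
#'
#' @slot phantom a \code{StenosisPhantom}.
#' @slot fluid a \code{FluidProperties}.
#' @slot flowRate volumetric inflow, m^3/s.
#' @slot mode \code{"axisymmetric"} (Stokes stream function) or \code{"planar"}.
#' @slot nAxial,nRadial grid points along the axis / across the half-lumen.
#' @slot maxIter maximum outer (Picard) iterations.
#' @slot relax under-relaxation factor for the vorticity update, in (0, 1].
#' @slot tol relative vorticity-residual convergence tolerance.
#' @export
setClass("NavierStokesProblem",
  representation(phantom = "StenosisPhantom", fluid = "FluidProperties",
                 flowRate = "numeric", mode = "character",
                 nAxial = "integer", nRadial = "integer",
                 maxIter = "integer", relax = "numeric", tol = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!(object@flowRate >= 0)) msg <- c(msg, "flowRate must be >= 0")
    if (!.enum_ok(object@mode, c("axisymmetric", "planar")))
      msg <- c(msg, "mode must be 'axisymmetric' or 'planar'")
    if (object@nAxial < 16L || object@nRadial < 8L)
      msg <- c(msg, "grid too coarse: need nAxial >= 16, nRadial >= 8")
    if (!(object@tol > 0)) msg <- c(msg, "tol must be > 0")
    if (!(object@relax > 0 && object@relax <= 1))
      msg <- c(msg, "relax must lie in (0, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname NavierStokesProblem-class
#' @param phantom,fluid,flowRate,mode,nAxial,nRadial,maxIter,relax,tol see slots.
#' @export
NavierStokesProblem <- function(phantom, fluid = FluidProperties(),
                                flowRate = 16e-3 / 3600,
                                mode = c("axisymmetric", "planar"),
                                nAxial = 161L, nRadial = 41L,
                                maxIter = 2000L, relax = 0.3, tol = 1e-6)
  new("NavierStokesProblem", phantom = phantom, fluid = fluid,
      flowRate = flowRate, mode = match.arg(mode),
      nAxial = as.integer(nAxial), nRadial = as.integer(nRadial),
      maxIter = as.integer(maxIter), relax = relax, tol = tol)

#' Imaging configuration for synthetic microbubble frames
#'
#' Defaults emulate a high-frequency small-animal scanner: 150 fps over a
#' 7 mm (depth) by 15 mm (width) field of view at 0.02 mm/px.  Image row 0 is
#' the shallowest depth (smallest \code{y}); pixel centres sit at integer
#' 0-based coordinates.
#'
#' @slot frameRate frames per second.
#' @slot fovDepth,fovWidth field of view, mm (depth maps to image rows).
#' @slot imageRows,imageCols frame size in pixels.
#' @slot psfSigma point-spread-function sigma, px.
#' @slot particleDensity tracer density, particles per mm^2 of lumen
#'   (the default gives roughly 15-20 tracers per 32 px interrogation window
#'   at the default pitch, the classical recipe for robust correlation
#'   peaks).
#' @slot dropoutRate per-frame fraction of tracers lost out of plane and
#'   re-seeded elsewhere.
#' @slot noiseSigma additive Gaussian noise sigma as a fraction of full scale.
#' @slot bitDepth integer bit depth of rendered frames.
#' @slot interframeScale dimensionless scaling of the per-frame displacement
#'   (an effective shortening of the inter-frame interval, used to keep
#'   displacements trackable at high flow speeds).
#' @export
setClass("ImagingConfig",
  representation(frameRate = "numeric", fovDepth = "numeric", fovWidth = "numeric",
                 imageRows = "integer", imageCols = "integer",
                 psfSigma = "numeric", particleDensity = "numeric",
                 dropoutRate = "numeric", noiseSigma = "numeric",
                 bitDepth = "integer", interframeScale = "numeric"),
  prototype(frameRate = 150, fovDepth = 7, fovWidth = 15,
            imageRows = 350L, imageCols = 750L, psfSigma = 1.5,
            particleDensity = 40.0, dropoutRate = 0.02, noiseSigma = 0.02,
            bitDepth = 16L, interframeScale = 1.0),
  validity = function(object) {
    msg <- character()
    pos <- c(frameRate = object@frameRate, fovDepth = object@fovDepth,
             fovWidth = object@fovWidth, psfSigma = object@psfSigma,
             particleDensity = object@particleDensity,
             interframeScale = object@interframeScale)
    if (any(pos <= 0))
      msg <- c(msg, paste("must be > 0:", paste(names(pos)[pos <= 0], collapse = ", ")))
    if (object@dropoutRate < 0 || object@dropoutRate >= 1)
      msg <- c(msg, "dropoutRate must lie in [0, 1)")
    if (object@noiseSigma < 0 || object@noiseSigma >= 1)
      msg <- c(msg, "noiseSigma must lie in [0, 1)")
    if (object@imageRows < 8L || object@imageCols < 8L)
      msg <- c(msg, "image must be at least 8 x 8 px")
    if (!(object@bitDepth %in% c(8L, 16L)))
      msg <- c(msg, "bitDepth must be 8 or 16")
    p1 <- object@fovDepth / object@imageRows
    p2 <- object@fovWidth / object@imageCols
    if (abs(p1 - p2) > 1e-9 * max(p1, p2))
      msg <- c(msg, "pixel pitch must be identical in both axes (fov/size)")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname ImagingConfig-class
#' @param frameRate,fovDepth,fovWidth,imageRows,imageCols,psfSigma,particleDensity,dropoutRate,noiseSigma,bitDepth,interframeScale
#'   see slots.
#' @export
ImagingConfig <- function(frameRate = 150, fovDepth = 7, fovWidth = 15,
                          imageRows = 350L, imageCols = 750L, psfSigma = 1.5,
                          particleDensity = 40.0, dropoutRate = 0.02,
                          noiseSigma = 0.02, bitDepth = 16L,
                          interframeScale = 1.0)
  new("ImagingConfig", frameRate = frameRate, fovDepth = fovDepth,
      fovWidth = fovWidth, imageRows = as.integer(imageRows),
      imageCols = as.integer(imageCols), psfSigma = psfSigma,
      particleDensity = particleDensity, dropoutRate = dropoutRate,
      noiseSigma = noiseSigma, bitDepth = as.integer(bitDepth),
      interframeScale = interframeScale)

#' Tracer particle ensemble
#'
#' @slot x,y particle positions, mm.
#' @slot intensity per-particle brightness (positive, relative units).
#' @slot seed RNG seed recorded at creation.
#' @export
setClass("ParticleEnsemble",
  representation(x = "numeric", y = "numeric", intensity = "numeric",
                 seed = "integer"),
  validity = function(object) {
    n <- length(object@x)
    if (length(object@y) != n || length(object@intensity) != n)
      return("x, y and intensity must have equal length")
    if (n > 0 && any(object@intensity <= 0))
      return("intensities must be positive")
    TRUE
  }
)

#' Multi-frame synthetic image stack with ground truth
#'
#' @slot frames list of grayscale matrices (rows = depth, cols = width),
#'   values in [0, 2^bitDepth - 1].
#' @slot config the \code{ImagingConfig} used to render the frames.
#' @slot phaseTimes per-frame acquisition times, s.
#' @slot truthFields list of distinct ground-truth \code{VelocityField}s.
#' @slot truthIndex for each inter-frame interval, the index into
#'   \code{truthFields} of the field that advected the tracers.
#' @slot seed generation seed.
#' @export
setClass("ImageStack",
  representation(frames = "list", config = "ImagingConfig",
                 phaseTimes = "numeric", truthFields = "list",
                 truthIndex = "integer", seed = "integer"),
  validity = function(object) {
    n <- length(object@frames)
    if (n == 0) return("stack must contain at least one frame")
    d <- dim(object@frames[[1]])
    if (!all(vapply(object@frames, function(f) identical(dim(f), d), logical(1))))
      return("all frames must share one shape")
    if (length(object@phaseTimes) != n)
      return("phaseTimes must have one entry per frame")
    if (length(object@truthIndex) != max(0L, n - 1L))
      return("truthIndex must have one entry per inter-frame interval")
    TRUE
  }
)

#' PIV engine configuration
#'
#' @slot windowSize final interrogation window side, px (even, >= 8).
#' @slot overlap window overlap fraction in [0, 1).
#' @slot nPasses number of correlation passes (earlier passes may use an
#'   enlarged window; the final ones use \code{windowSize}).
#' @slot filterK robust-scale multiplier of the neighbourhood deviation test.
#' @slot filterFloor minimum tolerated deviation, px.
#' @slot maxDisplacement largest accepted displacement magnitude, px.
#' @slot filterStat \code{"median"} (robust, default) or \code{"mean"} for the
#'   neighbourhood reference of the spurious-vector filter.
#' @export
setClass("PIVConfig",
  representation(windowSize = "integer", overlap = "numeric", nPasses = "integer",
                 filterK = "numeric", filterFloor = "numeric",
                 maxDisplacement = "numeric", filterStat = "character"),
  prototype(windowSize = 32L, overlap = 0.5, nPasses = 3L, filterK = 2.0,
            filterFloor = 0.1, maxDisplacement = 16, filterStat = "median"),
  validity = function(object) {
    msg <- character()
    if (object@windowSize < 8L || object@windowSize %% 2L != 0L)
      msg <- c(msg, "windowSize must be even and >= 8")
    if (object@overlap < 0 || object@overlap >= 1)
      msg <- c(msg, "overlap must lie in [0, 1)")
    if (object@nPasses < 1L) msg <- c(msg, "nPasses must be >= 1")
    if (!.enum_ok(object@filterStat, c("median", "mean")))
      msg <- c(msg, "filterStat must be 'median' or 'mean'")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname PIVConfig-class
#' @param windowSize,overlap,nPasses,filterK,filterFloor,maxDisplacement,filterStat
#'   see slots; \code{maxDisplacement} defaults to \code{windowSize / 2}.
#' @export
PIVConfig <- function(windowSize = 32L, overlap = 0.5, nPasses = 3L,
                      filterK = 2.0, filterFloor = 0.1,
                      maxDisplacement = windowSize / 2,
                      filterStat = c("median", "mean"))
  new("PIVConfig", windowSize = as.integer(windowSize), overlap = overlap,
      nPasses = as.integer(nPasses), filterK = filterK,
      filterFloor = filterFloor, maxDisplacement = maxDisplacement,
      filterStat = match.arg(filterStat))

#' PIV displacement field on the interrogation grid
#'
#' Vector flags: \code{0} valid, \code{1} replaced by the local filter
#' (original estimate retained in \code{dx0}/\code{dy0}), \code{2} rejected.
#'
#' @slot xPx,yPx window-centre coordinates, 0-based px (cols / rows).
#' @slot dx,dy displacement components, px per frame, dim
#'   \code{c(length(xPx), length(yPx))}.
#' @slot dx0,dy0 pre-replacement estimates (equal to dx/dy where flag != 1).
#' @slot flag integer matrix of per-vector validity codes.
#' @slot peakCorr peak correlation coefficient per vector.
#' @export
setClass("DisplacementField",
  representation(xPx = "numeric", yPx = "numeric", dx = "matrix", dy = "matrix",
                 dx0 = "matrix", dy0 = "matrix", flag = "matrix",
                 peakCorr = "matrix"),
  validity = function(object) {
    d <- c(length(object@xPx), length(object@yPx))
    for (nm in c("dx", "dy", "dx0", "dy0", "flag", "peakCorr"))
      if (!identical(dim(slot(object, nm)), as.integer(d)))
        return(sprintf("%s must have dim c(length(xPx), length(yPx))", nm))
    if (!all(object@flag %in% c(0L, 1L, 2L)))
      return("flags must be 0 (valid), 1 (replaced) or 2 (rejected)")
    TRUE
  }
)

#' Arc-length-parameterised wall curves of a phantom lumen
#'
#' @slot upper,lower data frames with columns \code{x}, \code{y} (mm),
#'   \code{nx}, \code{ny} (unit inward normal) and \code{arclength} (mm).
#' @slot throatIndex row index of the minimum-gap point.
#' @export
setClass("WallCurves",
  representation(upper = "data.frame", lower = "data.frame",
                 throatIndex = "integer"),
  validity = function(object) {
    need <- c("x", "y", "nx", "ny", "arclength")
    for (w in c("upper", "lower")) {
      df <- slot(object, w)
      if (!all(need %in% names(df)))
        return(sprintf("%s wall must have columns %s", w, paste(need, collapse = ", ")))
      if (any(diff(df$arclength) <= 0))
        return("arclength must be strictly increasing")
      nrm <- sqrt(df$nx^2 + df$ny^2)
      if (any(abs(nrm - 1) > 1e-8)) return("normals must have unit length")
    }
    TRUE
  }
)

#' Planar shear-stress field
#'
#' @slot x,y grid axes, mm.
#' @slot tau shear stress, Pa, dim \code{c(length(x), length(y))} (NA outside
#'   the mask).
#' @slot mask logical lumen-interior matrix.
#' @slot source \code{"piv"} or \code{"solver"}.
#' @export
setClass("ShearStressField",
  representation(x = "numeric", y = "numeric", tau = "matrix",
                 mask = "matrix", source = "character"),
  validity = function(object) {
    d <- as.integer(c(length(object@x), length(object@y)))
    if (!identical(dim(object@tau), d) || !identical(dim(object@mask), d))
      return("tau and mask must have dim c(length(x), length(y))")
    if (any(!is.finite(object@tau[object@mask])))
      return("tau must be finite on the lumen interior")
    TRUE
  }
)

#' Wall shear stress along one wall
#'
#' @slot wall \code{"upper"} or \code{"lower"}.
#' @slot arclength arc length along the wall, mm, strictly increasing.
#' @slot x axial position of each sample, mm.
#' @slot tau wall shear stress magnitude, Pa.
#' @slot throatIndex sample index closest to the throat.
#' @slot source \code{"piv"} or \code{"solver"}.
#' @export
setClass("WallShearSeries",
  representation(wall = "character", arclength = "numeric", x = "numeric",
                 tau = "numeric", throatIndex = "integer", source = "character"),
  validity = function(object) {
    if (!.enum_ok(object@wall, c("upper", "lower")))
      return("wall must be 'upper' or 'lower'")
    n <- length(object@arclength)
    if (length(object@x) != n || length(object@tau) != n)
      return("arclength, x and tau must have equal length")
    if (n > 1 && any(diff(object@arclength) <= 0))
      return("arclength must be strictly increasing")
    if (any(!is.finite(object@tau))) return("tau must be finite")
    TRUE
  }
)

#' Severity-sweep configuration
#'
#' Bundles every sub-configuration of the end-to-end pipeline: which
#' severities to run, how many pump cycles to image, and the phantom, fluid,
#' waveform, imaging, PIV and solver settings shared across severities.
#'
#' @slot severities fractional severities to sweep.
#' @slot nCycles pump cycles per acquisition.
#' @slot nPhases quasi-steady phases solved per cycle.
#' @slot seed base RNG seed, recorded in every output.
#' @slot fluid,waveform,imaging,piv shared sub-configurations.
#' @slot phantomArgs named list of \code{StenosisPhantom} arguments applied to
#'   every severity (everything but \code{severity}).
#' @slot solver named list of \code{NavierStokesProblem} controls
#'   (\code{mode}, \code{nAxial}, \code{nRadial}, \code{maxIter}, \code{tol}).
#' @export
setClass("SweepConfig",
  representation(severities = "numeric", nCycles = "integer", nPhases = "integer",
                 seed = "integer", fluid = "FluidProperties",
                 waveform = "PulsatileWaveform", imaging = "ImagingConfig",
                 piv = "PIVConfig", phantomArgs = "list", solver = "list"),
  validity = function(object) {
    if (any(object@severities < 0 | object@severities >= 1))
      return("severities must lie in [0, 1)")
    if (object@nCycles < 1L) return("nCycles must be >= 1")
    if (object@nPhases < 2L) return("nPhases must be >= 2")
    TRUE
  }
)

#' @rdname SweepConfig-class
#' @param severities,nCycles,nPhases,seed,fluid,waveform,imaging,piv,phantomArgs,solver
#'   see slots.
#' @export
SweepConfig <- function(severities = c(0.3, 0.5, 0.7), nCycles = 3L,
                        nPhases = 8L, seed = 1L, fluid = FluidProperties(),
                        waveform = PulsatileWaveform(),
                        imaging = ImagingConfig(), piv = PIVConfig(),
                        phantomArgs = list(), solver = list())
  new("SweepConfig", severities = severities, nCycles = as.integer(nCycles),
      nPhases = as.integer(nPhases), seed = as.integer(seed), fluid = fluid,
      waveform = waveform, imaging = imaging, piv = piv,
      phantomArgs = phantomArgs, solver = solver)
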