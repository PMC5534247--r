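#' Instantaneous pump flow rate
#'
#' Evaluates the stylised pulsatile waveform: a raised-cosine systolic pulse
#' over the first \code{systolicFraction} of each cycle on a constant
#' diastolic baseline.  The baseline is chosen in closed form so that the
#' cycle mean equals \code{meanFlow} and the systolic peak (at the middle of
#' systole) equals \code{peakFactor * meanFlow}; the waveform is periodic and
#' non-negative.
#'
#' @param t time, s (vectorised).
#' @param waveform a \code{\link{PulsatileWaveform}}.
#' @return volumetric flow rate, m^3/s.
#' @examples
#' w <- PulsatileWaveform()          # 16 L/h mean, 30 cycles/min, 35/65 phases
#' flowRateAt(0.35, w)               # systolic peak = 2 x mean
#' @export
flowRateAt <- function(t, waveform) {
  stopifnot(is(waveform, "PulsatileWaveform"))
  T <- waveform@period
  f <- waveform@systolicFraction
  Qm <- waveform@meanFlow
  Qp <- waveform@peakFactor * Qm
  Qd <- Qm * (1 - f * waveform@peakFactor / 2) / (1 - f / 2)
  tt <- t %% T
  ifelse(tt < f * T,
         Qd + (Qp - Qd) * 0.5 * (1 - cos(2 * pi * tt / (f * T))),
         Qd)
}

#' Systolic-peak phase time
#' @param waveform a \code{\link{PulsatileWaveform}}.
#' @return time of maximum flow within one cycle, s.
#' @export
systolicPeakTime <- function(waveform)
  waveform@systolicFraction * waveform@period / 2

#' Analytic Poiseuille reference field
#'
#' Fully developed axisymmetric flow in the straight (zero-severity) phantom:
#' \eqn{u(r) = 2\bar v (1 - r^2/R^2)} with \eqn{\bar v = Q/(\pi R^2)}, zero
#' transverse velocity.
#'
#' @param Q volumetric flow rate, m^3/s.
#' @param phantom a zero-severity \code{\link{StenosisPhantom}}.
#' @param nx,ny grid resolution.
#' @param time phase stamp attached to the field, s.
#' @return a \code{\link{VelocityField}} (cm/s, mm axes).
#' @export
poiseuilleField <- function(Q, phantom, nx = 257L, ny = 65L, time = 0) {
  stopifnot(is(phantom, "StenosisPhantom"), Q >= 0)
  if (phantom@severity > 0)
    stop("poiseuilleField is defined for the straight tube (severity = 0)")
  ax <- .phantom_axes(phantom, nx, ny)
  R <- phantom@inletRadius * 1e-3                 # m
  vbar <- Q / (pi * R^2)                          # m/s
  mask <- lumenMask(phantom, ax$x, ax$y)
  prof <- 2 * vbar * pmax(0, 1 - (ax$y / phantom@inletRadius)^2) * 100  # cm/s
  u <- matrix(prof, nrow = nx, ncol = ny, byrow = TRUE)
  VelocityField(ax$x, ax$y, u, time = time, mask = mask)
}

#' Laminar entrance length
#'
#' The development length needed for a parabolic profile in a straight tube,
#' \eqn{L = 0.06\,\mathrm{Re}\,D} with \eqn{\mathrm{Re} = \rho \bar v D/\mu}.
#'
#' @param D tube diameter, m.
#' @param vMean mean velocity, m/s.
#' @param fluid a \code{\link{FluidProperties}}.
#' @return entrance length, m.
#' @examples
#' entranceLength(5e-3, 0.45, FluidProperties(viscosity = 8.7e-4))  # ~0.78 m
#' @export
entranceLength <- function(D, vMean, fluid) {
  stopifnot(is(fluid, "FluidProperties"), D >= 0, vMean >= 0)
  if (fluid@viscosity <= 0) stop("viscosity must be positive")
  Re <- fluid@density * vMean * D / fluid@viscosity
  0.06 * Re * D
}

#' Quasi-steady pulsatile cycle
#'
#' Samples the pump waveform at \code{nPhases} uniformly spaced phase times
#' and runs one converged steady solve per phase at the instantaneous flow
#' rate.  This quasi-steady surrogate is appropriate for the slow pump cycles
#' modelled here (low Womersley number); each returned field carries its phase
#' time stamp.
#'
#' @param problem a \code{\link{NavierStokesProblem}} (its \code{flowRate} is
#'   overridden phase by phase).
#' @param waveform a \code{\link{PulsatileWaveform}}.
#' @param nPhases number of phase samples per cycle (>= 2).
#' @param ... passed on to \code{\link{solveStenoticSteady}} (e.g.
#'   \code{outGrid}).
#' @return list of \code{\link{VelocityField}}s with attribute
#'   \code{"phaseTimes"}.
#' @export
quasiSteadyCycle <- function(problem, waveform, nPhases = 8L, ...) {
  stopifnot(is(problem, "NavierStokesProblem"), is(waveform, "PulsatileWaveform"))
  if (nPhases < 2L) stop("nPhases must be >= 2")
  times <- (seq_len(nPhases) - 1) * waveform@period / nPhases
  fields <- vector("list", nPhases)
  for (i in seq_len(nPhases)) {
    p <- problem
    p@flowRate <- flowRateAt(times[i], waveform)
    fields[[i]] <- tryCatch(
      solveStenoticSteady(p, time = times[i], ...),
      error = function(e) stop("phase ", i, " (t = ", signif(times[i], 4),
                               " s) failed: ", conditionMessage(e)))
  }
  attr(fields, "phaseTimes") <- times
  fields
}
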