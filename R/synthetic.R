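#' Seed tracer particles uniformly over the lumen
#'
#' Draws a Poisson-distributed number of tracers (mean = \code{particleDensity}
#' times the lumen area visible in the field of view) and places them
#' uniformly over the lumen interior by rejection sampling.  Per-particle
#' brightness is uniform on [0.5, 1], mimicking variable microbubble
#' scattering.
#'
#' @param phantom a \code{\link{StenosisPhantom}}.
#' @param imaging an \code{\link{ImagingConfig}} (defines the field of view).
#' @param seed integer RNG seed; the ensemble is reproducible given the seed.
#' @param margin axial margin beyond the field of view that is also seeded,
#'   mm; lets advection carry real tracers into the frame instead of leaving
#'   an upstream void.
#' @return a \code{\link{ParticleEnsemble}}.
#' @export
seedParticles <- function(phantom, imaging, seed = 1L, margin = 0) {
  stopifnot(is(phantom, "StenosisPhantom"), is(imaging, "ImagingConfig"))
  xw <- imaging@fovWidth / 2 + margin
  yw <- imaging@fovDepth / 2
  area <- .lumen_area(phantom, xw, yw)
  .with_seed(seed, {
    n <- stats::rpois(1, imaging@particleDensity * area)
    pos <- .sample_lumen(phantom, n, xw, yw)
    new("ParticleEnsemble", x = pos$x, y = pos$y,
        intensity = stats::runif(n, 0.5, 1), seed = as.integer(seed))
  })
}

# Lumen area (mm^2) inside the field-of-view rectangle.
.lumen_area <- function(phantom, xw, yw, n = 2001L) {
  xs <- seq(-xw, xw, length.out = n)
  w <- .wall_positions(xs, phantom)
  gap <- pmin(w$upper, yw) - pmax(w$lower, -yw)
  sum(pmax(gap, 0)) * (xs[2] - xs[1])
}

# Uniform rejection sampling of n points in the lumen (within the FOV).
.sample_lumen <- function(phantom, n, xw, yw) {
  x <- numeric(0); y <- numeric(0)
  while (length(x) < n) {
    m <- max(16L, 2L * (n - length(x)))
    cx <- stats::runif(m, -xw, xw)
    cy <- stats::runif(m, -yw, yw)
    w <- .wall_positions(cx, phantom)
    keep <- cy > w$lower & cy < w$upper
    x <- c(x, cx[keep]); y <- c(y, cy[keep])
  }
  list(x = x[seq_len(n)], y = y[seq_len(n)])
}

#' Advect a particle ensemble through a velocity field
#'
#' Positions are advanced by one 4th-order Runge-Kutta step through the
#' bilinearly interpolated velocity field.  Velocities are identically zero
#' outside the lumen mask, so particles cannot cross a wall.  Particles
#' leaving the downstream edge of the field of view are recycled at the
#' inlet; an optional per-step dropout fraction is re-seeded at random lumen
#' positions, modelling out-of-plane tracer loss.
#'
#' @param ens a \code{\link{ParticleEnsemble}}.
#' @param field a \code{\link{VelocityField}} (cm/s).
#' @param dt time step, s.
#' @param phantom phantom geometry (needed for recycling / dropout re-seeding;
#'   optional when both are disabled).
#' @param imaging \code{\link{ImagingConfig}} bounding the re-seeding region.
#' @param dropoutRate fraction of particles replaced this step.
#' @param recycle recycle particles leaving downstream at the inlet.
#' @param margin axial margin used when seeding (see
#'   \code{\link{seedParticles}}); recycling wraps over the widened extent.
#' @return the advected \code{\link{ParticleEnsemble}}.
#' @export
advectParticles <- function(ens, field, dt, phantom = NULL, imaging = NULL,
                            dropoutRate = 0, recycle = FALSE, margin = 0) {
  stopifnot(is(ens, "ParticleEnsemble"), is(field, "VelocityField"), dt > 0)
  x <- ens@x; y <- ens@y
  vel <- function(px, py) {                       # mm/s
    s <- .sample_field(field, px, py)
    list(u = s$u * 10, v = s$v * 10)
  }
  k1 <- vel(x, y)
  k2 <- vel(x + dt / 2 * k1$u, y + dt / 2 * k1$v)
  k3 <- vel(x + dt / 2 * k2$u, y + dt / 2 * k2$v)
  k4 <- vel(x + dt * k3$u, y + dt * k3$v)
  x <- x + dt / 6 * (k1$u + 2 * k2$u + 2 * k3$u + k4$u)
  y <- y + dt / 6 * (k1$v + 2 * k2$v + 2 * k3$v + k4$v)
  if (recycle && !is.null(imaging)) {
    xw <- imaging@fovWidth / 2 + margin
    out <- x > xw
    x[out] <- x[out] - 2 * xw
  }
  if (dropoutRate > 0) {
    stopifnot(!is.null(phantom), !is.null(imaging))
    drop <- stats::runif(length(x)) < dropoutRate
    if (any(drop)) {
      pos <- .sample_lumen(phantom, sum(drop), imaging@fovWidth / 2 + margin,
                           imaging@fovDepth / 2)
      x[drop] <- pos$x; y[drop] <- pos$y
    }
  }
  new("ParticleEnsemble", x = x, y = y, intensity = ens@intensity,
      seed = ens@seed)
}

#' Render a particle ensemble as one grayscale frame
#'
#' Each tracer becomes an isotropic Gaussian blob (sigma \code{psfSigma} px)
#' centred at its sub-pixel position; additive Gaussian noise (sigma
#' \code{noiseSigma} of full scale) is applied and values are clipped to the
#' configured bit depth.  Pixel centres sit at integer 0-based coordinates;
#' row 0 is the shallowest depth (smallest y).
#'
#' @param ens a \code{\link{ParticleEnsemble}}.
#' @param imaging an \code{\link{ImagingConfig}}.
#' @param seed optional RNG seed for the noise (deterministic when given).
#' @return numeric matrix \code{imageRows x imageCols} in
#'   \code{[0, 2^bitDepth - 1]}.
#' @export
renderFrame <- function(ens, imaging, seed = NULL) {
  stopifnot(is(ens, "ParticleEnsemble"), is(imaging, "ImagingConfig"))
  render <- function() {
    nr <- imaging@imageRows; nc <- imaging@imageCols
    p <- pixelPitch(imaging)
    full <- 2^imaging@bitDepth - 1
    amp <- 0.5 * full
    sig <- imaging@psfSigma
    rad <- ceiling(4 * sig)
    img <- matrix(0, nr, nc)
    # mm -> 0-based pixel-centre coordinates
    cx <- (ens@x + imaging@fovWidth / 2) / p - 0.5
    cy <- (ens@y + imaging@fovDepth / 2) / p - 0.5
    for (k in seq_along(cx)) {
      c0 <- round(cx[k]); r0 <- round(cy[k])
      cl <- max(0, c0 - rad); ch <- min(nc - 1, c0 + rad)
      rl <- max(0, r0 - rad); rh <- min(nr - 1, r0 + rad)
      if (cl > ch || rl > rh) next           # blob entirely off-frame
      cols <- cl:ch; rows <- rl:rh
      gx <- exp(-(cols - cx[k])^2 / (2 * sig^2))
      gy <- exp(-(rows - cy[k])^2 / (2 * sig^2))
      img[rows + 1, cols + 1] <- img[rows + 1, cols + 1] +
        amp * ens@intensity[k] * outer(gy, gx)
    }
    if (imaging@noiseSigma > 0)
      img <- img + stats::rnorm(nr * nc, 0, imaging@noiseSigma * full)
    pmin(pmax(img, 0), full)
  }
  if (is.null(seed)) render() else .with_seed(seed, render())
}

#' Generate a synthetic microbubble image stack with ground truth
#'
#' Seeds tracers, then alternates rendering and advection to produce
#' \code{round(frameRate * nCycles * period)} frames.  Each inter-frame step
#' uses the phase-appropriate velocity field (nearest phase when a
#' quasi-steady cycle is supplied) over an effective time step
#' \code{interframeScale / frameRate}; the advecting field of every interval
#' is stored alongside the frames, so downstream PIV estimates can be scored
#' against exact ground truth.
#'
#' A warning is raised when the expected maximum tracer displacement exceeds
#' half the default 32 px interrogation window, advising a smaller
#' \code{interframeScale}.
#'
#' @param phantom a \code{\link{StenosisPhantom}}.
#' @param flow a single \code{\link{VelocityField}} or a list of fields with a
#'   \code{"phaseTimes"} attribute (see \code{\link{quasiSteadyCycle}}).
#' @param imaging an \code{\link{ImagingConfig}}.
#' @param nCycles number of pump cycles to image (>= 1).
#' @param period cycle period, s (defaults to the span implied by
#'   \code{phaseTimes}, else 2 s).
#' @param seed integer seed controlling seeding, dropout and noise.
#' @return an \code{\link{ImageStack}}.
#' @export
generateStack <- function(phantom, flow, imaging, nCycles = 1L, period = NULL,
                          seed = 1L) {
  stopifnot(is(phantom, "StenosisPhantom"), is(imaging, "ImagingConfig"))
  if (nCycles < 1L) stop("nCycles must be >= 1")
  if (is(flow, "VelocityField")) {
    fields <- list(flow); times <- 0
  } else {
    fields <- flow
    times <- attr(flow, "phaseTimes")
    if (is.null(times)) stop("a field list must carry a 'phaseTimes' attribute")
  }
  if (is.null(period)) period <- if (length(times) > 1)
    length(times) * diff(times[1:2]) else 2
  nFrames <- round(imaging@frameRate * nCycles * period)
  dtEff <- imaging@interframeScale / imaging@frameRate
  p <- pixelPitch(imaging)

  vmax <- max(vapply(fields, function(f) max(sqrt(f@u^2 + f@v^2)), numeric(1)))
  maxDisp <- vmax * 10 * dtEff / p               # px per frame
  if (maxDisp > 16)
    warning(sprintf(paste(
      "expected maximum displacement %.1f px/frame exceeds half a 32 px",
      "window; reduce interframeScale below %.3g"), maxDisp,
      imaging@interframeScale * 16 / maxDisp))

  # seed beyond the frame so advection carries real tracers across the inlet
  margin <- min(0.2 * imaging@fovWidth,
                1.5 * vmax * 10 * dtEff + 4 * imaging@psfSigma * p)
  .with_seed(.child_seed(seed, "stack"), {
    ens <- seedParticles(phantom, imaging, margin = margin,
                         seed = .child_seed(seed, "seeding"))
    framesOut <- vector("list", nFrames)
    truthIndex <- integer(max(0L, nFrames - 1L))
    phase <- ((seq_len(nFrames) - 1) / imaging@frameRate) %% period
    for (k in seq_len(nFrames)) {
      framesOut[[k]] <- renderFrame(ens, imaging)
      if (k < nFrames) {
        fi <- if (length(fields) == 1L) 1L else
          which.min(pmin(abs(times - phase[k]), period - abs(times - phase[k])))
        truthIndex[k] <- fi
        ens <- advectParticles(ens, fields[[fi]], dtEff, phantom = phantom,
                               imaging = imaging,
                               dropoutRate = imaging@dropoutRate,
                               recycle = TRUE, margin = margin)
      }
    }
    new("ImageStack", frames = framesOut, config = imaging,
        phaseTimes = (seq_len(nFrames) - 1) / imaging@frameRate,
        truthFields = fields, truthIndex = truthIndex,
        seed = as.integer(seed))
  })
}
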