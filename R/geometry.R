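#' Local lumen half-width of a stenosed phantom
#'
#' Half the local wall-to-wall gap.  Outside the plaque extent
#' (\code{|x| >= plaqueLength / 2}) this equals the inlet radius; inside, the
#' constriction follows a raised-cosine taper that is C1-smooth at the plaque
#' edges and reaches its minimum at the throat (\code{x = 0}):
#' \eqn{R_0\sqrt{1-s}} on the area basis, \eqn{R_0(1-s)} on the diameter
#' basis.
#'
#' @param x axial positions, mm (vectorised).
#' @param phantom a \code{\link{StenosisPhantom}}.
#' @return lumen half-width at each \code{x}, mm.
#' @examples
#' ph <- StenosisPhantom(severity = 0.7)
#' lumenHalfwidth(c(-10, 0, 10), ph)  # 2.5, 2.5 * sqrt(0.3), 2.5
#' @export
lumenHalfwidth <- function(x, phantom) {
  stopifnot(is(phantom, "StenosisPhantom"))
  R0 <- phantom@inletRadius
  depth <- R0 - throatRadius(phantom)
  Lp <- phantom@plaqueLength
  bump <- ifelse(abs(x) < Lp / 2, 0.5 * (1 + cos(2 * pi * x / Lp)), 0)
  R0 - depth * bump
}

#' @rdname accessors
#' @export
setMethod("throatRadius", "StenosisPhantom", function(object) {
  s <- object@severity
  if (object@severityBasis == "area") object@inletRadius * sqrt(1 - s)
  else object@inletRadius * (1 - s)
})

# First and second axial derivatives of the half-width (analytic; used by the
# wall-fitted solver grid).
.halfwidth_d1 <- function(x, phantom) {
  depth <- phantom@inletRadius - throatRadius(phantom)
  Lp <- phantom@plaqueLength
  ifelse(abs(x) < Lp / 2, depth * (pi / Lp) * sin(2 * pi * x / Lp), 0)
}
.halfwidth_d2 <- function(x, phantom) {
  depth <- phantom@inletRadius - throatRadius(phantom)
  Lp <- phantom@plaqueLength
  ifelse(abs(x) < Lp / 2, depth * (2 * pi^2 / Lp^2) * cos(2 * pi * x / Lp), 0)
}

# Physical wall positions (may be asymmetric for one-sided plaques): the gap
# always equals 2 * lumenHalfwidth(x), but a one-sided bump indents only the
# upper wall.
.wall_positions <- function(x, phantom) {
  h <- lumenHalfwidth(x, phantom)
  if (phantom@bumpSide == "symmetric") list(lower = -h, upper = h)
  else list(lower = rep(-phantom@inletRadius, length(x)),
            upper = -phantom@inletRadius + 2 * h)
}

#' Boolean lumen-interior mask on a regular grid
#'
#' A grid point is interior iff its transverse coordinate lies strictly
#' between the local walls.  For \code{bumpSide = "symmetric"} the mask is
#' symmetric about the centreline.
#'
#' @param phantom a \code{\link{StenosisPhantom}}.
#' @param x,y grid axes, mm.  The x axis must cover the plaque extent.
#' @return logical matrix of dim \code{c(length(x), length(y))}.
#' @export
lumenMask <- function(phantom, x, y) {
  stopifnot(is(phantom, "StenosisPhantom"))
  if (min(x) > -phantom@plaqueLength / 2 || max(x) < phantom@plaqueLength / 2)
    stop("grid x axis does not cover the plaque extent [",
         -phantom@plaqueLength / 2, ", ", phantom@plaqueLength / 2, "] mm")
  w <- .wall_positions(x, phantom)
  outer(seq_along(x), seq_along(y),
        function(i, j) y[j] > w$lower[i] & y[j] < w$upper[i])
}

#' Arc-length-parameterised wall curves
#'
#' Samples both lumen walls at \code{nPoints} axial stations across the
#' phantom domain, with unit inward normals and cumulative arc length, and
#' marks the throat (minimum-gap) station.
#'
#' @param phantom a \code{\link{StenosisPhantom}}.
#' @param nPoints number of stations (>= 16).
#' @return a \code{\link{WallCurves}} object.
#' @export
wallCurves <- function(phantom, nPoints = 201L) {
  stopifnot(is(phantom, "StenosisPhantom"))
  if (nPoints < 16L) stop("nPoints must be >= 16")
  x <- seq(-phantom@domainLength / 2, phantom@domainLength / 2,
           length.out = nPoints)
  w <- .wall_positions(x, phantom)
  one <- function(yw, upper) {
    # centred wall slope where possible, one-sided at the ends
    n <- length(x)
    slope <- numeric(n)
    slope[2:(n - 1)] <- (yw[3:n] - yw[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
    slope[1] <- (yw[2] - yw[1]) / (x[2] - x[1])
    slope[n] <- (yw[n] - yw[n - 1]) / (x[n] - x[n - 1])
    nrm <- sqrt(1 + slope^2)
    if (upper) data.frame(x = x, y = yw, nx = slope / nrm, ny = -1 / nrm,
                          arclength = c(0, cumsum(sqrt(diff(x)^2 + diff(yw)^2))))
    else data.frame(x = x, y = yw, nx = -slope / nrm, ny = 1 / nrm,
                    arclength = c(0, cumsum(sqrt(diff(x)^2 + diff(yw)^2))))
  }
  new("WallCurves", upper = one(w$upper, TRUE), lower = one(w$lower, FALSE),
      throatIndex = which.min(w$upper - w$lower))
}
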