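#' Planar shear-stress field from a velocity field
#'
#' Evaluates \eqn{\tau = \mu\,(\partial v/\partial x + \partial u/\partial y)}
#' on the field grid: central differences in the interior of the lumen mask,
#' second-order one-sided differences where a masked-out neighbour would
#' otherwise be used (so exterior values never contaminate the gradients).
#' Units: velocities in cm/s on mm axes, viscosity in Pa s, stress in Pa.
#'
#' @param vf a \code{\link{VelocityField}} with at least 3 points per axis.
#' @param fluid a \code{\link{FluidProperties}}.
#' @param source tag recorded on the result (\code{"piv"} or
#'   \code{"solver"}).
#' @return a \code{\link{ShearStressField}} (tau is NA outside the mask and
#'   at isolated mask points where no gradient is defined).
#' @export
shearField <- function(vf, fluid, source = "solver") {
  stopifnot(is(vf, "VelocityField"), is(fluid, "FluidProperties"))
  if (length(vf@x) < 3 || length(vf@y) < 3)
    stop("grid must have at least 3 points per axis")
  dudy <- .masked_gradient(vf@u, vf@mask, along = 2, h = vf@y[2] - vf@y[1])
  dvdx <- .masked_gradient(vf@v, vf@mask, along = 1, h = vf@x[2] - vf@x[1])
  tau <- fluid@viscosity * (dvdx + dudy) * 10     # (cm/s)/mm -> 1/s
  tau[!vf@mask] <- NA_real_
  # isolated interior points with no usable stencil stay NA; mask them out
  mask <- vf@mask & is.finite(tau)
  tau[!mask] <- NA_real_
  new("ShearStressField", x = vf@x, y = vf@y, tau = tau, mask = mask,
      source = source)
}

# Gradient of z along dimension `along`, restricted to contiguous runs of
# mask = TRUE: central differences inside a run, second-order one-sided at
# run ends, simple difference for 2-point runs, NA for singletons.
.masked_gradient <- function(z, mask, along, h) {
  out <- matrix(NA_real_, nrow(z), ncol(z))
  nOuter <- if (along == 1) ncol(z) else nrow(z)
  for (k in seq_len(nOuter)) {
    zl <- if (along == 1) z[, k] else z[k, ]
    ml <- if (along == 1) mask[, k] else mask[k, ]
    g <- rep(NA_real_, length(zl))
    r <- rle(ml)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (seg in which(r$values)) {
      a <- starts[seg]; b <- ends[seg]
      len <- b - a + 1
      if (len == 1) next
      if (len == 2) {
        g[a] <- g[b] <- (zl[b] - zl[a]) / h
      } else {
        idx <- (a + 1):(b - 1)
        g[idx] <- (zl[idx + 1] - zl[idx - 1]) / (2 * h)
        g[a] <- (-3 * zl[a] + 4 * zl[a + 1] - zl[a + 2]) / (2 * h)
        g[b] <- (3 * zl[b] - 4 * zl[b - 1] + zl[b - 2]) / (2 * h)
      }
    }
    if (along == 1) out[, k] <- g else out[k, ] <- g
  }
  out
}

#' Wall shear stress along the lumen walls
#'
#' Samples the shear stress one grid step inside the wall at every wall-curve
#' point, following the inward normal, and (by default) linearly extrapolates
#' the one- and two-step samples back to the wall, which is exact for the
#' linear near-wall stress profile of fully developed flow.  Two stress
#' definitions are available: the planar shear component
#' \eqn{\mu(\partial v/\partial x + \partial u/\partial y)} (default,
#' matching \code{\link{shearField}}) or the wall-normal gradient of the
#' wall-tangential velocity, which is the better estimate on steeply
#' inclined walls.  Magnitudes are reported.
#'
#' @param vf a \code{\link{VelocityField}}.
#' @param fluid a \code{\link{FluidProperties}}.
#' @param walls a \code{\link{WallCurves}} consistent with the field domain.
#' @param method \code{"shear"} (the planar component) or \code{"normal"}
#'   (wall-normal tangential-velocity gradient).
#' @param extrapolate extrapolate the two near-wall samples to the wall
#'   (default) instead of reporting the one-step-inside value.
#' @param offsetSteps distance of the first sample from the wall, in grid
#'   steps.  Keep 1 for solver fields; for PIV fields use roughly half an
#'   interrogation window so that samples avoid vectors whose windows
#'   straddled the wall.
#' @param source tag recorded on the series.
#' @return list with \code{upper} and \code{lower}
#'   \code{\link{WallShearSeries}}; points falling outside the field domain
#'   are skipped and counted in the \code{"skipped"} attribute.
#' @export
wallShear <- function(vf, fluid, walls, method = c("shear", "normal"),
                      extrapolate = TRUE, offsetSteps = 1, source = "solver") {
  method <- match.arg(method)
  stopifnot(is(vf, "VelocityField"), is(walls, "WallCurves"))
  step <- min(abs(diff(vf@x[1:2])), abs(diff(vf@y[1:2]))) * offsetSteps
  tauF <- if (method == "shear") shearField(vf, fluid, source = source) else NULL
  mk <- function(df, wallName) {
    p1x <- df$x + step * df$nx; p1y <- df$y + step * df$ny
    p2x <- df$x + 2 * step * df$nx; p2y <- df$y + 2 * step * df$ny
    if (method == "shear") {
      t1 <- .bilinear_xy(vf@x, vf@y, tauF@tau, p1x, p1y, fill = NA)
      t2 <- .bilinear_xy(vf@x, vf@y, tauF@tau, p2x, p2y, fill = NA)
      # NA neighbours inside the bilinear stencil: retreat to nearest sample
      t1[is.na(t1)] <- .nearest_xy(vf@x, vf@y, tauF@tau, p1x, p1y)[is.na(t1)]
      t2[is.na(t2)] <- .nearest_xy(vf@x, vf@y, tauF@tau, p2x, p2y)[is.na(t2)]
      tau <- if (extrapolate) 2 * t1 - t2 else t1
    } else {
      # tangential velocity (cm/s) at one and two steps inside; wall value 0
      tx <- df$ny * ifelse(wallName == "upper", -1, 1)
      ty <- -df$nx * ifelse(wallName == "upper", -1, 1)
      s1 <- .sample_field(vf, p1x, p1y); s2 <- .sample_field(vf, p2x, p2y)
      u1 <- s1$u * tx + s1$v * ty
      u2 <- s2$u * tx + s2$v * ty
      # second-order one-sided derivative at the wall using u(0) = 0
      dudn <- if (extrapolate) (4 * u1 - u2) / (2 * step) else u1 / step
      tau <- fluid@viscosity * dudn * 10
    }
    keep <- is.finite(tau) &
      p1x >= min(vf@x) & p1x <= max(vf@x) & p1y >= min(vf@y) & p1y <= max(vf@y)
    ser <- new("WallShearSeries", wall = wallName,
               arclength = df$arclength[keep], x = df$x[keep],
               tau = abs(tau[keep]),
               throatIndex = as.integer(which.min(abs(df$x[keep]))),
               source = source)
    attr(ser, "skipped") <- sum(!keep)
    ser
  }
  list(upper = mk(walls@upper, "upper"), lower = mk(walls@lower, "lower"))
}

# Nearest-neighbour fallback sampling (used where bilinear stencils hit NA).
.nearest_xy <- function(x, y, z, xi, yi) {
  dx <- x[2] - x[1]; dy <- y[2] - y[1]
  i <- pmin(pmax(round((xi - x[1]) / dx) + 1, 1), length(x))
  j <- pmin(pmax(round((yi - y[1]) / dy) + 1, 1), length(y))
  z[cbind(i, j)]
}

#' Summarise wall-shear-stress series
#'
#' For each series: the global maximum and its axial location, the largest
#' value upstream of the throat (x < 0) and downstream (x > 0), and the mean
#' over the plaque surface.
#'
#' @param series a \code{\link{WallShearSeries}} or list of them (e.g. the
#'   output of \code{\link{wallShear}}).
#' @param plaqueLength restrict the surface mean to \code{|x| <=
#'   plaqueLength / 2} (mm); NULL averages the full series.
#' @return data frame with one row per series.
#' @export
wssSummary <- function(series, plaqueLength = NULL) {
  if (is(series, "WallShearSeries")) series <- list(series)
  if (length(series) == 0) stop("at least one series is required")
  rows <- lapply(series, function(s) {
    stopifnot(is(s, "WallShearSeries"))
    imax <- which.max(s@tau)
    up <- s@tau[s@x < 0]; dn <- s@tau[s@x > 0]
    inPlaque <- if (is.null(plaqueLength)) rep(TRUE, length(s@x))
                else abs(s@x) <= plaqueLength / 2
    data.frame(wall = s@wall, source = s@source,
               max_tau_pa = s@tau[imax], max_x_mm = s@x[imax],
               upstream_max_pa = if (length(up)) max(up) else NA_real_,
               downstream_max_pa = if (length(dn)) max(dn) else NA_real_,
               plaque_mean_pa = mean(s@tau[inPlaque]))
  })
  do.call(rbind, rows)
}
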