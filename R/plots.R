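#' Quick-look plots
#'
#' Base-graphics visualisations used by the pipeline reports:
#' \code{plotField} shows the velocity-magnitude map with a sparse quiver
#' overlay, \code{plotWallShear} the wall-shear-stress series against axial
#' position, and \code{plotTransects} the three transect profiles.
#'
#' @param field a \code{\link{VelocityField}}.
#' @param every quiver decimation factor.
#' @param main plot title.
#' @param ... passed to \code{image}.
#' @export
plotField <- function(field, every = 4L, main = "velocity magnitude (cm/s)",
                      ...) {
  sp <- sqrt(field@u^2 + field@v^2)
  sp[!field@mask] <- NA
  graphics::image(field@x, field@y, sp, col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x (mm)", ylab = "y (mm)", main = main, useRaster = TRUE,
                  ...)
  ix <- seq(1, length(field@x), by = every)
  iy <- seq(1, length(field@y), by = every)
  g <- expand.grid(i = ix, j = iy)
  keep <- field@mask[cbind(g$i, g$j)]
  g <- g[keep, ]
  sc <- 0.8 * (field@x[2] - field@x[1]) * every / max(sp, na.rm = TRUE)
  graphics::arrows(field@x[g$i], field@y[g$j],
                   field@x[g$i] + sc * field@u[cbind(g$i, g$j)],
                   field@y[g$j] + sc * field@v[cbind(g$i, g$j)],
                   length = 0.02, col = "white")
  invisible(NULL)
}

#' @rdname plotField
#' @param series list of \code{\link{WallShearSeries}} (as from
#'   \code{\link{wallShear}}).
#' @export
plotWallShear <- function(series, main = "wall shear stress") {
  if (is(series, "WallShearSeries")) series <- list(series)
  cols <- seq_along(series)
  rng <- range(unlist(lapply(series, slot, "tau")))
  graphics::plot(NULL, xlim = range(unlist(lapply(series, slot, "x"))),
                 ylim = c(0, rng[2] * 1.05), xlab = "x (mm)",
                 ylab = expression(tau[w] ~ "(Pa)"), main = main)
  for (k in seq_along(series))
    graphics::lines(series[[k]]@x, series[[k]]@tau, col = cols[k], lwd = 2)
  graphics::abline(v = 0, lty = 3)
  graphics::legend("topright", legend = vapply(series, function(s)
    paste(s@wall, s@source), character(1)), col = cols, lwd = 2, bty = "n")
  invisible(NULL)
}

#' @rdname plotField
#' @param profiles data frame from \code{\link{transectProfiles}}.
#' @export
plotTransects <- function(profiles, main = "transect profiles") {
  lines_ <- unique(profiles$line)
  graphics::plot(NULL, xlim = range(profiles$y_mm),
                 ylim = c(0, max(profiles$speed_cm_s) * 1.05),
                 xlab = "y (mm)", ylab = "|v| (cm/s)", main = main)
  for (k in seq_along(lines_)) {
    d <- profiles[profiles$line == lines_[k], ]
    graphics::lines(d$y_mm, d$speed_cm_s, col = k, lwd = 2)
  }
  graphics::legend("topright", legend = lines_, col = seq_along(lines_),
                   lwd = 2, bty = "n")
  invisible(NULL)
}
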