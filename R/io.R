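#' Velocity-field CSV round trip
#'
#' One row per grid point: \code{x_mm, y_mm, u_cm_s, v_cm_s, mask, phase_s}.
#'
#' @param field a \code{\link{VelocityField}}.
#' @param path output file.
#' @export
writeFieldCSV <- function(field, path) {
  pts <- expand.grid(ix = seq_along(field@x), iy = seq_along(field@y))
  df <- data.frame(x_mm = field@x[pts$ix], y_mm = field@y[pts$iy],
                   u_cm_s = field@u[cbind(pts$ix, pts$iy)],
                   v_cm_s = field@v[cbind(pts$ix, pts$iy)],
                   mask = as.integer(field@mask[cbind(pts$ix, pts$iy)]),
                   phase_s = field@time)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFieldCSV
#' @return \code{readFieldCSV} returns the reconstructed
#'   \code{\link{VelocityField}}.
#' @export
readFieldCSV <- function(path) {
  df <- utils::read.csv(path)
  x <- sort(unique(df$x_mm)); y <- sort(unique(df$y_mm))
  ix <- match(df$x_mm, x); iy <- match(df$y_mm, y)
  u <- v <- matrix(0, length(x), length(y))
  mask <- matrix(FALSE, length(x), length(y))
  u[cbind(ix, iy)] <- df$u_cm_s
  v[cbind(ix, iy)] <- df$v_cm_s
  mask[cbind(ix, iy)] <- df$mask > 0
  VelocityField(x, y, u, v, time = df$phase_s[1], mask = mask)
}

#' Write wall curves as CSV
#'
#' Columns: \code{wall, x_mm, y_mm, nx, ny, arclength_mm}.
#'
#' @param walls a \code{\link{WallCurves}}.
#' @param path output file.
#' @export
writeWallCurvesCSV <- function(walls, path) {
  up <- walls@upper; lo <- walls@lower
  df <- rbind(data.frame(wall = "upper", x_mm = up$x, y_mm = up$y,
                         nx = up$nx, ny = up$ny, arclength_mm = up$arclength),
              data.frame(wall = "lower", x_mm = lo$x, y_mm = lo$y,
                         nx = lo$nx, ny = lo$ny, arclength_mm = lo$arclength))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Image-stack TIFF round trip
#'
#' Frames are written as a multi-page grayscale TIFF at the configured bit
#' depth, with a JSON sidecar (\code{<path>.json}) holding the imaging
#' configuration, seed and phase times so that metadata round-trips exactly.
#' Ground-truth fields are not embedded; store them with
#' \code{\link{writeFieldCSV}}.
#'
#' @param stack an \code{\link{ImageStack}}.
#' @param path output TIFF file.
#' @export
writeStackTIFF <- function(stack, path) {
  full <- 2^stack@config@bitDepth - 1
  pages <- lapply(stack@frames, function(f) round(f) / full)
  tiff::writeTIFF(pages, path, bits.per.sample = stack@config@bitDepth)
  cfg <- stack@config
  side <- list(
    imaging = list(frameRate = cfg@frameRate, fovDepth = cfg@fovDepth,
                   fovWidth = cfg@fovWidth, imageRows = cfg@imageRows,
                   imageCols = cfg@imageCols, psfSigma = cfg@psfSigma,
                   particleDensity = cfg@particleDensity,
                   dropoutRate = cfg@dropoutRate, noiseSigma = cfg@noiseSigma,
                   bitDepth = cfg@bitDepth, interframeScale = cfg@interframeScale),
    phaseTimes = stack@phaseTimes, seed = stack@seed,
    truthIndex = stack@truthIndex)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeStackTIFF
#' @return \code{readStackTIFF} returns the reconstructed
#'   \code{\link{ImageStack}} (with an empty ground-truth field list).
#' @export
readStackTIFF <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- do.call(ImagingConfig, side$imaging)
  full <- 2^cfg@bitDepth - 1
  frames <- lapply(pages, function(p) round(p * full))
  new("ImageStack", frames = frames, config = cfg,
      phaseTimes = as.numeric(side$phaseTimes),
      truthFields = list(), truthIndex = as.integer(side$truthIndex),
      seed = as.integer(side$seed))
}

#' Read a sweep configuration from YAML
#'
#' Recognised top-level keys (all optional): \code{severities},
#' \code{n_cycles}, \code{n_phases}, \code{seed}, and the blocks
#' \code{phantom} (\code{inlet_diameter_mm}, \code{wall_thickness_mm},
#' \code{plaque_length_mm}, \code{severity_basis}, \code{bump_side},
#' \code{domain_length_mm}), \code{fluid} (\code{density}, \code{viscosity}),
#' \code{waveform} (\code{period_s}, \code{systolic_fraction},
#' \code{mean_flow_l_h}, \code{peak_factor}), \code{imaging} and \code{piv}
#' (keys mirroring the \code{\link{ImagingConfig}} / \code{\link{PIVConfig}}
#' constructor arguments) and \code{solver} (\code{mode}, \code{n_axial},
#' \code{n_radial}, \code{max_iter}, \code{tol}).
#'
#' @param path YAML file.
#' @return a \code{\link{SweepConfig}}.
#' @export
readSweepConfig <- function(path) {
  y <- yaml::read_yaml(path)
  g <- function(block, key, default) {
    v <- y[[block]][[key]]
    if (is.null(v)) default else v
  }
  phantomArgs <- list(
    inletRadius = g("phantom", "inlet_diameter_mm", 5) / 2,
    wallThickness = g("phantom", "wall_thickness_mm", 1),
    plaqueLength = g("phantom", "plaque_length_mm", 8),
    severityBasis = g("phantom", "severity_basis", "area"),
    bumpSide = g("phantom", "bump_side", "symmetric"),
    domainLength = g("phantom", "domain_length_mm", 40))
  fluid <- FluidProperties(density = g("fluid", "density", 1000),
                           viscosity = g("fluid", "viscosity", 0.0087))
  waveform <- PulsatileWaveform(
    period = g("waveform", "period_s", 2),
    systolicFraction = g("waveform", "systolic_fraction", 0.35),
    meanFlow = g("waveform", "mean_flow_l_h", 16) * 1e-3 / 3600,
    peakFactor = g("waveform", "peak_factor", 2))
  imaging <- do.call(ImagingConfig, if (is.null(y$imaging)) list() else y$imaging)
  piv <- do.call(PIVConfig, if (is.null(y$piv)) list() else y$piv)
  solver <- list()
  for (k in c("mode", "n_axial", "n_radial", "max_iter", "tol")) {
    v <- y$solver[[k]]
    if (!is.null(v))
      solver[[c(mode = "mode", n_axial = "nAxial", n_radial = "nRadial",
                max_iter = "maxIter", tol = "tol")[[k]]]] <- v
  }
  SweepConfig(
    severities = if (is.null(y$severities)) c(0.3, 0.5, 0.7) else y$severities,
    nCycles = if (is.null(y$n_cycles)) 3L else y$n_cycles,
    nPhases = if (is.null(y$n_phases)) 8L else y$n_phases,
    seed = if (is.null(y$seed)) 1L else y$seed,
    fluid = fluid, waveform = waveform, imaging = imaging, piv = piv,
    phantomArgs = phantomArgs, solver = solver)
}

#' Write the sweep report as JSON
#'
#' @param report the list returned by \code{\link{runSweep}}.
#' @param path output file.
#' @export
writeReportJSON <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
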