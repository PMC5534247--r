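#' Accessor generics
#'
#' Small accessor family used instead of direct slot access: grid axes
#' (\code{xCoords}, \code{yCoords}), velocity components (\code{uVelocity},
#' \code{vVelocity}, cm/s), the lumen-interior mask (\code{fieldMask}),
#' image-stack content (\code{frames}, \code{phaseTimes}, \code{nFrames},
#' \code{pixelPitch}), PIV vector metadata (\code{vectorFlags},
#' \code{peakCorrelation}) and geometry summaries (\code{severity},
#' \code{throatRadius}).
#'
#' @param object an object of the relevant class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("xCoords", function(object) standardGeneric("xCoords"))
#' @rdname accessors
#' @export
setGeneric("yCoords", function(object) standardGeneric("yCoords"))
#' @rdname accessors
#' @export
setGeneric("uVelocity", function(object) standardGeneric("uVelocity"))
#' @rdname accessors
#' @export
setGeneric("vVelocity", function(object) standardGeneric("vVelocity"))
#' @rdname accessors
#' @export
setGeneric("fieldMask", function(object) standardGeneric("fieldMask"))
#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("phaseTimes", function(object) standardGeneric("phaseTimes"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("pixelPitch", function(object) standardGeneric("pixelPitch"))
#' @rdname accessors
#' @export
setGeneric("vectorFlags", function(object) standardGeneric("vectorFlags"))
#' @rdname accessors
#' @export
setGeneric("peakCorrelation", function(object) standardGeneric("peakCorrelation"))
#' @rdname accessors
#' @export
setGeneric("severity", function(object) standardGeneric("severity"))
#' @rdname accessors
#' @export
setGeneric("throatRadius", function(object) standardGeneric("throatRadius"))

#' @rdname accessors
setMethod("xCoords", "VelocityField", function(object) object@x)
#' @rdname accessors
setMethod("yCoords", "VelocityField", function(object) object@y)
#' @rdname accessors
setMethod("uVelocity", "VelocityField", function(object) object@u)
#' @rdname accessors
setMethod("vVelocity", "VelocityField", function(object) object@v)
#' @rdname accessors
setMethod("fieldMask", "VelocityField", function(object) object@mask)
#' @rdname accessors
setMethod("xCoords", "ShearStressField", function(object) object@x)
#' @rdname accessors
setMethod("yCoords", "ShearStressField", function(object) object@y)
#' @rdname accessors
setMethod("fieldMask", "ShearStressField", function(object) object@mask)

#' @rdname accessors
setMethod("frames", "ImageStack", function(object) object@frames)
#' @rdname accessors
setMethod("phaseTimes", "ImageStack", function(object) object@phaseTimes)
#' @rdname accessors
setMethod("nFrames", "ImageStack", function(object) length(object@frames))
#' @rdname accessors
setMethod("pixelPitch", "ImagingConfig",
          function(object) object@fovDepth / object@imageRows)
#' @rdname accessors
setMethod("pixelPitch", "ImageStack", function(object) pixelPitch(object@config))

#' @rdname accessors
setMethod("vectorFlags", "DisplacementField", function(object) object@flag)
#' @rdname accessors
setMethod("peakCorrelation", "DisplacementField", function(object) object@peakCorr)
#' @rdname accessors
setMethod("xCoords", "DisplacementField", function(object) object@xPx)
#' @rdname accessors
setMethod("yCoords", "DisplacementField", function(object) object@yPx)

#' @rdname accessors
setMethod("severity", "StenosisPhantom", function(object) object@severity)

#' Ground-truth field advecting a given inter-frame interval
#'
#' @param object an \code{ImageStack}.
#' @param interval inter-frame interval index (between frames
#'   \code{interval} and \code{interval + 1}).
#' @return the \code{VelocityField} used for that interval.
#' @export
setGeneric("truthField", function(object, interval) standardGeneric("truthField"))
#' @rdname truthField
setMethod("truthField", "ImageStack", function(object, interval) {
  stopifnot(interval >= 1L, interval <= length(object@truthIndex))
  object@truthFields[[object@truthIndex[interval]]]
})

setMethod("show", "StenosisPhantom", function(object) {
  rt <- throatRadius(object)
  cat(sprintf("StenosisPhantom: %.0f%% %s stenosis\n", 100 * object@severity,
              object@severityBasis))
  cat(sprintf("  inlet radius %.2f mm, throat radius %.3f mm (%s bump)\n",
              object@inletRadius, rt, object@bumpSide))
  cat(sprintf("  plaque length %.1f mm, domain %.1f mm (throat-centred)\n",
              object@plaqueLength, object@domainLength))
})

setMethod("show", "VelocityField", function(object) {
  sp <- sqrt(object@u^2 + object@v^2)
  cat(sprintf("VelocityField: %d x %d grid, t = %.3f s\n",
              length(object@x), length(object@y), object@time))
  cat(sprintf("  x in [%.2f, %.2f] mm, y in [%.2f, %.2f] mm\n",
              min(object@x), max(object@x), min(object@y), max(object@y)))
  cat(sprintf("  |v| max %.2f cm/s, lumen coverage %.0f%%\n",
              max(sp), 100 * mean(object@mask)))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames[[1]])
  cat(sprintf("ImageStack: %d frames of %d x %d px (%.0f fps, pitch %.3f mm/px)\n",
              length(object@frames), d[1], d[2], object@config@frameRate,
              pixelPitch(object)))
  cat(sprintf("  %d distinct ground-truth fields, seed %d\n",
              length(object@truthFields), object@seed))
})

setMethod("show", "DisplacementField", function(object) {
  n <- length(object@flag)
  cat(sprintf("DisplacementField: %d x %d vectors\n",
              length(object@xPx), length(object@yPx)))
  cat(sprintf("  valid %d, replaced %d, rejected %d\n",
              sum(object@flag == 0L), sum(object@flag == 1L),
              sum(object@flag == 2L)))
  ok <- object@flag != 2L
  if (any(ok))
    cat(sprintf("  mean |d| %.2f px, mean peak corr %.3f\n",
                mean(sqrt(object@dx[ok]^2 + object@dy[ok]^2)),
                mean(object@peakCorr[ok])))
})

setMethod("show", "WallShearSeries", function(object) {
  cat(sprintf("WallShearSeries (%s wall, %s): %d samples, max %.3f Pa at x = %.2f mm\n",
              object@wall, object@source, length(object@tau),
              max(object@tau), object@x[which.max(object@tau)]))
})

setMethod("show", "SweepConfig", function(object) {
  cat(sprintf("SweepConfig: severities %s, %d cycles, %d phases/cycle, seed %d\n",
              paste(object@severities, collapse = "/"), object@nCycles,
              object@nPhases, object@seed))
})

#' Coerce package objects to data frames
#'
#' \code{DisplacementField} rows carry one vector each (pixel and, when an
#' \code{ImagingConfig} is attached via \code{imaging}, physical coordinates);
#' \code{WallShearSeries} rows carry one wall sample.
#'
#' @param x a \code{DisplacementField} or \code{WallShearSeries}.
#' @param row.names,optional ignored (base signature).
#' @param imaging optional \code{ImagingConfig} adding mm / cm/s columns.
#' @param ... ignored.
#' @return a \code{data.frame}.
#' @export
as.data.frame.DisplacementField <- function(x, row.names = NULL,
                                            optional = FALSE,
                                            imaging = NULL, ...) {
  g <- expand.grid(ix = seq_along(x@xPx), iy = seq_along(x@yPx))
  out <- data.frame(
    x_px = x@xPx[g$ix], y_px = x@yPx[g$iy],
    dx_px = x@dx[cbind(g$ix, g$iy)], dy_px = x@dy[cbind(g$ix, g$iy)],
    peak_corr = x@peakCorr[cbind(g$ix, g$iy)],
    flag = c("valid", "replaced", "rejected")[x@flag[cbind(g$ix, g$iy)] + 1L])
  if (!is.null(imaging)) {
    p <- pixelPitch(imaging)
    out$x_mm <- out$x_px * p - imaging@fovWidth / 2
    out$y_mm <- out$y_px * p - imaging@fovDepth / 2
    f <- p * imaging@frameRate / imaging@interframeScale / 10  # px/frame -> cm/s
    out$u_cm_s <- out$dx_px * f
    out$v_cm_s <- out$dy_px * f
  }
  out
}

#' @rdname as.data.frame.DisplacementField
#' @export
as.data.frame.WallShearSeries <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(wall = x@wall, arclength_mm = x@arclength, x_mm = x@x,
             tau_pa = x@tau, source = x@source)
}
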