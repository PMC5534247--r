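#' Zero-mean normalised cross-correlation map
#'
#' Correlates two equally sized interrogation windows at every integer lag
#' within \code{maxLag}.  At each lag the correlation coefficient is computed
#' over the overlap region of the two windows (zero-padded linear
#' correlation, with per-lag overlap means and variances obtained by the same
#' frequency-domain machinery), so values lie in [-1, 1], are invariant to
#' affine intensity changes, and the peak is not biased toward zero lag the
#' way plain circular correlation is.  The direct-sum definition gives the
#' same map to rounding error.
#'
#' @slot values correlation at each lag, dim
#'   \code{c(2 maxLag + 1, 2 maxLag + 1)} (rows = y lag, cols = x lag).
#' @slot lags the lag axis, \code{-maxLag:maxLag}, px.
#' @slot peakLag integer (x, y) lag of the peak.
#' @slot peakValue correlation at the peak.
#' @slot degenerate TRUE when a window had zero variance (map all zero).
#' @export
setClass("CorrelationMap",
  representation(values = "matrix", lags = "integer", peakLag = "integer",
                 peakValue = "numeric", degenerate = "logical"))

#' @rdname CorrelationMap-class
#' @param winA,winB numeric matrices of identical shape (rows = y, cols = x).
#' @param maxLag largest lag searched, px (defaults to just under half the
#'   window).
#' @return a \code{CorrelationMap}.
#' @examples
#' w <- matrix(rnorm(64), 8, 8)
#' znccMap(w, w)@peakLag        # c(0, 0); peak value 1
#' @export
znccMap <- function(winA, winB, maxLag = NULL) {
  stopifnot(identical(dim(winA), dim(winB)))
  n1 <- nrow(winA); n2 <- ncol(winA)
  if (is.null(maxLag)) maxLag <- min(n1, n2) %/% 2L - 1L
  maxLag <- as.integer(min(maxLag, n1 %/% 2L - 1L, n2 %/% 2L - 1L))
  lags <- -maxLag:maxLag
  if (stats::sd(winA) == 0 || stats::sd(winB) == 0)
    return(new("CorrelationMap",
               values = matrix(0, 2 * maxLag + 1, 2 * maxLag + 1),
               lags = lags, peakLag = c(0L, 0L), peakValue = 0,
               degenerate = TRUE))
  # zero-padded linear cross-correlations; per-lag overlap statistics
  xc <- function(a, b) {
    pa <- matrix(0, 2 * n1, 2 * n2); pa[1:n1, 1:n2] <- a
    pb <- matrix(0, 2 * n1, 2 * n2); pb[1:n1, 1:n2] <- b
    cc <- Re(stats::fft(Conj(stats::fft(pa)) * stats::fft(pb),
                        inverse = TRUE)) / (4 * n1 * n2)
    cc[1L + (lags %% (2 * n1)), 1L + (lags %% (2 * n2)), drop = FALSE]
  }
  one <- matrix(1, n1, n2)
  Sab <- xc(winA, winB)
  Sa  <- xc(winA, one);     Sb  <- xc(one, winB)
  Sa2 <- xc(winA^2, one);   Sb2 <- xc(one, winB^2)
  nOv <- outer(n1 - abs(lags), n2 - abs(lags))       # overlap pixel count
  cov  <- Sab - Sa * Sb / nOv
  varA <- pmax(Sa2 - Sa^2 / nOv, 0)
  varB <- pmax(Sb2 - Sb^2 / nOv, 0)
  den <- sqrt(varA * varB)
  vals <- ifelse(den > 1e-12 * max(den), cov / den, 0)
  vals <- pmin(pmax(vals, -1), 1)
  pk <- .zncc_peak(vals, lags)
  new("CorrelationMap", values = vals, lags = lags,
      peakLag = pk$lag, peakValue = pk$value, degenerate = FALSE)
}

# Deterministic peak: maximum value, ties broken by smallest lag magnitude.
.zncc_peak <- function(vals, lags) {
  m <- max(vals)
  cand <- which(vals >= m - 1e-14, arr.ind = TRUE)
  mag <- lags[cand[, 1]]^2 + lags[cand[, 2]]^2
  best <- cand[which.min(mag), ]
  list(lag = c(lags[best[2]], lags[best[1]]), value = vals[best[1], best[2]])
}

#' Three-point Gaussian sub-pixel peak interpolation
#'
#' Fits a Gaussian through a correlation peak and its two neighbours along
#' one axis: \eqn{\delta = (\ln c_- - \ln c_+) /
#' (2\ln c_- - 4\ln c_0 + 2\ln c_+)}.  Exact for samples of any Gaussian.
#'
#' @param cMinus,c0,cPlus correlation at lag -1, 0, +1 relative to the
#'   integer peak; all must be positive with \code{c0} the largest.
#' @return list with \code{offset} (in (-1, 1), or 0 when degraded) and
#'   \code{valid} (FALSE when the preconditions fail and the vector should
#'   fall back to integer precision).
#' @export
gaussianSubpixel <- function(cMinus, c0, cPlus) {
  if (any(!is.finite(c(cMinus, c0, cPlus))) || cMinus <= 0 || c0 <= 0 ||
      cPlus <= 0 || c0 < cMinus || c0 < cPlus)
    return(list(offset = 0, valid = FALSE))
  den <- 2 * log(cMinus) - 4 * log(c0) + 2 * log(cPlus)
  if (den == 0) return(list(offset = 0, valid = TRUE))
  off <- (log(cMinus) - log(cPlus)) / den
  if (!is.finite(off) || abs(off) >= 1) return(list(offset = 0, valid = FALSE))
  list(offset = off, valid = TRUE)
}

# Interrogation-grid geometry: 0-based window starts and centres.
.piv_grid <- function(npx, w, overlap) {
  step <- max(1L, as.integer(round(w * (1 - overlap))))
  n <- (npx - w) %/% step + 1L
  starts <- (seq_len(n) - 1L) * step
  list(starts = starts, centres = starts + (w - 1) / 2, step = step, n = n)
}

# Dense predictor displacement sampled at 0-based pixel coords (vectorised).
.predict_at <- function(pred, px, py) {
  if (is.null(pred)) return(list(dx = rep(0, length(px)), dy = rep(0, length(px))))
  gx <- pred@xPx; gy <- pred@yPx
  sx <- if (length(gx) > 1) gx[2] - gx[1] else 1
  sy <- if (length(gy) > 1) gy[2] - gy[1] else 1
  i1 <- (px - gx[1]) / sx + 1
  i2 <- (py - gy[1]) / sy + 1
  list(dx = .bilinear_idx(pred@dx, i1, i2, fill = NA),
       dy = .bilinear_idx(pred@dy, i1, i2, fill = NA))
}

#' Single PIV correlation pass
#'
#' One vector per interrogation window on the overlap grid.  With a
#' predictor field, each window of the second frame is sampled at
#' predictor-shifted locations (bilinear warp) and the pass returns
#' predictor + residual, which is what lets later passes handle velocity
#' gradients.  Vectors whose magnitude exceeds \code{maxDisplacement}, or
#' whose window has no texture, are flagged rejected.
#'
#' @param frameA,frameB grayscale matrices of identical shape
#'   (rows = y, cols = x).
#' @param cfg a \code{\link{PIVConfig}}.
#' @param predictor optional \code{\link{DisplacementField}} from a previous
#'   pass.
#' @param windowSize overrides \code{cfg@windowSize} (used by the multipass
#'   schedule).
#' @return a \code{\link{DisplacementField}} (dx along columns/x, dy along
#'   rows/y, px per frame).
#' @export
pivPass <- function(frameA, frameB, cfg = PIVConfig(), predictor = NULL,
                    windowSize = cfg@windowSize) {
  stopifnot(identical(dim(frameA), dim(frameB)))
  w <- as.integer(windowSize)
  if (nrow(frameA) < w || ncol(frameA) < w)
    stop("frames (", nrow(frameA), " x ", ncol(frameA),
         ") are smaller than one ", w, " px window")
  gc_ <- .piv_grid(ncol(frameA), w, cfg@overlap)   # x / columns
  gr <- .piv_grid(nrow(frameA), w, cfg@overlap)    # y / rows
  nxv <- gc_$n; nyv <- gr$n
  dx <- dy <- pc <- matrix(0, nxv, nyv)
  flag <- matrix(0L, nxv, nyv)
  maxLag <- min(w %/% 2L - 1L, as.integer(ceiling(cfg@maxDisplacement)))
  win_rel <- 0:(w - 1L)
  for (ix in seq_len(nxv)) {
    c0 <- gc_$starts[ix]
    cols <- c0 + win_rel
    for (iy in seq_len(nyv)) {
      r0 <- gr$starts[iy]
      rows <- r0 + win_rel
      A <- frameA[rows + 1L, cols + 1L]
      pdx <- 0; pdy <- 0
      if (is.null(predictor)) {
        B <- frameB[rows + 1L, cols + 1L]
      } else {
        pix <- expand.grid(r = rows, c = cols)
        pr <- .predict_at(predictor, pix$c, pix$r)
        pr$dx[is.na(pr$dx)] <- 0; pr$dy[is.na(pr$dy)] <- 0
        B <- matrix(.bilinear_idx(frameB, pix$r + pr$dy + 1, pix$c + pr$dx + 1,
                                  fill = 0), w, w)
        pc_ctr <- .predict_at(predictor, gc_$centres[ix], gr$centres[iy])
        pdx <- if (is.na(pc_ctr$dx)) 0 else pc_ctr$dx
        pdy <- if (is.na(pc_ctr$dy)) 0 else pc_ctr$dy
      }
      cm <- znccMap(A, B, maxLag = maxLag)
      if (cm@degenerate) { flag[ix, iy] <- 2L; next }
      pk <- cm@peakLag
      pi_ <- match(pk[2], cm@lags); pj <- match(pk[1], cm@lags)
      nl <- length(cm@lags)
      sub <- c(0, 0)   # integer-precision fallback at correlation-map borders
      if (pj > 1 && pj < nl)
        sub[1] <- gaussianSubpixel(cm@values[pi_, pj - 1], cm@values[pi_, pj],
                                   cm@values[pi_, pj + 1])$offset
      if (pi_ > 1 && pi_ < nl)
        sub[2] <- gaussianSubpixel(cm@values[pi_ - 1, pj], cm@values[pi_, pj],
                                   cm@values[pi_ + 1, pj])$offset
      res <- c(pk[1] + sub[1], pk[2] + sub[2])   # this pass's own estimate
      if (sqrt(sum(res^2)) > cfg@maxDisplacement) flag[ix, iy] <- 2L
      dx[ix, iy] <- pdx + res[1]; dy[ix, iy] <- pdy + res[2]
      pc[ix, iy] <- cm@peakValue
    }
  }
  new("DisplacementField", xPx = gc_$centres, yPx = gr$centres,
      dx = dx, dy = dy, dx0 = dx, dy0 = dy, flag = flag, peakCorr = pc)
}

#' Local spurious-vector filter
#'
#' Compares every vector against its 3 x 3 neighbourhood (border vectors use
#' the available neighbours).  A component deviating from the neighbourhood
#' reference (median by default; mean available for fidelity with simpler
#' filters) by more than \code{max(filterFloor, filterK * MAD)} marks the
#' vector spurious; it is replaced by the neighbourhood median and flagged
#' \code{replaced}, with the original estimate retained.  Vectors already
#' rejected by the correlation stage are likewise replaced when they have
#' any usable neighbour.  The filter is idempotent on its own output.
#'
#' @param field a \code{\link{DisplacementField}}.
#' @param cfg a \code{\link{PIVConfig}}.
#' @return the filtered \code{\link{DisplacementField}}.
#' @export
validateVectors <- function(field, cfg = PIVConfig()) {
  nx <- length(field@xPx); ny <- length(field@yPx)
  dx <- field@dx; dy <- field@dy; flag <- field@flag
  newdx <- dx; newdy <- dy; newflag <- flag
  centre_stat <- if (cfg@filterStat == "median") stats::median else mean
  for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
    nbx <- max(1, ix - 1):min(nx, ix + 1)
    nby <- max(1, iy - 1):min(ny, iy + 1)
    sel <- expand.grid(a = nbx, b = nby)
    sel <- sel[!(sel$a == ix & sel$b == iy), ]
    ok <- flag[cbind(sel$a, sel$b)] != 2L
    if (!any(ok)) next
    ndx <- dx[cbind(sel$a, sel$b)][ok]
    ndy <- dy[cbind(sel$a, sel$b)][ok]
    mx <- centre_stat(ndx); my <- centre_stat(ndy)
    madx <- stats::median(abs(ndx - stats::median(ndx)))
    mady <- stats::median(abs(ndy - stats::median(ndy)))
    tolx <- max(cfg@filterFloor, cfg@filterK * madx)
    toly <- max(cfg@filterFloor, cfg@filterK * mady)
    bad <- flag[ix, iy] == 2L ||
      abs(dx[ix, iy] - mx) > tolx || abs(dy[ix, iy] - my) > toly
    if (bad) {
      newdx[ix, iy] <- stats::median(ndx)
      newdy[ix, iy] <- stats::median(ndy)
      newflag[ix, iy] <- 1L
    }
  }
  new("DisplacementField", xPx = field@xPx, yPx = field@yPx,
      dx = newdx, dy = newdy, dx0 = field@dx0, dy0 = field@dy0,
      flag = newflag, peakCorr = field@peakCorr)
}

# 3x3 mean smoothing of a displacement field (predictor conditioning).
.smooth_field <- function(field) {
  sm <- function(m) {
    nx <- nrow(m); ny <- ncol(m)
    out <- m
    for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
      out[ix, iy] <- mean(m[max(1, ix - 1):min(nx, ix + 1),
                            max(1, iy - 1):min(ny, iy + 1)])
    }
    out
  }
  field@dx <- sm(field@dx); field@dy <- sm(field@dy)
  field
}

#' Multi-pass PIV with window deformation
#'
#' Runs \code{nPasses} correlation passes, each followed by the local
#' spurious-vector filter.  Early passes use a doubled window to capture
#' large displacements robustly; the final two passes use the configured
#' window.  Each pass after the first warps the second frame by the smoothed,
#' interpolated field of the previous pass, so the residual correlation only
#' has to resolve what the predictor missed -- the standard remedy for high
#' velocity gradients.
#'
#' @param frameA,frameB grayscale matrices of identical shape.
#' @param cfg a \code{\link{PIVConfig}}.
#' @return the final-pass \code{\link{DisplacementField}}.
#' @export
pivMultipass <- function(frameA, frameB, cfg = PIVConfig()) {
  n <- cfg@nPasses
  sizes <- ifelse(seq_len(n) <= n - 2L, 2L * cfg@windowSize, cfg@windowSize)
  sizes <- pmin(sizes, min(dim(frameA)))
  sizes <- sizes - sizes %% 2L
  field <- NULL
  for (p in seq_len(n)) {
    pred <- if (is.null(field)) NULL else .smooth_field(field)
    field <- pivPass(frameA, frameB, cfg, predictor = pred,
                     windowSize = sizes[p])
    field <- validateVectors(field, cfg)
  }
  field
}

#' Convert a displacement field to physical velocity
#'
#' Displacements in px/frame become velocities via the pixel pitch and frame
#' interval: \code{u = dx * pitch * frameRate / interframeScale} (mm/s,
#' reported in cm/s).  Window centres are mapped to mm coordinates; rejected
#' vectors are masked out.
#'
#' @param field a \code{\link{DisplacementField}}.
#' @param imaging the \code{\link{ImagingConfig}} the frames were rendered
#'   with.
#' @param time phase stamp for the resulting field, s.
#' @return a \code{\link{VelocityField}}.
#' @export
toVelocity <- function(field, imaging, time = 0) {
  stopifnot(is(field, "DisplacementField"), is(imaging, "ImagingConfig"))
  p <- pixelPitch(imaging)
  f <- p * imaging@frameRate / imaging@interframeScale / 10   # px -> cm/s
  x_mm <- (field@xPx + 0.5) * p - imaging@fovWidth / 2
  y_mm <- (field@yPx + 0.5) * p - imaging@fovDepth / 2
  mask <- field@flag != 2L
  VelocityField(x_mm, y_mm, field@dx * f, field@dy * f, time = time,
                mask = mask)
}

#' Restrict a velocity field to the phantom lumen
#'
#' The region-of-interest step of the measurement chain: vectors whose grid
#' point lies outside the lumen interior (where interrogation windows see no
#' tracers, only noise) are masked out and zeroed.
#'
#' @param field a \code{\link{VelocityField}} (typically from
#'   \code{\link{toVelocity}}).
#' @param phantom a \code{\link{StenosisPhantom}}.
#' @return the masked \code{\link{VelocityField}}.
#' @export
maskToLumen <- function(field, phantom) {
  w <- .wall_positions(field@x, phantom)
  inl <- outer(seq_along(field@x), seq_along(field@y),
               function(i, j) field@y[j] > w$lower[i] & field@y[j] < w$upper[i])
  VelocityField(field@x, field@y, field@u, field@v, time = field@time,
                mask = field@mask & inl)
}

#' Phase-average displacement fields across cycles
#'
#' Averages a frame-pair series over repeated cycles at matched phase, using
#' only valid or replaced vectors, and retains the across-cycle standard
#' deviation of each vector for error reporting.
#'
#' @param fields list of \code{\link{DisplacementField}}s (one per frame
#'   pair), of length divisible by \code{framesPerCycle}.
#' @param framesPerCycle number of pairs per cycle.
#' @return list of \code{framesPerCycle} averaged
#'   \code{\link{DisplacementField}}s, each with an \code{"sd"} attribute
#'   (list of dx/dy SD matrices) and an \code{"n"} attribute (contributing
#'   cycles per vector).
#' @export
phaseAverage <- function(fields, framesPerCycle) {
  if (length(fields) %% framesPerCycle != 0)
    stop("length(fields) = ", length(fields),
         " is not divisible by framesPerCycle = ", framesPerCycle)
  nCyc <- length(fields) %/% framesPerCycle
  lapply(seq_len(framesPerCycle), function(ph) {
    grp <- fields[ph + (seq_len(nCyc) - 1L) * framesPerCycle]
    tmpl <- grp[[1]]
    d <- dim(tmpl@dx)
    sumx <- sumy <- sumx2 <- sumy2 <- nmat <- matrix(0, d[1], d[2])
    for (g in grp) {
      use <- g@flag != 2L
      sumx[use] <- sumx[use] + g@dx[use]
      sumy[use] <- sumy[use] + g@dy[use]
      sumx2[use] <- sumx2[use] + g@dx[use]^2
      sumy2[use] <- sumy2[use] + g@dy[use]^2
      nmat[use] <- nmat[use] + 1
    }
    ok <- nmat > 0
    dx <- dy <- matrix(0, d[1], d[2])
    dx[ok] <- sumx[ok] / nmat[ok]
    dy[ok] <- sumy[ok] / nmat[ok]
    sdx <- sdy <- matrix(NA_real_, d[1], d[2])
    m2 <- nmat > 1
    sdx[m2] <- sqrt(pmax(0, (sumx2[m2] - sumx[m2]^2 / nmat[m2]) / (nmat[m2] - 1)))
    sdy[m2] <- sqrt(pmax(0, (sumy2[m2] - sumy[m2]^2 / nmat[m2]) / (nmat[m2] - 1)))
    pk <- Reduce(`+`, lapply(grp, slot, "peakCorr")) / nCyc
    out <- new("DisplacementField", xPx = tmpl@xPx, yPx = tmpl@yPx,
               dx = dx, dy = dy, dx0 = dx, dy0 = dy,
               flag = matrix(ifelse(ok, 0L, 2L), d[1], d[2]),
               peakCorr = pk)
    attr(out, "sd") <- list(dx = sdx, dy = sdy)
    attr(out, "n") <- nmat
    out
  })
}
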