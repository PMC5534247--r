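test_that("ZNCC map matches the direct-sum definition and its invariances", {
  set.seed(1)
  w <- matrix(stats::runif(256), 16, 16)
  cm <- znccMap(w, w, maxLag = 5)
  expect_equal(cm@peakLag, c(0L, 0L))
  expect_equal(cm@peakValue, 1, tolerance = 1e-12)
  expect_true(all(cm@values >= -1 - 1e-12 & cm@values <= 1 + 1e-12))

  # direct-sum oracle: correlation coefficient over the per-lag overlap
  directZncc <- function(a, b, maxLag) {
    n1 <- nrow(a); n2 <- ncol(a)
    sapply(-maxLag:maxLag, function(lx)
      sapply(-maxLag:maxLag, function(ly) {
        ii <- intersect(1:n1, (1:n1) - ly)     # rows with b(i+ly) in range
        jj <- intersect(1:n2, (1:n2) - lx)
        av <- as.vector(a[ii, jj])
        bv <- as.vector(b[ii + ly, jj + lx])
        suppressWarnings(stats::cor(av, bv))
      }))
  }
  b <- matrix(stats::runif(256), 16, 16)
  cm2 <- znccMap(w, b, maxLag = 4)
  expect_equal(cm2@values, directZncc(w, b, 4), tolerance = 1e-10)

  # circular shift by (x = 2, y = 3) is recovered exactly
  bs <- w[((0:15 - 3) %% 16) + 1, ((0:15 - 2) %% 16) + 1]
  expect_equal(znccMap(w, bs)@peakLag, c(2L, 3L))
  # affine intensity invariance: identical map to the self-correlation
  cma <- znccMap(w, 2 * w + 10, maxLag = 5)
  expect_equal(cma@values, cm@values, tolerance = 1e-12)
  expect_equal(cma@peakLag, c(0L, 0L))
  # constant window -> degenerate, not an exception
  cd <- znccMap(matrix(1, 16, 16), w)
  expect_true(cd@degenerate)
})

test_that("Gaussian sub-pixel fit is exact on Gaussian peaks and matches least squares", {
  # symmetric neighbours -> zero offset
  expect_equal(gaussianSubpixel(0.4, 0.9, 0.4)$offset, 0)
  # worked closed-form case: Gaussian centred at +0.3
  g <- gaussianSubpixel(exp(-1.69), exp(-0.09), exp(-0.49))
  expect_equal(g$offset, 0.3, tolerance = 1e-12)
  expect_true(g$valid)
  # exact on randomised noiseless Gaussian triplets
  set.seed(7)
  for (k in 1:50) {
    d0 <- stats::runif(1, -0.45, 0.45)
    s2 <- stats::runif(1, 0.3, 3)
    a <- stats::runif(1, 0.5, 2)
    cc <- a * exp(-((-1:1) - d0)^2 / (2 * s2))
    expect_equal(gaussianSubpixel(cc[1], cc[2], cc[3])$offset, d0,
                 tolerance = 1e-12)
    # independent least-squares fit of the log-Gaussian (quadratic model):
    # centre = -b/(2c) from the fitted coefficients
    fit <- stats::lm(log(cc) ~ poly(x, 2, raw = TRUE),
                     data = list(cc = cc, x = -1:1))
    ctr <- -stats::coef(fit)[2] / (2 * stats::coef(fit)[3])
    expect_equal(gaussianSubpixel(cc[1], cc[2], cc[3])$offset,
                 unname(ctr), tolerance = 1e-9)
  }
  # degraded inputs fall back to integer precision
  expect_false(gaussianSubpixel(-0.1, 0.5, 0.2)$valid)
  expect_false(gaussianSubpixel(0.6, 0.5, 0.2)$valid)
  expect_equal(gaussianSubpixel(0.6, 0.5, 0.2)$offset, 0)
})

test_that("sub-pixel estimation stays unbiased under additive noise", {
  set.seed(11)
  d0 <- 0.3
  est <- replicate(400, {
    cc <- exp(-((-1:1) - d0)^2 / 2) + stats::rnorm(3, 0, 0.02)
    if (all(cc > 0) && which.max(cc) == 2)
      gaussianSubpixel(cc[1], cc[2], cc[3])$offset else NA
  })
  expect_lt(abs(mean(est, na.rm = TRUE) - d0), 0.02)
})

test_that("a single pass recovers translations on the overlap grid", {
  img <- fixImaging()
  pair <- fixShiftedPair(2.5, 0, img)
  cfg <- PIVConfig()
  # identical frames -> all vectors zero (to rounding)
  f0 <- pivPass(pair$a, pair$a, cfg)
  expect_true(all(abs(f0@dx) < 1e-6) && all(abs(f0@dy) < 1e-6))
  # known sub-pixel shift
  f <- pivPass(pair$a, pair$b, cfg)
  ok <- vectorFlags(f) != 2L
  expect_lt(abs(mean(f@dx[ok]) - 2.5), 0.05)
  expect_lt(abs(mean(f@dy[ok])), 0.05)
  # grid count arithmetic: floor((image - window)/step) + 1
  expect_length(f@xPx, (128 - 32) %/% 16 + 1)
  expect_length(f@yPx, (128 - 32) %/% 16 + 1)
  expect_equal(diff(f@xPx[1:2]), 16)
  expect_error(pivPass(matrix(0, 16, 16), matrix(0, 16, 16),
                       PIVConfig(windowSize = 32L)), "window")
})

test_that("the local filter rejects and repairs spurious vectors, idempotently", {
  cfg <- PIVConfig()
  mk <- function(dx) new("DisplacementField",
    xPx = seq(15.5, by = 16, length.out = 5),
    yPx = seq(15.5, by = 16, length.out = 5),
    dx = dx, dy = matrix(0, 5, 5), dx0 = dx, dy0 = matrix(0, 5, 5),
    flag = matrix(0L, 5, 5), peakCorr = matrix(1, 5, 5))
  # uniform field -> untouched
  u <- mk(matrix(2, 5, 5))
  vu <- validateVectors(u, cfg)
  expect_identical(vu@dx, u@dx)
  expect_true(all(vectorFlags(vu) == 0L))
  # one injected outlier among uniform neighbours
  d <- matrix(2, 5, 5); d[3, 3] <- 10
  vf <- validateVectors(mk(d), cfg)
  expect_equal(vf@dx[3, 3], 2)
  expect_equal(vectorFlags(vf)[3, 3], 1L)
  expect_equal(vf@dx0[3, 3], 10)          # original retained
  expect_equal(sum(vectorFlags(vf) == 1L), 1L)
  # idempotence: a second application changes nothing
  vf2 <- validateVectors(vf, cfg)
  expect_identical(vf2@dx, vf@dx)
  expect_identical(sum(vectorFlags(vf2) != 0L), sum(vectorFlags(vf) != 0L))
  # mean-based variant also catches the outlier
  vm <- validateVectors(mk(d), PIVConfig(filterStat = "mean"))
  expect_equal(vectorFlags(vm)[3, 3], 1L)
})

test_that("multipass window deformation beats a single pass on shear flow", {
  sp <- fixShearPair(0.05)
  cfg <- PIVConfig()
  single <- validateVectors(pivPass(sp$a, sp$b, cfg), cfg)
  multi <- pivMultipass(sp$a, sp$b, cfg)
  rmsS <- sqrt(mean((single@dx - sp$truth(single))^2))
  rmsM <- sqrt(mean((multi@dx - sp$truth(multi))^2))
  expect_lt(rmsM, rmsS)
  # interior vectors (full neighbourhoods) are accurate to a few hundredths
  inner <- 2:(length(multi@yPx) - 1)
  errInner <- (multi@dx - sp$truth(multi))[2:(length(multi@xPx) - 1), inner]
  expect_lt(mean(abs(errInner)), 0.1)
  # zero displacement is a fixed point of the multipass chain
  fz <- pivMultipass(sp$a, sp$a, cfg)
  expect_true(all(abs(fz@dx) < 1e-6) && all(abs(fz@dy) < 1e-6))
  # uniform shift through the full chain
  up <- fixShiftedPair(2.5, 0)
  fu <- pivMultipass(up$a, up$b, cfg)
  ok <- vectorFlags(fu) != 2L
  expect_lt(mean(abs(fu@dx[ok] - 2.5)), 0.05)
})

test_that("displacements convert to physical velocity and back", {
  img <- ImagingConfig()    # 0.02 mm/px, 150 fps
  f <- new("DisplacementField",
           xPx = c(15.5, 31.5), yPx = c(15.5, 31.5),
           dx = matrix(3, 2, 2), dy = matrix(0, 2, 2),
           dx0 = matrix(3, 2, 2), dy0 = matrix(0, 2, 2),
           flag = matrix(0L, 2, 2), peakCorr = matrix(1, 2, 2))
  v <- toVelocity(f, img)
  # 3 px x 0.02 mm/px x 150 fps = 9 mm/s = 0.9 cm/s
  expect_equal(unique(as.vector(uVelocity(v))), 0.9, tolerance = 1e-12)
  expect_true(all(vVelocity(v) == 0))
  # zero displacement -> zero velocity
  fz <- f; fz@dx <- matrix(0, 2, 2)
  expect_true(all(uVelocity(toVelocity(fz, img)) == 0))
  # round trip velocity -> displacement -> velocity is the identity
  back <- uVelocity(v) * 10 / (pixelPitch(img) * img@frameRate /
                                 img@interframeScale)
  expect_equal(back, f@dx, tolerance = 1e-12)
  # interframeScale rescales the conversion
  img2 <- ImagingConfig(interframeScale = 0.5)
  expect_equal(unique(as.vector(uVelocity(toVelocity(f, img2)))), 1.8,
               tolerance = 1e-12)
})

test_that("phase averaging pools cycles at matched phase with SD bookkeeping", {
  base <- matrix(2, 3, 3)
  mk <- function(dx) new("DisplacementField",
    xPx = c(0, 16, 32), yPx = c(0, 16, 32), dx = dx, dy = matrix(0, 3, 3),
    dx0 = dx, dy0 = matrix(0, 3, 3), flag = matrix(0L, 3, 3),
    peakCorr = matrix(1, 3, 3))
  # identical cycles -> the average equals any single cycle
  fields <- rep(list(mk(base)), 6)
  avg <- phaseAverage(fields, framesPerCycle = 2L)
  expect_length(avg, 2L)
  expect_equal(avg[[1]]@dx, base)
  expect_equal(attr(avg[[1]], "n")[1, 1], 3)
  expect_error(phaseAverage(fields, framesPerCycle = 4L), "divisible")
  # i.i.d. noise across cycles: averaged SD shrinks like 1/sqrt(nCycles)
  set.seed(5)
  noisy <- lapply(1:30, function(k) mk(base + matrix(rnorm(9, 0, 0.5), 3, 3)))
  a1 <- phaseAverage(noisy, framesPerCycle = 10L)   # 3 cycles of 10 phases
  pooledSD <- mean(vapply(a1, function(f) mean(attr(f, "sd")$dx), numeric(1)))
  avgNoise <- sd(vapply(a1, function(f) f@dx[2, 2] - 2, numeric(1)))
  expect_lt(abs(avgNoise - 0.5 / sqrt(3)) / (0.5 / sqrt(3)), 0.5)
  expect_lt(abs(pooledSD - 0.5) / 0.5, 0.3)
  # rejected vectors are excluded from the pool
  bad <- mk(base + 100); bad@flag[] <- 2L
  avg2 <- phaseAverage(list(mk(base), bad, mk(base)), framesPerCycle = 1L)
  expect_equal(avg2[[1]]@dx, base)
  expect_equal(attr(avg2[[1]], "n")[1, 1], 2)
})
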