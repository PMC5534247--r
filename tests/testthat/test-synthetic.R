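test_that("particle seeding is Poisson-dense, uniform over the lumen, reproducible", {
  ph <- StenosisPhantom(severity = 0.5)
  img <- ImagingConfig(particleDensity = 5)
  ens <- seedParticles(ph, img, seed = 42L)
  # expected count = density x lumen area within the FOV
  xs <- seq(-7.5, 7.5, length.out = 4001)
  area <- sum(2 * pmin(lumenHalfwidth(xs, ph), 3.5)) * (xs[2] - xs[1])
  lambda <- 5 * area
  expect_lt(abs(length(ens@x) - lambda), 4 * sqrt(lambda))
  # containment: every particle strictly inside the walls
  expect_true(all(abs(ens@y) < lumenHalfwidth(ens@x, ph)))
  expect_true(all(ens@intensity > 0))
  # determinism
  ens2 <- seedParticles(ph, img, seed = 42L)
  expect_identical(ens@x, ens2@x)
  expect_identical(ens@y, ens2@y)
  # distinct seeds: counts stay Poisson-like (dispersion sanity check)
  counts <- vapply(1:30, function(s)
    length(seedParticles(ph, ImagingConfig(particleDensity = 0.5),
                         seed = s)@x), numeric(1))
  expect_gt(var(counts) / mean(counts), 0.3)
  expect_lt(var(counts) / mean(counts), 3)
})

test_that("advection is exact on constant and Poiseuille fields", {
  ph <- StenosisPhantom(severity = 0)
  ens <- new("ParticleEnsemble", x = c(-5, 0, 2), y = c(0, 1.2, -2.2),
             intensity = rep(1, 3), seed = 1L)
  x <- seq(-10, 10, length.out = 41); y <- seq(-3, 3, length.out = 25)
  # zero field: no motion
  zf <- VelocityField(x, y, matrix(0, 41, 25))
  e0 <- advectParticles(ens, zf, dt = 1)
  expect_identical(e0@x, ens@x)
  # uniform u = 1 cm/s = 10 mm/s, dt = 1/150 -> exactly 0.0667 mm
  uf <- VelocityField(x, y, matrix(1, 41, 25))
  e1 <- advectParticles(ens, uf, dt = 1 / 150)
  expect_equal(e1@x - ens@x, rep(10 / 150, 3), tolerance = 1e-12)
  expect_equal(e1@y, ens@y)
  # Poiseuille: centreline advances 2 vbar dt, wall particle stays
  Q <- 16e-3 / 3600
  pf <- poiseuilleField(Q, ph, nx = 201, ny = 201)
  vbar <- Q / (pi * 2.5e-3^2)
  epois <- new("ParticleEnsemble", x = c(0, 0), y = c(0, 2.5),
               intensity = c(1, 1), seed = 1L)
  ea <- advectParticles(epois, pf, dt = 0.01)
  expect_equal(ea@x[1], 2 * vbar * 1000 * 0.01, tolerance = 1e-3)
  expect_equal(ea@x[2], 0, tolerance = 1e-6)
})

test_that("rendering produces exact Gaussian blobs with linear superposition", {
  img <- ImagingConfig(fovDepth = 1.28, fovWidth = 1.28, imageRows = 64L,
                       imageCols = 64L, noiseSigma = 0, psfSigma = 1.5)
  # empty ensemble, zero noise -> all-zero frame
  empty <- new("ParticleEnsemble", x = numeric(), y = numeric(),
               intensity = numeric(), seed = 1L)
  expect_true(all(renderFrame(empty, img) == 0))
  # single particle at the centre of pixel (row 32, col 32), 0-based (31, 31)
  p <- pixelPitch(img)
  x0 <- (31 + 0.5) * p - 0.64; y0 <- (31 + 0.5) * p - 0.64
  one <- new("ParticleEnsemble", x = x0, y = y0, intensity = 1, seed = 1L)
  fr <- renderFrame(one, img)
  expect_equal(unname(which(fr == max(fr), arr.ind = TRUE)[1, ]),
               c(32L, 32L))
  # profile matches the Gaussian exactly along the row
  amp <- 0.5 * (2^16 - 1)
  cols <- 26:38
  expect_equal(fr[32, cols], amp * exp(-((cols - 32)^2) / (2 * 1.5^2)),
               tolerance = 1e-6)
  # total intensity ~ count x blob integral (2 pi sigma^2 amp mean-intensity)
  many <- new("ParticleEnsemble",
              x = stats::runif(40, -0.4, 0.4), y = stats::runif(40, -0.4, 0.4),
              intensity = rep(0.8, 40), seed = 1L)
  tot <- sum(renderFrame(many, img))
  expect_equal(tot, 40 * 0.8 * amp * 2 * pi * 1.5^2, tolerance = 0.02)
})

test_that("stack generation honours the frame-count arithmetic and determinism", {
  ph <- StenosisPhantom(severity = 0)
  # 150 fps x 2 s cycles x 3 cycles -> 900 frames (tiny frames keep it cheap)
  img <- ImagingConfig(fovDepth = 0.32, fovWidth = 0.64, imageRows = 16L,
                       imageCols = 32L, particleDensity = 2, noiseSigma = 0,
                       dropoutRate = 0)
  still <- VelocityField(seq(-20, 20, length.out = 11),
                         seq(-2.6, 2.6, length.out = 11),
                         matrix(0, 11, 11))
  st <- generateStack(ph, still, img, nCycles = 3, period = 2, seed = 5)
  expect_equal(nFrames(st), 900L)
  expect_equal(phaseTimes(st), (0:899) / 150)
  # constant zero flow, zero noise/dropout -> all frames identical
  expect_identical(frames(st)[[1]], frames(st)[[500]])
  # bit-identical stacks under the same seed
  img2 <- ImagingConfig(fovDepth = 0.64, fovWidth = 1.28, imageRows = 32L,
                        imageCols = 64L, particleDensity = 10,
                        noiseSigma = 0.02, dropoutRate = 0.05)
  mk <- function() generateStack(ph, still, img2, nCycles = 1, period = 0.05,
                                 seed = 9)
  expect_identical(frames(mk()), frames(mk()))
  # ground-truth bookkeeping: one advecting field per interval
  expect_length(st@truthIndex, 899L)
  expect_s4_class(truthField(st, 1L), "VelocityField")
})

test_that("untrackable displacements trigger the interframe-scale warning", {
  ph <- StenosisPhantom(severity = 0)
  img <- ImagingConfig(fovDepth = 0.64, fovWidth = 1.28, imageRows = 32L,
                       imageCols = 64L, particleDensity = 1)
  fast <- VelocityField(seq(-20, 20, length.out = 11),
                        seq(-2.6, 2.6, length.out = 11),
                        matrix(100, 11, 11))   # 100 cm/s
  expect_warning(generateStack(ph, fast, img, nCycles = 1, period = 0.02,
                               seed = 1), "interframeScale")
})

test_that("the default pipeline recovers ground truth to sub-tenth-pixel accuracy", {
  # uniform advection at 6 px/frame, rendered and tracked end to end
  img <- fixImaging(rows = 160L, cols = 160L, noiseSigma = 0.02,
                    interframeScale = 1)
  p <- pixelPitch(img)
  speed_cms <- 6 * p * img@frameRate / 10          # 6 px/frame
  field <- VelocityField(seq(-3, 3, length.out = 31),
                         seq(-3, 3, length.out = 31),
                         matrix(speed_cms, 31, 31))
  ph <- StenosisPhantom(severity = 0)
  st <- generateStack(ph, field, img, nCycles = 1, period = 3 / 150, seed = 21)
  est <- pivMultipass(frames(st)[[1]], frames(st)[[2]], PIVConfig())
  ok <- vectorFlags(est) == 0L
  expect_gt(mean(ok), 0.8)
  expect_lt(mean(abs(est@dx[ok] - 6)), 0.1)
  expect_lt(mean(abs(est@dy[ok])), 0.1)
})
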