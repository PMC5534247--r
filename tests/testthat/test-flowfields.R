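test_that("pump waveform is periodic, non-negative and has the right mean and peak", {
  w <- PulsatileWaveform()   # 16 L/h mean, 30 cycles/min, 35/65, peak 2x
  expect_equal(w@meanFlow, 16e-3 / 3600, tolerance = 1e-12)
  # degenerate peak factor -> constant flow at the mean
  wc <- PulsatileWaveform(peakFactor = 1)
  t <- seq(0, 4, by = 0.01)
  expect_equal(flowRateAt(t, wc), rep(16e-3 / 3600, length(t)),
               tolerance = 1e-12)
  # quadrature mean over one period (piecewise-smooth: integrate each piece)
  ts <- 0.35 * 2
  m <- (stats::integrate(function(tt) flowRateAt(tt, w), 0, ts,
                         rel.tol = 1e-12)$value +
        stats::integrate(function(tt) flowRateAt(tt, w), ts, 2,
                         rel.tol = 1e-12)$value) / 2
  expect_equal(m / w@meanFlow, 1, tolerance = 1e-9)
  # periodicity and non-negativity
  expect_equal(flowRateAt(t + 2, w), flowRateAt(t, w), tolerance = 1e-12)
  expect_true(all(flowRateAt(t, w) >= 0))
  # peak value and location
  expect_equal(flowRateAt(systolicPeakTime(w), w), 2 * w@meanFlow,
               tolerance = 1e-12)
  expect_equal(max(flowRateAt(seq(0, 2, by = 1e-4), w)), 2 * w@meanFlow,
               tolerance = 1e-6)
  # a peak below the mean is contradictory
  expect_error(PulsatileWaveform(peakFactor = 0.5), "peakFactor")
})

test_that("Poiseuille reference has the closed-form centreline, mean and wall gradient", {
  ph <- StenosisPhantom(severity = 0)
  Q <- 16e-3 / 3600
  f <- poiseuilleField(Q, ph, nx = 101, ny = 201)
  vbar <- Q / (pi * 2.5e-3^2)             # 0.226 m/s
  expect_equal(vbar, 0.2263, tolerance = 1e-3)
  expect_equal(max(uVelocity(f)), 2 * vbar * 100, tolerance = 1e-3)
  expect_true(all(vVelocity(f) == 0))
  # near-wall velocity gradient tends to 4 vbar / R (central difference)
  y <- yCoords(f); iy <- which.min(abs(y - 2.4))
  grad_si <- abs((f@u[50, iy + 1] - f@u[50, iy - 1]) /
                 (y[iy + 1] - y[iy - 1])) * 10         # (cm/s)/mm -> 1/s
  expect_equal(grad_si, 4 * vbar * (y[iy] * 1e-3) / (2.5e-3)^2,
               tolerance = 1e-6)
  # zero flow -> zero field
  f0 <- poiseuilleField(0, ph, nx = 21, ny = 21)
  expect_true(all(uVelocity(f0) == 0))
  expect_error(poiseuilleField(Q, StenosisPhantom(severity = 0.3)),
               "severity")
})

test_that("entrance length follows 0.06 Re D and reproduces the 70 cm requirement", {
  water <- FluidProperties(viscosity = 8.7e-4)
  expect_equal(entranceLength(5e-3, 0, water), 0)
  # 5 mm tube at 45 cm/s in water at 26 C: at least 70 cm of inlet is needed
  L <- entranceLength(5e-3, 0.45, water)
  expect_equal(L, 0.06 * (1000 * 0.45 * 5e-3 / 8.7e-4) * 5e-3,
               tolerance = 1e-12)
  expect_gte(L, 0.70)
  # with the tenfold-higher nominal viscosity the same formula gives ~7.8 cm
  expect_equal(entranceLength(5e-3, 0.45, FluidProperties(viscosity = 0.0087)),
               L / 10, tolerance = 1e-12)
})

test_that("quasi-steady cycle tags phases and tracks the waveform", {
  ph <- StenosisPhantom(severity = 0.3)
  prob <- NavierStokesProblem(ph, flowRate = 16e-3 / 3600,
                              nAxial = 49L, nRadial = 13L)
  # constant waveform -> all phases identical within solver tolerance
  wc <- PulsatileWaveform(peakFactor = 1)
  fc <- quasiSteadyCycle(prob, wc, nPhases = 3L)
  expect_length(fc, 3L)
  expect_equal(attr(fc, "phaseTimes"), c(0, 2 / 3, 4 / 3))
  expect_equal(uVelocity(fc[[1]]), uVelocity(fc[[2]]), tolerance = 1e-4)
  # pulsatile waveform: the systolic-peak phase dominates
  w <- PulsatileWaveform()
  fp <- quasiSteadyCycle(prob, w, nPhases = 4L)
  peaks <- vapply(fp, function(f) max(uVelocity(f)), numeric(1))
  tp <- attr(fp, "phaseTimes")
  expect_equal(which.max(peaks),
               which.max(flowRateAt(tp, w)))
  expect_gt(max(peaks), min(peaks))
  expect_true(all(tp >= 0 & tp < w@period))
  expect_error(quasiSteadyCycle(prob, w, nPhases = 1L), "nPhases")
})
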