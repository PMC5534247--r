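fluid87 <- FluidProperties()   # the nominal 0.0087 Pa s working fluid

test_that("the shear field is exact on affine velocity fields", {
  x <- seq(-5, 5, length.out = 21); y <- seq(-2, 2, length.out = 21)
  # uniform flow -> zero stress
  su <- shearField(VelocityField(x, y, matrix(7, 21, 21)), fluid87)
  expect_true(all(abs(su@tau[su@mask]) < 1e-12))
  # u = k y with k = 100 /s (u_cm_s = 10 y_mm) -> tau = 0.87 Pa everywhere
  u <- matrix(rep(10 * y, each = 21), 21, 21)
  sl <- shearField(VelocityField(x, y, u), fluid87)
  expect_equal(range(sl@tau[sl@mask]), c(0.87, 0.87), tolerance = 1e-12)
  # solid-body rotation: the two gradient terms cancel
  om <- 10
  ur <- -om * matrix(rep(y, each = 21), 21, 21)
  vr <- om * matrix(rep(x, times = 21), 21, 21)
  sr <- shearField(VelocityField(x, y, ur, vr), fluid87)
  expect_lt(max(abs(sr@tau[sr@mask])), 1e-12)
  # a random affine field: mu * (c_vx + c_uy), exact
  set.seed(2)
  cf <- stats::rnorm(6)
  ua <- outer(x, y, function(xx, yy) cf[1] + cf[2] * xx + cf[3] * yy)
  va <- outer(x, y, function(xx, yy) cf[4] + cf[5] * xx + cf[6] * yy)
  sa <- shearField(VelocityField(x, y, ua, va), fluid87)
  expect_equal(unique(round(sa@tau[sa@mask], 12)),
               round(fluid87@viscosity * (cf[5] + cf[3]) * 10, 12))
  expect_error(shearField(VelocityField(1:2, 1:2, matrix(0, 2, 2)), fluid87),
               "3 points")
})

test_that("masked boundaries never use exterior values", {
  x <- seq(-5, 5, length.out = 21); y <- seq(-3, 3, length.out = 31)
  ph <- StenosisPhantom(severity = 0)
  mask <- lumenMask(ph, x, y)
  u <- matrix(rep(10 * y, each = 21), 21, 31)
  # poison the exterior: gradients inside must be unaffected
  u2 <- u; u2[!mask] <- 1e6
  vf <- VelocityField(x, y, u2, mask = mask)
  sf <- shearField(vf, fluid87)
  expect_equal(range(sf@tau[sf@mask]), c(0.87, 0.87), tolerance = 1e-9)
  expect_true(all(is.na(sf@tau[!sf@mask])))
})

test_that("wall series recovers the Poiseuille closed form 4 mu vbar / R", {
  ph <- StenosisPhantom(severity = 0)
  Q <- 16e-3 / 3600
  vbar <- Q / (pi * 2.5e-3^2)
  twExact <- 4 * fluid87@viscosity * vbar / 2.5e-3   # ~3.15 Pa
  f <- poiseuilleField(Q, ph, nx = 201, ny = 65)
  walls <- wallCurves(ph, 101L)
  ws <- wallShear(f, fluid87, walls)
  expect_true(all(abs(ws$upper@tau - twExact) / twExact < 0.05))
  expect_true(all(abs(ws$lower@tau - twExact) / twExact < 0.05))
  # refinement brings it within 1%
  f2 <- poiseuilleField(Q, ph, nx = 201, ny = 129)
  ws2 <- wallShear(f2, fluid87, walls)
  expect_true(all(abs(ws2$upper@tau - twExact) / twExact < 0.01))
  # wall-normal variant agrees on the straight wall
  wsn <- wallShear(f, fluid87, walls, method = "normal")
  expect_true(all(abs(wsn$upper@tau - twExact) / twExact < 0.05))
  # zero flow -> zero stress
  wz <- wallShear(poiseuilleField(0, ph, nx = 51, ny = 33), fluid87, walls)
  expect_true(all(wz$upper@tau == 0))
})

test_that("stenotic wall shear peaks upstream of the throat on solver fields", {
  sw <- fixSolverSweep()
  run5 <- sw$runs[[2]]                     # severity 0.5
  ws <- wallShear(run5$field, sw$fluid, run5$walls)
  s <- wssSummary(ws, plaqueLength = 8)
  expect_true(all(s$max_x_mm < 0))
  expect_true(all(s$upstream_max_pa >= s$downstream_max_pa))
})

test_that("wss summaries order severities and handle degenerate input", {
  sw <- fixSolverSweep()
  maxima <- vapply(sw$runs, function(r) {
    ws <- wallShear(r$field, sw$fluid, r$walls)
    max(wssSummary(ws)$max_tau_pa)
  }, numeric(1))
  expect_true(all(diff(maxima) > 0))       # 0.3 < 0.5 < 0.7
  # single-point series: that point is every statistic
  one <- new("WallShearSeries", wall = "upper", arclength = 1, x = 2,
             tau = 3.5, throatIndex = 1L, source = "solver")
  s1 <- wssSummary(one)
  expect_equal(s1$max_tau_pa, 3.5)
  expect_equal(s1$downstream_max_pa, 3.5)
  expect_true(is.na(s1$upstream_max_pa))
  expect_equal(s1$plaque_mean_pa, 3.5)
  expect_error(wssSummary(list()), "at least one")
})
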