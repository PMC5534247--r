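test_that("lumen half-width honours the plaque taper and severity bases", {
  for (s in c(0, 0.3, 0.5, 0.7)) {
    ph <- StenosisPhantom(severity = s)
    # unobstructed outside the plaque extent, any severity
    expect_equal(lumenHalfwidth(c(-10, -4, 4, 10), ph), rep(2.5, 4))
    # closed-form throat radius on the area basis
    expect_equal(lumenHalfwidth(0, ph), 2.5 * sqrt(1 - s))
    expect_equal((throatRadius(ph) / ph@inletRadius)^2, 1 - s)
  }
  expect_equal(lumenHalfwidth(0, StenosisPhantom(severity = 0.7)),
               2.5 * sqrt(0.3), tolerance = 1e-12)
  expect_equal(
    lumenHalfwidth(0, StenosisPhantom(severity = 0.7,
                                      severityBasis = "diameter")),
    2.5 * 0.3)
  # severity 0 is the straight tube everywhere
  expect_equal(lumenHalfwidth(seq(-20, 20, by = 0.1), StenosisPhantom()),
               rep(2.5, 401))
})

test_that("half-width is continuous, C1 at the plaque edges, minimal at the throat", {
  ph <- StenosisPhantom(severity = 0.6)
  x <- seq(-6, 6, length.out = 4001)
  h <- lumenHalfwidth(x, ph)
  expect_true(all(is.finite(h)))
  expect_equal(which.min(h), which.min(abs(x)))
  # continuity: adjacent samples differ by O(dx)
  expect_lt(max(abs(diff(h))), 5 * (x[2] - x[1]))
  # C1 at the edges: slope tends to zero approaching +-plaqueLength/2
  edge <- abs(abs(x) - 4) < 0.02
  slopes <- abs(diff(h) / diff(x))
  expect_lt(max(slopes[edge[-1]]), 0.05)
})

test_that("lumen mask matches the wall curves and shrinks with severity", {
  x <- seq(-10, 10, length.out = 201)
  y <- seq(-3, 3, length.out = 121)
  m0 <- lumenMask(StenosisPhantom(severity = 0), x, y)
  # straight slab of constant height 5 mm
  heights <- colSums(t(m0)) * (y[2] - y[1])
  expect_true(all(abs(heights - 5) < 2 * (y[2] - y[1])))
  m3 <- lumenMask(StenosisPhantom(severity = 0.3), x, y)
  m7 <- lumenMask(StenosisPhantom(severity = 0.7), x, y)
  expect_lt(sum(m7), sum(m3))
  # throat-column interior height ~ 2 * halfwidth(0) within one grid step
  ph <- StenosisPhantom(severity = 0.7)
  m <- lumenMask(ph, x, y)
  ht <- sum(m[which.min(abs(x)), ]) * (y[2] - y[1])
  expect_lt(abs(ht - 2 * lumenHalfwidth(0, ph)), 2 * (y[2] - y[1]))
  # symmetric about the centreline for a symmetric bump
  expect_identical(m, m[, rev(seq_along(y))])
  # grid not covering the plaque is refused
  expect_error(lumenMask(ph, seq(1, 10, by = 0.5), y), "plaque")
})

test_that("wall curves carry unit inward normals, arc length and the throat", {
  ph0 <- StenosisPhantom(severity = 0)
  w0 <- wallCurves(ph0, 64L)
  expect_true(all(abs(w0@upper$nx) < 1e-12) && all(w0@upper$ny == -1))
  expect_true(all(abs(w0@lower$nx) < 1e-12) && all(w0@lower$ny == 1))

  ph <- StenosisPhantom(severity = 0.7)
  w <- wallCurves(ph, 401L)
  gap <- w@upper$y[w@throatIndex] - w@lower$y[w@throatIndex]
  expect_equal(gap, 2 * lumenHalfwidth(w@upper$x[w@throatIndex], ph),
               tolerance = 1e-9)
  expect_true(all(diff(w@upper$arclength) > 0))
  expect_true(all(abs(sqrt(w@upper$nx^2 + w@upper$ny^2) - 1) < 1e-8))
  # the curved plaque-side wall is longer than its straight-line extent
  inPlaque <- abs(w@upper$x) <= 4
  arc <- max(w@upper$arclength[inPlaque]) - min(w@upper$arclength[inPlaque])
  expect_gte(arc, 8)
  # points lie on +-halfwidth and walls never cross the centreline
  expect_equal(w@upper$y, lumenHalfwidth(w@upper$x, ph), tolerance = 1e-12)
  expect_true(all(w@upper$y > 0) && all(w@lower$y < 0))
  expect_error(wallCurves(ph, 8L), "nPoints")
})

test_that("phantom validity rejects out-of-range parameters", {
  expect_error(StenosisPhantom(severity = 1), "severity")
  expect_error(StenosisPhantom(severity = -0.1), "severity")
  expect_error(StenosisPhantom(inletRadius = 0), "inletRadius")
  expect_error(new("StenosisPhantom", inletRadius = 2.5, wallThickness = 1,
                   plaqueLength = 8, severity = 0.3, severityBasis = "volume",
                   bumpSide = "symmetric", domainLength = 40), "severityBasis")
})

test_that("one-sided plaques indent only the upper wall but keep the throat gap", {
  ph <- StenosisPhantom(severity = 0.5, bumpSide = "one_sided")
  w <- wallCurves(ph, 101L)
  expect_true(all(w@lower$y == -2.5))
  gap <- w@upper$y[w@throatIndex] - w@lower$y[w@throatIndex]
  expect_equal(gap, 2 * 2.5 * sqrt(0.5), tolerance = 1e-9)
})
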