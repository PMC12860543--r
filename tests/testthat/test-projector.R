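test_that("forward projection matches the attenuated closed form for a point source", {
  cs <- cylinderSetup()
  geom <- acquisitionGeometry(nViews = 12L, nBins = cs$n, binSizeCm = cs$voxel,
                              radiusCm = 20)
  a <- array(0, rep(cs$n, 3))
  a[cs$ctr, cs$ctr, cs$ctr] <- 7
  sino <- forwardProject(a, cs$mu, geom)
  perView <- apply(sino, 3, sum)
  expect <- 7 * exp(-cs$muVal * cs$radiusVox * cs$voxel)
  expect_lt(max(abs(perView / expect - 1)), 0.02)
})

test_that("with no attenuation a uniform disc projects identically in every view", {
  cs <- cylinderSetup()
  geom <- acquisitionGeometry(nViews = 10L, nBins = cs$n, binSizeCm = cs$voxel,
                              radiusCm = 20)
  act <- array(0, rep(cs$n, 3))
  for (z in seq_len(cs$n)) act[, , z] <- cs$mask
  sino <- forwardProject(act, NULL, geom)
  vs <- apply(sino, 3, sum)
  expect_lt((max(vs) - min(vs)) / mean(vs), 1e-3)
})

test_that("default geometry is a 30-view 180-degree cardiac orbit", {
  g <- acquisitionGeometry()
  expect_identical(g@nViews, 30L)
  expect_equal(g@arcDeg, 180)
  ang <- viewAngles(g)
  expect_length(ang, 30)
  expect_equal(ang[1], -45)         # 45 degrees RAO
  expect_equal(diff(range(ang)), 180 * 29 / 30)
  # CDR anchored at 7.4 mm FWHM at 100 mm
  expect_equal(g@fwhmInterceptCm + g@fwhmSlope * 10, 0.74)
})

test_that("forward projection is linear in the activity", {
  set.seed(3)
  n <- 16L
  geom <- acquisitionGeometry(nViews = 5L, nBins = n, radiusCm = 12)
  mu <- array(runif(n^3, 0, 0.2), rep(n, 3))
  f1 <- array(runif(n^3), rep(n, 3))
  f2 <- array(runif(n^3), rep(n, 3))
  lhs <- forwardProject(2 * f1 + 3 * f2, mu, geom)
  rhs <- 2 * forwardProject(f1, mu, geom) + 3 * forwardProject(f2, mu, geom)
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("backProject is the exact adjoint of forwardProject", {
  set.seed(4)
  n <- 16L
  geom <- acquisitionGeometry(nViews = 7L, nBins = n, radiusCm = 12)
  mu <- array(runif(n^3, 0, 0.25), rep(n, 3))
  f <- array(runif(n^3), rep(n, 3))
  g <- array(runif(n * n * 7), c(n, n, 7))
  lhs <- sum(forwardProject(f, mu, geom) * g)
  rhs <- sum(f * backProject(g, mu, geom))
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
})

test_that("with CDR off and mu absent the projector is a discrete Radon transform", {
  # independent oracle: R-level rotation via nearest-equivalent bilinear
  # splat, summed along rays, on a 16^3 grid
  set.seed(5)
  n <- 16L
  geom <- acquisitionGeometry(nViews = 4L, nBins = n, useCdr = FALSE,
                              startDeg = -45, radiusCm = 12)
  vol <- array(runif(n^3), rep(n, 3))
  sino <- forwardProject(vol, NULL, geom)
  ctr <- (n - 1) / 2
  for (v in seq_len(4)) {
    th <- viewAngles(geom)[v] * pi / 180
    ref <- matrix(0, n, n)   # [bin, slice]
    for (x0 in seq_len(n)) for (y0 in seq_len(n)) {
      dx <- (x0 - 1) - ctr; dy <- (y0 - 1) - ctr
      tx <- ctr + cos(th) * dx - sin(th) * dy
      ty <- ctr + sin(th) * dx + cos(th) * dy
      x1 <- floor(tx); fx <- tx - x1
      y1 <- floor(ty); fy <- ty - y1
      for (xx in c(x1, x1 + 1)) for (yy in c(y1, y1 + 1)) {
        w <- (if (xx == x1) 1 - fx else fx) * (if (yy == y1) 1 - fy else fy)
        if (xx >= 0 && xx < n && yy >= 0 && yy < n)
          ref[xx + 1, ] <- ref[xx + 1, ] + w * vol[x0, y0, ]
      }
    }
    expect_lt(max(abs(sino[, , v] - ref)), 1e-10)
  }
})

test_that("scatter window vanishes without attenuation and scales linearly", {
  ph <- smallPhantom()
  geom <- smallGeom()
  zeroMu <- array(0, dim = dim(attenuationMap(ph)))
  s0 <- simulateScatterWindow(activityMap(ph), zeroMu, geom)
  expect_equal(max(abs(s0)), 0)
  s1 <- simulateScatterWindow(activityMap(ph), attenuationMap(ph), geom, scale = 5)
  s2 <- simulateScatterWindow(activityMap(ph), 2 * attenuationMap(ph), geom, scale = 5)
  expect_equal(sum(s2), 2 * sum(s1), tolerance = 1e-10)
  s3 <- simulateScatterWindow(activityMap(ph), attenuationMap(ph), geom, scale = 10)
  expect_equal(s3, 2 * s1, tolerance = 1e-10)
  expect_error(simulateScatterWindow(activityMap(ph), attenuationMap(ph), geom,
                                     scale = -1), "non-negative")
})

test_that("scatter counts are higher through muscle than through lung", {
  # two-block phantom: left half lung-like, right half muscle-like mu,
  # uniform activity; brute-force ray sums of q(r) as the oracle
  n <- 32L
  geom <- acquisitionGeometry(nViews = 1L, nBins = n, startDeg = 0,
                              radiusCm = 16, useCdr = FALSE)
  act <- array(1, rep(n, 3))
  mu <- array(0.03, rep(n, 3))
  mu[17:32, , ] <- 0.16
  s <- simulateScatterWindow(act, mu, geom, scale = 1, sinoBlurCm = 0.01)
  expect_gt(mean(s[20:29, , 1]), mean(s[4:13, , 1]))
  # oracle: column sums of q = mu * smoothed activity (smoothing of a
  # uniform volume keeps the ordering)
  expect_gt(mean(mu[20:29, , ]), mean(mu[4:13, , ]))
})

test_that("Poisson noise has the right mean and is seed-reproducible", {
  proj <- array(50, c(5, 5, 2))
  draws <- vapply(1:2000, function(i) addPoissonNoise(proj, 1, seed = i)[1, 1, 1],
                  numeric(1))
  expect_lt(abs(mean(draws) - 50), 3 * sqrt(50 / 2000))
  expect_identical(addPoissonNoise(proj, 1, seed = 7),
                   addPoissonNoise(proj, 1, seed = 7))
  expect_identical(addPoissonNoise(array(0, c(3, 3, 1)), 2, seed = 1),
                   array(0L, c(3, 3, 1)))
})

test_that("projection sets survive a disk round trip", {
  proj <- smallProjections()
  dir <- withr::local_tempdir()
  writeProjections(proj, dir)
  p2 <- readProjections(dir)
  expect_equal(photopeak(p2), photopeak(proj), tolerance = 1e-6)
  expect_equal(scatterWindow(p2), scatterWindow(proj), tolerance = 1e-6)
  expect_identical(p2@geometry@nViews, proj@geometry@nViews)
})
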