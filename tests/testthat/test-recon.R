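test_that("one MLEM iteration equals the hand-computed multiplicative update", {
  set.seed(1)
  n <- 8L
  geom <- acquisitionGeometry(nViews = 4L, nBins = n, radiusCm = 8,
                              useCdr = FALSE)
  act <- array(runif(n^3), rep(n, 3))
  g <- forwardProject(act, NULL, geom)
  f0 <- array(1, rep(n, 3))
  ratio <- g / pmax(forwardProject(f0, NULL, geom), 1e-12)
  fHand <- f0 * backProject(ratio, NULL, geom) /
    pmax(backProject(array(1, dim(g)), NULL, geom), 1e-12)
  rec <- osem(g, reconConfig(1L, 1L), geom)
  expect_equal(reconVolume(rec), fHand, tolerance = 1e-12)
})

test_that("OSEM with one subset equals MLEM over several iterations", {
  set.seed(2)
  n <- 8L
  geom <- acquisitionGeometry(nViews = 4L, nBins = n, radiusCm = 8)
  g <- forwardProject(array(runif(n^3), rep(n, 3)), NULL, geom)
  r1 <- osem(g, reconConfig(3L, 1L), geom)
  # manual MLEM
  f <- array(1, rep(n, 3))
  sens <- backProject(array(1, dim(g)), NULL, geom)
  for (i in 1:3) {
    fp <- forwardProject(f, NULL, geom)
    f <- f * backProject(g / pmax(fp, 1e-12), NULL, geom) / pmax(sens, 1e-12)
  }
  expect_equal(reconVolume(r1), f, tolerance = 1e-12)
})

test_that("noise-free matched-model reconstruction recovers the activity", {
  n <- 16L
  geom <- acquisitionGeometry(nViews = 30L, nBins = n, radiusCm = 12,
                              useCdr = FALSE)
  idx <- seq_len(n); ctr <- (n + 1) / 2
  r2 <- outer(idx - ctr, rep(1, n))^2 + outer(rep(1, n), idx - ctr)^2
  act <- array(0, rep(n, 3)); mu <- array(0, rep(n, 3))
  for (z in idx) {
    act[, , z] <- exp(-r2 / 18) * exp(-(z - ctr)^2 / 18)
    mu[, , z] <- 0.15 * (r2 <= 36)
  }
  g <- forwardProject(act, mu, geom)
  rec <- osem(g, reconConfig(50L, 1L, mu), geom)
  nrmse <- sqrt(mean((reconVolume(rec) - act)^2)) / sqrt(mean(act^2))
  expect_lt(nrmse, 0.05)
})

test_that("OSEM keeps non-negativity and zero data give a zero image", {
  set.seed(3)
  n <- 8L
  geom <- acquisitionGeometry(nViews = 6L, nBins = n, radiusCm = 8)
  g <- forwardProject(array(runif(n^3), rep(n, 3)), NULL, geom)
  rec <- osem(g, reconConfig(2L, 3L), geom)
  expect_true(all(reconVolume(rec) >= 0))
  z <- osem(array(0, dim(g)), reconConfig(1L, 1L), geom)
  expect_equal(max(reconVolume(z)), 0)
  expect_error(osem(g, reconConfig(1L, 4L), geom), "divisible")
  expect_error(osem(-g, reconConfig(1L, 1L), geom), "negative")
})

test_that("AC reconstruction restores deep activity that NAC suppresses", {
  cs <- cylinderSetup(n = 33L, muVal = 0.15, voxel = 0.68)
  geom <- acquisitionGeometry(nViews = 30L, nBins = cs$n, binSizeCm = 0.68,
                              radiusCm = 20)
  act <- array(0, rep(cs$n, 3))
  for (z in seq_len(cs$n)) act[, , z] <- cs$mask
  g <- forwardProject(act, cs$mu, geom)
  core <- array(FALSE, rep(cs$n, 3))
  core[15:19, 15:19, 15:19] <- TRUE
  edge <- array(FALSE, rep(cs$n, 3))
  edge[cs$ctr + c(-9, 9), 13:21, 13:21] <- TRUE
  ac <- reconVolume(osem(g, reconConfig(8L, 6L, cs$mu), geom))
  nac <- reconVolume(osem(g, reconConfig(8L, 6L), geom))
  # NAC shows the classic rim-high/centre-low artifact; AC flattens it
  expect_gt(mean(ac[core]) / mean(ac[edge]),
            mean(nac[core]) / mean(nac[edge]))
})

test_that("Butterworth filter has unit DC gain and half-power at the cutoff", {
  img <- array(3.7, c(16, 16, 16))
  expect_equal(butterworthFilter(img), img, tolerance = 1e-10)
  # gain at an exactly representable frequency set equal to the cutoff
  n <- 32L; h <- 0.68; k <- 8L
  fc <- k / (n * h)
  wave <- array(0, rep(n, 3))
  for (z in seq_len(n))
    wave[, , z] <- matrix(rep(cos(2 * pi * k * (0:(n - 1)) / n), n), n)
  out <- butterworthFilter(wave, order = 5, cutoff = fc, voxelSizeCm = h)
  expect_equal(max(abs(out)) / max(abs(wave)), 1 / sqrt(2), tolerance = 1e-6)
  expect_warning(butterworthFilter(wave, cutoff = 1, voxelSizeCm = h),
                 "Nyquist")
  # defaults carry the clinical parameters
  expect_identical(formals(butterworthFilter)$order, 5)
  expect_identical(formals(butterworthFilter)$cutoff, 0.44)
})

test_that("cardiac ROI extraction clips to the LV maximum and maps to 8 bits", {
  ph <- smallPhantom()
  mask <- lvWallMask(ph)
  img <- array(1, dim = dim(mask))
  img[mask] <- 4
  ctrd <- lvGeometry(ph)$center
  roi <- extractCardiacROI(img, ctrd, mask)
  expect_identical(dim(roiPixels(roi)), c(32L, 32L))
  expect_equal(roi@xLV, 4)
  expect_true(all(roiPixels(roi) >= 0 & roiPixels(roi) <= 255))
  # image equal to xLV inside the mask maps to 255 there
  px <- roiPixels(roi)
  expect_equal(max(px), 255)
  # values above xLV clip to 255
  img2 <- img; img2[1, 1, ] <- 100
  roi2 <- extractCardiacROI(img2, c(2, 2, round(ctrd[3])), mask)
  expect_equal(roiPixels(roi2)[15, 15], 255)  # voxel (1,1) maps here
  # centroid near the edge pads with zeros instead of failing
  roi3 <- extractCardiacROI(img, c(2, 2, round(ctrd[3])), mask)
  expect_equal(roiPixels(roi3)[1, 1], 0)
  expect_error(extractCardiacROI(img, c(100, 2, 2), mask), "outside")
})
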