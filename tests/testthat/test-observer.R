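test_that("RSF channels follow the octave doubling rule from f0 = 0.046", {
  U <- makeRsfChannels()
  pb <- attr(U, "passbands")
  expect_equal(pb[, "start"], c(0.046, 0.092, 0.184, 0.368))
  expect_equal(pb[, "end"], c(0.092, 0.184, 0.368, 0.736))
  expect_identical(dim(U), c(1024L, 4L))
  # disjoint passbands: orthogonal columns
  G <- crossprod(U)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-10)
  # DC excluded: constant images give zero output
  expect_lt(max(abs(applyChannels(matrix(5, 32, 32), U))), 1e-12)
  expect_error(makeRsfChannels(f0 = 0.2), "Nyquist")
})

test_that("channel application is the linear map U'f", {
  U <- makeRsfChannels()
  img <- withr::with_seed(4, matrix(rnorm(1024), 32))
  v <- applyChannels(img, U)
  expect_length(v, 4L)
  # brute-force per-pixel dot products
  ref <- vapply(1:4, function(j) sum(U[, j] * as.numeric(img)), numeric(1))
  expect_lt(max(abs(v - ref)), 1e-10)
  expect_equal(applyChannels(3 * img, U), 3 * v, tolerance = 1e-12)
  expect_lt(max(abs(applyChannels(matrix(0, 32, 32), U))), 1e-15)
  expect_error(applyChannels(matrix(0, 16, 16), U), "match")
})

test_that("the Hotelling template solves Kv w = delta-vbar", {
  withr::with_seed(6, {
    nS <- 300
    Sig <- crossprod(matrix(rnorm(16), 4)) + 2 * diag(4)
    L <- chol(Sig)
    vs <- matrix(rnorm(nS * 4), nS) %*% L + matrix(c(1, 0, -0.5, 0.2), nS, 4,
                                                   byrow = TRUE)
    vn <- matrix(rnorm(nS * 4), nS) %*% L
    w <- choTemplate(vs, vn)
    ref <- solve((cov(vs) + cov(vn)) / 2, colMeans(vs) - colMeans(vn))
    expect_lt(max(abs(w - ref)), 1e-8)
    # identity covariance -> template equals the mean difference
    id <- diag(4)
    a <- matrix(rnorm(4000), 1000) ; b <- matrix(rnorm(4000), 1000)
    # construct exact-mean classes by centering
    a <- scale(a, scale = FALSE) ; b <- scale(b, scale = FALSE)
    a <- a + matrix(c(1, 2, 3, 4), 1000, 4, byrow = TRUE)
    Kv <- (cov(a) + cov(b)) / 2
    expect_equal(choTemplate(a, b), solve(Kv, c(1, 2, 3, 4)), tolerance = 1e-8)
    # equal class means -> zero template
    expect_lt(max(abs(choTemplate(a, a))), 1e-10)
  })
})

test_that("leave-one-out statistics use downdated templates consistently", {
  withr::with_seed(7, {
    n <- 2000
    vs <- matrix(rnorm(n * 4), n) + matrix(c(1.2, 0.5, 0, 0.3), n, 4, byrow = TRUE)
    vn <- matrix(rnorm(n * 4), n)
    f <- rbind(vs, vn); lab <- c(rep(1, n), rep(0, n))
    t <- looTestStatistics(f, lab)
    expect_length(t, 2 * n)
    # large-n: LOO AUC close to resubstitution AUC
    w <- choTemplate(vs, vn)
    tRes <- as.numeric(f %*% w)
    expect_lt(abs(rocAuc(t, lab)$auc - rocAuc(tRes, lab)$auc), 0.01)
    # duplicated samples receive identical statistics
    f2 <- rbind(vs[1:50, ], vs[1:50, ], vn[1:100, ])
    l2 <- c(rep(1, 100), rep(0, 100))
    t2 <- looTestStatistics(f2, l2)
    expect_equal(t2[1:50], t2[51:100], tolerance = 1e-10)
    expect_error(looTestStatistics(f[1:3, , drop = FALSE], c(1, 0, 0)),
                 "two samples")
  })
})

test_that("small-sample LOO statistic matches an explicit refit oracle", {
  withr::with_seed(8, {
    vs <- matrix(rnorm(40), 10) + 1
    vn <- matrix(rnorm(40), 10)
    f <- rbind(vs, vn); lab <- c(rep(1, 10), rep(0, 10))
    t <- looTestStatistics(f, lab)
    for (i in c(1, 7, 13, 20)) {
      keepS <- setdiff(which(lab == 1), i)
      keepN <- setdiff(which(lab == 0), i)
      ns <- length(keepS); nn <- length(keepN)
      Kv <- (cov(f[keepS, , drop = FALSE]) + cov(f[keepN, , drop = FALSE])) / 2
      dv <- colMeans(f[keepS, , drop = FALSE]) - colMeans(f[keepN, , drop = FALSE])
      expect_equal(t[i], sum(solve(Kv, dv) * f[i, ]), tolerance = 1e-8)
    }
  })
})

test_that("empirical AUC equals the exhaustive pairwise Mann-Whitney count", {
  withr::with_seed(9, {
    t1 <- c(rnorm(50, 1), rnorm(50))
    t1[3] <- t1[60]  # inject a tie
    lab <- c(rep(1, 50), rep(0, 50))
    r <- rocAuc(t1, lab)
    brute <- mean(outer(t1[lab == 1], t1[lab == 0],
                        function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(r$auc, brute, tolerance = 1e-12)
    expect_equal(max(r$tpr), 1); expect_equal(max(r$fpr), 1)
    # perfectly separated scores
    expect_equal(rocAuc(c(5, 6, 7, 1, 2), c(1, 1, 1, 0, 0))$auc, 1)
    # labels independent of scores: AUC near 1/2
    big <- rnorm(4000); bl <- rbinom(4000, 1, 0.5)
    se <- sqrt(1 / (12 * sum(bl) ) + 1 / (12 * sum(1 - bl)))
    expect_lt(abs(rocAuc(big, bl)$auc - 0.5), 3 * se)
    expect_error(rocAuc(t1, rep(1, 100)), "both classes")
  })
})

test_that("CHO performance approaches the known-Gaussian closed form", {
  withr::with_seed(10, {
    nS <- 5000
    Sig <- crossprod(matrix(rnorm(16), 4)) + 2 * diag(4)
    dm <- c(0.5, -0.3, 0.8, 0.2)
    L <- chol(Sig)
    vs <- matrix(rnorm(nS * 4), nS) %*% L + matrix(dm, nS, 4, byrow = TRUE)
    vn <- matrix(rnorm(nS * 4), nS) %*% L
    lab <- c(rep(1, nS), rep(0, nS))
    t <- looTestStatistics(rbind(vs, vn), lab)
    auc <- rocAuc(t, lab)$auc
    theory <- pnorm(sqrt(sum(dm * solve(Sig, dm)) / 2))
    expect_lt(abs(auc - theory), 0.015)  # ~3 Monte-Carlo sigma at n = 5000
    # AUC invariance under strictly increasing transforms
    expect_equal(rocAuc(exp(t / max(abs(t))), lab)$auc, auc, tolerance = 1e-12)
    # affine ROI rescaling leaves the AUC essentially unchanged (exact up
    # to floating-point perturbation of near-tied score pairs)
    t2 <- looTestStatistics(rbind(vs, vn) * 3.7 + 2, lab)
    expect_lt(abs(rocAuc(t2, lab)$auc - auc), 1e-4)
  })
})
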