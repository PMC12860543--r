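test_that("singleton clusters reduce the variance to the standard DeLong estimator", {
  withr::with_seed(1, {
    t <- c(rnorm(60, 1), rnorm(80))
    lab <- c(rep(1, 60), rep(0, 80))
    r <- aucCiCorrelated(t, lab)
    # direct placement-value DeLong computation
    V10 <- vapply(t[lab == 1], function(x)
      (sum(t[lab == 0] < x) + 0.5 * sum(t[lab == 0] == x)) / 80, numeric(1))
    V01 <- vapply(t[lab == 0], function(x)
      (sum(t[lab == 1] > x) + 0.5 * sum(t[lab == 1] == x)) / 60, numeric(1))
    expect_lt(abs(r$variance - (var(V10) / 60 + var(V01) / 80)), 1e-10)
    expect_equal(r$auc, rocAuc(t, lab)$auc, tolerance = 1e-12)
    expect_gte(r$variance, 0)
    expect_true(all(r$ci >= 0 & r$ci <= 1))
  })
})

test_that("the clustered AUC variance agrees with pROC DeLong for independent samples", {
  skip_if_not_installed("pROC")
  withr::with_seed(2, {
    t <- c(rnorm(50, 0.8), rnorm(50))
    lab <- c(rep(1, 50), rep(0, 50))
    r <- aucCiCorrelated(t, lab)
    v <- pROC::var(pROC::roc(lab, t, quiet = TRUE), method = "delong")
    expect_equal(r$variance, v, tolerance = 1e-10)
  })
})

test_that("confidence intervals achieve near-nominal coverage at true AUC 0.8", {
  trueAuc <- 0.8
  mu <- sqrt(2) * qnorm(trueAuc)
  # independent samples (singleton clusters)
  withr::with_seed(3, {
    hits <- vapply(1:400, function(r) {
      t <- c(rnorm(50, mu), rnorm(50))
      lab <- c(rep(1, 50), rep(0, 50))
      ci <- aucCiCorrelated(t, lab)$ci
      ci[1] <= trueAuc && trueAuc <= ci[2]
    }, logical(1))
    expect_gte(mean(hits), 0.92)
    expect_lte(mean(hits), 0.98)
  })
  # correlated within-subject replicates, enough clusters for the CLT
  withr::with_seed(13, {
    hits <- vapply(1:300, function(r) {
      nSub <- 60
      sP <- rep(rnorm(nSub, mu, 0.8), each = 3) + rnorm(3 * nSub, 0, 0.6)
      sN <- rep(rnorm(nSub, 0, 0.8), each = 3) + rnorm(3 * nSub, 0, 0.6)
      # the AUC of this mixture is not exactly pnorm(mu/sqrt(2)); compare
      # against the design value of the latent subject effect instead
      t <- c(sP, sN); lab <- c(rep(1, 3 * nSub), rep(0, 3 * nSub))
      cl <- c(rep(sprintf("P%d", 1:nSub), each = 3),
              rep(sprintf("N%d", 1:nSub), each = 3))
      truth <- pnorm(mu / sqrt(2 * (0.8^2 + 0.6^2)))
      ci <- aucCiCorrelated(t, lab, cl)$ci
      ci[1] <= truth && truth <= ci[2]
    }, logical(1))
    expect_gte(mean(hits), 0.92)
    expect_lte(mean(hits), 0.98)
  })
})

test_that("non-inferiority follows the 5%-of-reference margin rule", {
  # margin arithmetic
  r <- noninferiorityTest(0.88, 0.90, varDiff = 1e-6)
  expect_equal(r$margin, 0.045)
  # equal AUCs with vanishing variance: non-inferior (indeed superior-tied)
  r2 <- noninferiorityTest(0.9, 0.9, varDiff = 1e-12)
  expect_true(r2$decision %in% c("non-inferior", "superior"))
  # deficit exactly at the margin with vanishing variance: NOT non-inferior
  r3 <- noninferiorityTest(0.9 - 0.045, 0.9, varDiff = 0)
  expect_identical(r3$decision, "inconclusive")
  # clearly better method with tight CI: superior
  r4 <- noninferiorityTest(0.95, 0.85, varDiff = 1e-6)
  expect_identical(r4$decision, "superior")
  expect_error(noninferiorityTest(0.9, 0.9, 0.01, marginFrac = 0), "positive")
  # Bonferroni adjustment is min(1, m p) and monotone
  s1 <- superiorityTest(0.05, 0.001, m = 2L)
  expect_equal(s1$pAdjusted, min(1, 2 * s1$p))
  s2 <- superiorityTest(0.01, 0.001, m = 2L)
  expect_gte(s2$pAdjusted, s1$pAdjusted)
})

test_that("paired AUC difference accounts for between-method correlation", {
  withr::with_seed(4, {
    n <- 80
    base <- c(rnorm(n, 1), rnorm(n))
    lab <- c(rep(1, n), rep(0, n))
    t1 <- base + rnorm(2 * n, 0, 0.3)
    t2 <- base + rnorm(2 * n, 0, 0.3)   # strongly correlated with t1
    d <- pairedAucDiff(t1, t2, lab)
    v1 <- aucCiCorrelated(t1, lab)$variance
    v2 <- aucCiCorrelated(t2, lab)$variance
    expect_lt(d$variance, v1 + v2)  # positive correlation shrinks the variance
    expect_equal(d$delta, d$auc1 - d$auc2, tolerance = 1e-12)
  })
})

test_that("RMSE and SSIM behave on closed-form cases", {
  withr::with_seed(5, {
    x <- array(runif(16^3), rep(16, 3))
    m <- fidelityMetrics(x, x)
    expect_equal(m$rmse, 0)
    expect_equal(m$ssim, 1)
    m2 <- fidelityMetrics(x + 0.3, x)
    expect_equal(m2$rmse, 0.3, tolerance = 1e-12)
    expect_lt(m2$ssim, 1)
    expect_error(fidelityMetrics(x, x[1:8, 1:8, 1:8]), "mismatch")
    # degraded image scores worse on both metrics
    noisy <- x + array(rnorm(16^3, 0, 0.2), rep(16, 3))
    m3 <- fidelityMetrics(noisy, x)
    expect_gt(m3$rmse, 0.15)
    expect_lt(m3$ssim, m$ssim)
  })
})

test_that("SSIM matches the scikit-image reference implementation", {
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  withr::with_seed(6, {
    x <- matrix(runif(48 * 48), 48)
    y <- x * 0.8 + matrix(rnorm(48 * 48, 0, 0.1), 48)
  })
  L <- max(x, y) - min(x, y)
  got <- fidelityMetrics(x, y)$ssim
  d <- withr::local_tempdir()
  write.table(x, file.path(d, "x.csv"), sep = ",", row.names = FALSE,
              col.names = FALSE)
  write.table(y, file.path(d, "y.csv"), sep = ",", row.names = FALSE,
              col.names = FALSE)
  script <- sprintf(
    "import numpy as np
from skimage.metrics import structural_similarity as ssim
x = np.loadtxt('%s/x.csv', delimiter=',')
y = np.loadtxt('%s/y.csv', delimiter=',')
print(float(ssim(x, y, win_size=7, data_range=%.17g, gaussian_weights=False)))",
    d, d, L)
  ref <- as.numeric(system2(py, "-", input = script, stdout = TRUE))
  skip_if(is.na(ref), "reference SSIM unavailable")
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("cluster bootstrap CIs are seeded, degenerate-safe and well calibrated", {
  # all-zero differences
  r0 <- bootstrapDiff(rep(0, 30), B = 200, seed = 1)
  expect_equal(r0$ci, c(0, 0))
  expect_equal(r0$p, 1)
  # bit-identical across runs with one seed
  withr::with_seed(7, d <- rnorm(40, 0.2))
  r1 <- bootstrapDiff(d, B = 500, seed = 9)
  r2 <- bootstrapDiff(d, B = 500, seed = 9)
  expect_identical(r1$ci, r2$ci)
  expect_warning(bootstrapDiff(d, B = 50, seed = 1), "replicates")
  # coverage of the 95% CI in a Gaussian simulation
  withr::with_seed(8, {
    hits <- vapply(1:300, function(i) {
      dd <- rnorm(30, 0.5)
      ci <- bootstrapDiff(dd, B = 400, seed = i)$ci
      ci[1] <= 0.5 && 0.5 <= ci[2]
    }, logical(1))
    expect_gt(mean(hits), 0.90)
    expect_lte(mean(hits), 0.985)
  })
})
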