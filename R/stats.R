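# AUC variance for clustered samples, non-inferiority testing, fidelity
# metrics, and cluster bootstrap.
#
# The correlated-AUC variance is a cluster-aggregated DeLong estimator:
# per-sample placement values are averaged within each cluster (a cluster =
# one subject, whose 27 defect variants share statistical noise) and the
# empirical variance is taken across cluster means.  With all clusters of
# size one this reduces exactly to the standard DeLong variance.

# placement values: for each present sample, the fraction of absent samples
# it outscores (ties 0.5), and vice versa
.placements <- function(t, labels) {
  labels <- as.integer(labels)
  ts <- t[labels == 1L]; tn <- t[labels == 0L]
  n1 <- length(ts); n0 <- length(tn)
  V10 <- vapply(ts, function(x) (sum(tn < x) + 0.5 * sum(tn == x)) / n0,
                numeric(1))
  V01 <- vapply(tn, function(x) (sum(ts > x) + 0.5 * sum(ts == x)) / n1,
                numeric(1))
  list(V10 = V10, V01 = V01, n1 = n1, n0 = n0)
}

.clusterMeans <- function(v, cl) as.numeric(tapply(v, cl, mean))

#' AUC with a cluster-aware variance and confidence interval
#'
#' Nonparametric AUC (Mann-Whitney) with a DeLong-type variance in which
#' placement values are aggregated to cluster level before the empirical
#' variance is taken, accounting for the correlation among samples from the
#' same subject.  The CI is a normal approximation truncated to [0, 1].
#'
#' @param t test statistics.
#' @param labels 0/1 vector.
#' @param clusterIds cluster (subject) identifiers; NULL treats every
#'   sample as its own cluster.
#' @param conf confidence level.
#' @return list: `auc`, `variance`, `ci`, `nPresent`, `nAbsent`, `method`.
#' @export
aucCiCorrelated <- function(t, labels, clusterIds = NULL, conf = 0.95) {
  labels <- as.integer(labels)
  if (is.null(clusterIds)) clusterIds <- seq_along(t)
  pl <- .placements(t, labels)
  cls <- .clusterMeans(pl$V10, clusterIds[labels == 1L])
  cln <- .clusterMeans(pl$V01, clusterIds[labels == 0L])
  if (length(cls) < 2L || length(cln) < 2L)
    stop("need at least two clusters per class")
  auc <- mean(pl$V10)
  v <- var(cls) / length(cls) + var(cln) / length(cln)
  z <- qnorm(1 - (1 - conf) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * sqrt(v), 0), 1)
  list(auc = auc, variance = v, ci = ci, nPresent = pl$n1, nAbsent = pl$n0,
       method = "cluster-aggregated DeLong")
}

#' Paired AUC difference between two methods on the same samples
#'
#' Joint placement-value covariance at cluster level: the variance of the
#' difference accounts for both the within-subject correlation and the
#' correlation between the two methods.
#'
#' @param t1,t2 test statistics of the two methods on identical samples.
#' @param labels 0/1 vector.
#' @param clusterIds cluster identifiers (NULL = singleton clusters).
#' @param conf confidence level.
#' @return list: `delta` (auc1 - auc2), `variance`, `ci`, per-method AUCs.
#' @export
pairedAucDiff <- function(t1, t2, labels, clusterIds = NULL, conf = 0.95) {
  labels <- as.integer(labels)
  if (is.null(clusterIds)) clusterIds <- seq_along(t1)
  p1 <- .placements(t1, labels); p2 <- .placements(t2, labels)
  d10 <- .clusterMeans(p1$V10 - p2$V10, clusterIds[labels == 1L])
  d01 <- .clusterMeans(p1$V01 - p2$V01, clusterIds[labels == 0L])
  delta <- mean(p1$V10) - mean(p2$V10)
  v <- var(d10) / length(d10) + var(d01) / length(d01)
  z <- qnorm(1 - (1 - conf) / 2)
  list(delta = delta, variance = v, ci = delta + c(-1, 1) * z * sqrt(v),
       auc1 = mean(p1$V10), auc2 = mean(p2$V10))
}

#' Non-inferiority decision for an AUC comparison
#'
#' The margin is `marginFrac` of the reference AUC.  The test method is
#' non-inferior when the lower bound of the `1 - alpha` CI of
#' `aucTest - aucRef` lies strictly above `-margin`; it is additionally
#' superior when the lower bound exceeds 0.
#'
#' @param aucTest,aucRef the two AUCs.
#' @param varDiff variance of their difference (paired).
#' @param marginFrac margin as a fraction of `aucRef` (default 0.05).
#' @param alpha significance level.
#' @param m number of comparisons for the Bonferroni-adjusted p-value.
#' @return list: `margin`, `delta`, `ciLower`, `decision`, `p`,
#'   `pAdjusted`.
#' @export
noninferiorityTest <- function(aucTest, aucRef, varDiff, marginFrac = 0.05,
                               alpha = 0.05, m = 1L) {
  if (marginFrac <= 0) stop("marginFrac must be positive")
  margin <- marginFrac * aucRef
  delta <- aucTest - aucRef
  se <- sqrt(varDiff)
  z <- qnorm(1 - alpha / 2)
  lo <- delta - z * se
  decision <- if (lo > -margin) {
    if (lo > 0) "superior" else "non-inferior"
  } else "inconclusive"
  # one-sided non-inferiority p-value: H0 delta <= -margin
  p <- if (se > 0) pnorm((delta + margin) / se, lower.tail = FALSE)
       else as.numeric(delta <= -margin)
  list(margin = margin, delta = delta, ciLower = lo, decision = decision,
       p = p, pAdjusted = min(1, m * p))
}

#' Two-sided superiority z-test for an AUC difference
#'
#' @param delta AUC difference.
#' @param varDiff its variance.
#' @param m Bonferroni comparison count.
#' @return list with `z`, `p` and `pAdjusted = min(1, m p)`.
#' @export
superiorityTest <- function(delta, varDiff, m = 1L) {
  z <- if (varDiff > 0) delta / sqrt(varDiff) else sign(delta) * Inf
  p <- 2 * pnorm(-abs(z))
  list(z = z, p = p, pAdjusted = min(1, m * p))
}

# moving-window box means over the valid (fully inside) region, any dims;
# one cumsum pass per axis, rotating the leading axis to the back each time
.boxMeansValid <- function(x, win) {
  nd <- length(dim(x))
  for (ax in seq_len(nd)) {
    d <- dim(x)
    m <- matrix(x, nrow = d[1])
    cs <- rbind(0, apply(m, 2, cumsum))
    v <- (cs[(win + 1):(d[1] + 1), , drop = FALSE] -
          cs[1:(d[1] - win + 1), , drop = FALSE]) / win
    x <- aperm(array(v, dim = c(d[1] - win + 1L, d[-1])),
               c(seq_len(nd)[-1], 1L))
  }
  x
}

#' Root-mean-square error and structural similarity
#'
#' RMSE is the plain root mean squared difference (within `mask` when
#' given).  SSIM follows the standard formulation: uniform local windows
#' (side `win`, valid region only), constants `C1 = (K1 L)^2`,
#' `C2 = (K2 L)^2` with `L` the joint dynamic range, and the mean SSIM map
#' reported.
#'
#' @param image,reference arrays of identical shape (2-D or 3-D).
#' @param mask optional logical array for the RMSE.
#' @param win SSIM window side length.
#' @param K1,K2 SSIM stability constants.
#' @return list: `rmse`, `ssim`.
#' @export
fidelityMetrics <- function(image, reference, mask = NULL, win = 7L,
                            K1 = 0.01, K2 = 0.03) {
  if (is(image, "ReconImage")) image <- image@volume
  if (is(reference, "ReconImage")) reference <- reference@volume
  if (!identical(dim(image), dim(reference))) stop("shape mismatch")
  diffs <- (image - reference)^2
  rmse <- sqrt(if (is.null(mask)) mean(diffs) else mean(diffs[mask]))
  L <- max(image, reference) - min(image, reference)
  if (L == 0) return(list(rmse = rmse, ssim = 1))
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  ux <- .boxMeansValid(image, win)
  uy <- .boxMeansValid(reference, win)
  uxx <- .boxMeansValid(image^2, win)
  uyy <- .boxMeansValid(reference^2, win)
  uxy <- .boxMeansValid(image * reference, win)
  nw <- prod(rep(win, length(dim(image))))
  unb <- nw / (nw - 1)  # unbiased local (co)variances
  vx <- unb * (uxx - ux^2); vy <- unb * (uyy - uy^2)
  cxy <- unb * (uxy - ux * uy)
  s <- ((2 * ux * uy + C1) * (2 * cxy + C2)) /
       ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  list(rmse = rmse, ssim = mean(s))
}

#' Cluster bootstrap for a paired metric difference
#'
#' Resamples clusters with replacement and reports the percentile CI of the
#' mean paired difference and a two-sided p-value by CI inversion.
#'
#' @param diffs per-sample paired differences.
#' @param clusterIds resampling units (NULL = per-sample).
#' @param B bootstrap replicates (a warning below 100).
#' @param conf confidence level.
#' @param seed RNG seed.
#' @return list: `mean`, `ci`, `p`, `B`.
#' @export
bootstrapDiff <- function(diffs, clusterIds = NULL, B = 2000L, conf = 0.95,
                          seed = 1L) {
  if (B < 100L) warning("B < 100 bootstrap replicates")
  if (is.null(clusterIds)) clusterIds <- seq_along(diffs)
  groups <- split(diffs, clusterIds)
  nc <- length(groups)
  boot <- withSeed(seed, vapply(seq_len(B), function(b) {
    mean(unlist(groups[sample.int(nc, nc, replace = TRUE)]))
  }, numeric(1)))
  a <- (1 - conf) / 2
  ci <- as.numeric(quantile(boot, c(a, 1 - a), type = 7))
  pLo <- mean(boot < 0) + 0.5 * mean(boot == 0)
  pHi <- mean(boot > 0) + 0.5 * mean(boot == 0)
  list(mean = mean(diffs), ci = ci, p = min(1, 2 * min(pLo, pHi)), B = B)
}
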