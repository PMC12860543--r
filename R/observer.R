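# Channelized Hotelling observer with rotationally symmetric frequency
# channels, leave-one-out template training and empirical ROC analysis.

#' Rotationally symmetric frequency channels
#'
#' Four octave-spaced annular band-pass channels on the 32 x 32 DFT grid:
#' channel j is the indicator of radial frequency in
#' `[f0 * 2^(j-1), f0 * 2^j)` cycles/cm (half-open, bin-centre frequencies),
#' returned as real spatial-domain templates.  With the default
#' `f0 = 0.046` the passband edges are 0.046/0.092/0.184/0.368/0.736
#' cycles/cm; bands are truncated at the frequencies representable on the
#' grid, and a channel whose start frequency reaches Nyquist is rejected.
#'
#' @param grid ROI side length in pixels.
#' @param pixelCm pixel size, cm.
#' @param nChannels number of channels.
#' @param f0 start frequency and width of the first channel, cycles/cm.
#' @return `grid^2 x nChannels` matrix of spatial templates with
#'   `passbands` attribute (edges in cycles/cm).
#' @export
#' @examples
#' U <- makeRsfChannels()
#' attr(U, "passbands")
makeRsfChannels <- function(grid = 32L, pixelCm = 0.68, nChannels = 4L,
                            f0 = 0.046) {
  nyquist <- 1 / (2 * pixelCm)
  edges <- f0 * 2^(0:nChannels)
  if (edges[nChannels] >= nyquist)
    stop("channel start frequency at or above Nyquist")
  k <- c(0:floor(grid / 2), -(ceiling(grid / 2) - 1):-1)[seq_len(grid)]
  f <- k / (grid * pixelCm)
  fr <- sqrt(outer(f^2, f^2, "+"))
  U <- matrix(0, grid * grid, nChannels)
  for (j in seq_len(nChannels)) {
    mask <- fr >= edges[j] & fr < edges[j + 1]
    # radial masks are symmetric under frequency negation -> real template
    U[, j] <- as.numeric(Re(fft(mask + 0i, inverse = TRUE))) / (grid * grid)
  }
  attr(U, "passbands") <- cbind(start = edges[-(nChannels + 1)],
                                end = edges[-1])
  U
}

#' Apply channels to a cardiac ROI
#'
#' `v = U' f`: linear projection of the flattened ROI onto the channel
#' templates.
#'
#' @param roi a [CardiacROI-class] or a matrix matching the channel grid.
#' @param U channel matrix from [makeRsfChannels()].
#' @return feature vector of length `ncol(U)`.
#' @export
applyChannels <- function(roi, U) {
  if (is(roi, "CardiacROI")) roi <- roi@pixels
  if (length(roi) != nrow(U)) stop("ROI size does not match the channels")
  as.numeric(crossprod(U, as.numeric(roi)))
}

#' Hotelling template from channel features
#'
#' `w = Kv^{-1} (vbar_s - vbar_n)` with `Kv` the pooled (equal-weight
#' average of the two class) covariance of the training features.  A
#' near-singular `Kv` receives a ridge of `1e-8 * trace/ncol` with a
#' warning.
#'
#' @param signalFeatures,noiseFeatures feature matrices [n x C] for
#'   defect-present and defect-absent training samples.
#' @param trainingIndices optional row indices (applied to both classes'
#'   own matrices) selecting the training subset.
#' @return template vector w.
#' @export
choTemplate <- function(signalFeatures, noiseFeatures, trainingIndices = NULL) {
  if (!is.null(trainingIndices)) {
    signalFeatures <- signalFeatures[trainingIndices$signal, , drop = FALSE]
    noiseFeatures <- noiseFeatures[trainingIndices$noise, , drop = FALSE]
  }
  dv <- colMeans(signalFeatures) - colMeans(noiseFeatures)
  Kv <- (stats::cov(signalFeatures) + stats::cov(noiseFeatures)) / 2
  sol <- tryCatch(solve(Kv, dv), error = function(e) NULL)
  if (is.null(sol) || rcond(Kv) < 1e-12) {
    warning("near-singular channel covariance; adding ridge")
    Kv <- Kv + diag(1e-8 * sum(diag(Kv)) / ncol(Kv), ncol(Kv))
    sol <- solve(Kv, dv)
  }
  as.numeric(sol)
}

#' Leave-one-out Hotelling test statistics
#'
#' For every sample the template is learned from all other samples (the
#' held-out feature excluded from the class means and covariance via
#' rank-one downdates) and applied as `t = w' v`.  With
#' `clusterExclude = TRUE` all samples sharing the held-out sample's
#' cluster id are excluded from template training instead.
#'
#' @param features matrix [n x C] of channel features.
#' @param labels 0/1 vector (1 = defect present).
#' @param clusterIds optional cluster identifiers.
#' @param clusterExclude exclude the whole cluster rather than the sample.
#' @return numeric vector of test statistics.
#' @export
looTestStatistics <- function(features, labels, clusterIds = NULL,
                              clusterExclude = FALSE) {
  labels <- as.integer(labels)
  n <- nrow(features)
  if (sum(labels == 1L) < 2L || sum(labels == 0L) < 2L)
    stop("need at least two samples per class")
  if (clusterExclude && is.null(clusterIds))
    stop("clusterExclude requires clusterIds")
  C <- ncol(features)
  t <- numeric(n)
  if (!clusterExclude) {
    cls <- list(s = features[labels == 1L, , drop = FALSE],
                n = features[labels == 0L, , drop = FALSE])
    S1 <- lapply(cls, colSums)
    S2 <- lapply(cls, crossprod)
    ns <- vapply(cls, nrow, integer(1))
    for (i in seq_len(n)) {
      v <- features[i, ]
      cl <- if (labels[i] == 1L) "s" else "n"
      other <- if (labels[i] == 1L) "n" else "s"
      m1 <- (S1[[cl]] - v) / (ns[[cl]] - 1L)
      sc1 <- S2[[cl]] - tcrossprod(v) - (ns[[cl]] - 1L) * tcrossprod(m1)
      m2 <- S1[[other]] / ns[[other]]
      sc2 <- S2[[other]] - ns[[other]] * tcrossprod(m2)
      Kv <- (sc1 / (ns[[cl]] - 2L) + sc2 / (ns[[other]] - 1L)) / 2
      dv <- if (labels[i] == 1L) m1 - m2 else m2 - m1
      w <- tryCatch(solve(Kv, dv), error = function(e)
        solve(Kv + diag(1e-8 * sum(diag(Kv)) / C, C), dv))
      t[i] <- sum(w * v)
    }
  } else {
    for (i in seq_len(n)) {
      keep <- clusterIds != clusterIds[i]
      if (!any(keep & labels == 1L) || !any(keep & labels == 0L))
        stop("a class is absent from a training fold")
      w <- choTemplate(features[keep & labels == 1L, , drop = FALSE],
                       features[keep & labels == 0L, , drop = FALSE])
      t[i] <- sum(w * features[i, ])
    }
  }
  t
}

#' Empirical ROC curve and AUC
#'
#' AUC is the Mann-Whitney statistic (ties credited 0.5); the curve is the
#' empirical TPR/FPR path over all thresholds.
#'
#' @param t test statistics.
#' @param labels 0/1 vector (1 = defect present).
#' @return list: `auc`, `tpr`, `fpr`.
#' @export
rocAuc <- function(t, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(t)
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(t, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1L) / n1
  fp <- cumsum(labels[ord] == 0L) / n0
  list(auc = auc, tpr = c(0, tp), fpr = c(0, fp))
}
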