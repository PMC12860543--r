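# Multi-channel-input multi-decoder segmentation U-net (McEUN).
#
# Two input channels (scatter-window and photopeak-window reconstructions,
# each normalized to [0, 1]); a five-layer 3x3x3 encoder with two stride-2
# layers (spatial /4, filter count doubling at each downsampling); one
# decoder per attenuation region, each with three {transposed conv + conv}
# blocks (stride 2, 2, 1; filters halving as resolution doubles) and
# attention-gated skip connections from the encoder; the K single-channel
# decoder outputs are concatenated and passed through a voxelwise SoftMax.
# Leaky ReLU follows every convolution except the final logit layer.
#
# The whole network, including backpropagation and Adam, is implemented
# here on top of the im2col/col2im kernels; there is no external
# deep-learning runtime.

#' Build an untrained McEUN
#'
#' @param K number of attenuation regions (= number of decoders).
#' @param grid input grid side length; must be divisible by 4 (the encoder
#'   reduces 64 -> 16 via its two stride-2 layers).
#' @param baseFilters filters in the first encoder layer.
#' @param inChannels input channels (scatter recon, photopeak recon).
#' @param dropout dropout rate applied at the bottleneck during training.
#' @param initGain multiplier on the Glorot-normal weight scale (1 = exact
#'   Glorot; values around 1.4-1.8 compensate the variance loss of deep
#'   leaky-ReLU stacks when no batch normalization is present).
#' @param seed seed for weight initialization (biases are initialized to
#'   0.03).
#' @return a [McEUN-class].
#' @export
#' @examples
#' net <- buildMcEUN(K = 3, grid = 16, baseFilters = 2)
buildMcEUN <- function(K = 6L, grid = 64L, baseFilters = 8L, inChannels = 2L,
                       dropout = 0.1, initGain = 1, seed = 1L) {
  if (grid %% 4L != 0L) stop("grid must be divisible by 4")
  F1 <- as.integer(baseFilters)
  g <- initGain
  withSeed(seed, {
    params <- list(
      enc1 = .convLayer(inChannels, F1, 3L, 1L, 1L, g),
      enc2 = .convLayer(F1, 2L * F1, 3L, 2L, 1L, g),
      enc3 = .convLayer(2L * F1, 2L * F1, 3L, 1L, 1L, g),
      enc4 = .convLayer(2L * F1, 4L * F1, 3L, 2L, 1L, g),
      enc5 = .convLayer(4L * F1, 4L * F1, 3L, 1L, 1L, g),
      dec = lapply(seq_len(K), function(k) list(
        t1 = .tconvLayer(4L * F1, 2L * F1, 2L, 2L, 0L, g),
        a1 = .attLayer(2L * F1, 2L * F1, F1),
        c1 = .convLayer(4L * F1, 2L * F1, 3L, 1L, 1L, g),
        t2 = .tconvLayer(2L * F1, F1, 2L, 2L, 0L, g),
        a2 = .attLayer(F1, F1, max(1L, F1 %/% 2L)),
        c2 = .convLayer(2L * F1, F1, 3L, 1L, 1L, g),
        t3 = .tconvLayer(F1, F1, 3L, 1L, 1L, g),
        c3 = .convLayer(F1, 1L, 3L, 1L, 1L, g))))
    new("McEUN", params = params,
        config = list(K = as.integer(K), grid = as.integer(grid),
                      baseFilters = F1, inChannels = as.integer(inChannels),
                      dropout = dropout, initGain = initGain,
                      seed = as.integer(seed)),
        log = data.frame())
  })
}

#' Normalize a volume to [0, 1] by its maximum
#'
#' The normalization applied to both network input channels.  Idempotent;
#' an all-zero volume is returned unchanged with a warning.
#'
#' @param volume numeric array.
#' @return array with maximum 1 (or all zeros).
#' @export
normalizeInput <- function(volume) {
  m <- max(volume)
  if (m <= 0) {
    warning("all-zero volume; returning zeros")
    return(volume)
  }
  volume / m
}

# forward pass; x is [Nvox x inChannels]; returns probabilities + caches
.mceunForward <- function(params, K, x, dims, training = FALSE,
                          dropout = 0) {
  lr <- function(pre) .lrelu(pre)
  e1p <- .convFwd(x, dims, params$enc1); e1 <- lr(e1p$fm)
  e2p <- .convFwd(e1, e1p$dims, params$enc2); e2 <- lr(e2p$fm)
  e3p <- .convFwd(e2, e2p$dims, params$enc3); e3 <- lr(e3p$fm)
  e4p <- .convFwd(e3, e3p$dims, params$enc4); e4 <- lr(e4p$fm)
  e5p <- .convFwd(e4, e4p$dims, params$enc5); e5 <- lr(e5p$fm)
  drop <- NULL
  if (training && dropout > 0) {
    drop <- matrix(rbinom(length(e5), 1L, 1 - dropout), nrow(e5)) / (1 - dropout)
    e5 <- e5 * drop
  }
  dimsG <- dims; dims2 <- e2p$dims; dims4 <- e4p$dims
  N <- nrow(x)
  Z <- matrix(0, N, K)
  dcache <- vector("list", K)
  for (k in seq_len(K)) {
    pk <- params$dec[[k]]
    u1p <- .tconvFwd(e5, dims4, pk$t1); u1 <- lr(u1p$fm)
    a1 <- .attFwd(e3, u1, pk$a1)
    c1in <- cbind(u1, a1$out)
    d1p <- .convFwd(c1in, dims2, pk$c1); d1 <- lr(d1p$fm)
    u2p <- .tconvFwd(d1, dims2, pk$t2); u2 <- lr(u2p$fm)
    a2 <- .attFwd(e1, u2, pk$a2)
    c2in <- cbind(u2, a2$out)
    d2p <- .convFwd(c2in, dimsG, pk$c2); d2 <- lr(d2p$fm)
    u3p <- .tconvFwd(d2, dimsG, pk$t3); u3 <- lr(u3p$fm)
    zp <- .convFwd(u3, dimsG, pk$c3)
    Z[, k] <- zp$fm
    dcache[[k]] <- list(u1p = u1p, u1 = u1, a1 = a1, c1in = c1in, d1p = d1p,
                        d1 = d1, u2p = u2p, u2 = u2, a2 = a2, c2in = c2in,
                        d2p = d2p, d2 = d2, u3p = u3p, u3 = u3)
  }
  Zs <- Z - apply(Z, 1, max)
  E <- exp(Zs)
  P <- E / rowSums(E)
  list(P = P, Z = Z,
       cache = list(x = x, dims = dimsG, dims2 = dims2, dims4 = dims4,
                    e1p = e1p, e1 = e1, e2p = e2p, e2 = e2, e3p = e3p,
                    e3 = e3, e4p = e4p, e4 = e4, e5p = e5p, e5 = e5,
                    drop = drop, dec = dcache))
}

# backward pass from dZ (gradient at the logits); returns the gradient tree
.mceunBackward <- function(params, K, fw, dZ) {
  ch <- fw$cache
  g <- list(enc1 = NULL, enc2 = NULL, enc3 = NULL, enc4 = NULL, enc5 = NULL,
            dec = vector("list", K))
  dE5 <- matrix(0, nrow(ch$e5), ncol(ch$e5))
  dE3 <- matrix(0, nrow(ch$e3), ncol(ch$e3))
  dE1 <- matrix(0, nrow(ch$e1), ncol(ch$e1))
  for (k in seq_len(K)) {
    pk <- params$dec[[k]]
    dc <- ch$dec[[k]]
    b3 <- .convBwd(dc$u3, ch$dims, pk$c3, dZ[, k, drop = FALSE])
    dU3 <- .lreluBwd(dc$u3p$fm, b3$dX)
    bt3 <- .tconvBwd(dc$d2, ch$dims, pk$t3, dU3, dc$u3p$dims)
    dD2 <- .lreluBwd(dc$d2p$fm, bt3$dX)
    b2 <- .convBwd(dc$c2in, ch$dims, pk$c2, dD2)
    Cu2 <- ncol(dc$u2)
    dU2l <- b2$dX[, seq_len(Cu2), drop = FALSE]
    dS2 <- b2$dX[, Cu2 + seq_len(ncol(b2$dX) - Cu2), drop = FALSE]
    ab2 <- .attBwd(ch$e1, dc$u2, pk$a2, dc$a2, dS2)
    dE1 <- dE1 + ab2$dX
    dU2 <- .lreluBwd(dc$u2p$fm, dU2l + ab2$dG)
    bt2 <- .tconvBwd(dc$d1, ch$dims2, pk$t2, dU2, dc$u2p$dims)
    dD1 <- .lreluBwd(dc$d1p$fm, bt2$dX)
    b1 <- .convBwd(dc$c1in, ch$dims2, pk$c1, dD1)
    Cu1 <- ncol(dc$u1)
    dU1l <- b1$dX[, seq_len(Cu1), drop = FALSE]
    dS1 <- b1$dX[, Cu1 + seq_len(ncol(b1$dX) - Cu1), drop = FALSE]
    ab1 <- .attBwd(ch$e3, dc$u1, pk$a1, dc$a1, dS1)
    dE3 <- dE3 + ab1$dX
    dU1 <- .lreluBwd(dc$u1p$fm, dU1l + ab1$dG)
    bt1 <- .tconvBwd(ch$e5, ch$dims4, pk$t1, dU1, dc$u1p$dims)
    dE5 <- dE5 + bt1$dX
    g$dec[[k]] <- list(
      t1 = list(W = bt1$dW, b = bt1$db),
      a1 = list(Wx = ab1$dWx, Wg = ab1$dWg, bq = ab1$dbq,
                psi = ab1$dpsi, bpsi = ab1$dbpsi),
      c1 = list(W = b1$dW, b = b1$db),
      t2 = list(W = bt2$dW, b = bt2$db),
      a2 = list(Wx = ab2$dWx, Wg = ab2$dWg, bq = ab2$dbq,
                psi = ab2$dpsi, bpsi = ab2$dbpsi),
      c2 = list(W = b2$dW, b = b2$db),
      t3 = list(W = bt3$dW, b = bt3$db),
      c3 = list(W = b3$dW, b = b3$db))
  }
  if (!is.null(ch$drop)) dE5 <- dE5 * ch$drop
  dE5 <- .lreluBwd(ch$e5p$fm, dE5)
  b5 <- .convBwd(ch$e4, ch$dims4, params$enc5, dE5)
  dE4 <- .lreluBwd(ch$e4p$fm, b5$dX)
  b4 <- .convBwd(ch$e3, ch$dims2, params$enc4, dE4)
  dE3 <- .lreluBwd(ch$e3p$fm, dE3 + b4$dX)
  b3e <- .convBwd(ch$e2, ch$dims2, params$enc3, dE3)
  dE2 <- .lreluBwd(ch$e2p$fm, b3e$dX)
  b2e <- .convBwd(ch$e1, ch$dims, params$enc2, dE2)
  dE1 <- .lreluBwd(ch$e1p$fm, dE1 + b2e$dX)
  b1e <- .convBwd(ch$x, ch$dims, params$enc1, dE1)
  g$enc1 <- list(W = b1e$dW, b = b1e$db)
  g$enc2 <- list(W = b2e$dW, b = b2e$db)
  g$enc3 <- list(W = b3e$dW, b = b3e$db)
  g$enc4 <- list(W = b4$dW, b = b4$db)
  g$enc5 <- list(W = b5$dW, b = b5$db)
  g
}

#' Per-region loss weights
#'
#' @param weights K non-negative region weights (at least one positive).
#' @param eps probability clipping floor for the logarithms.
#' @return list used by [weightedCrossEntropy()] and [trainMcEUN()].
#' @export
lossConfig <- function(weights, eps = 1e-7) {
  if (all(weights <= 0)) stop("at least one region weight must be positive")
  if (any(weights < 0)) stop("region weights must be non-negative")
  list(weights = weights, eps = eps)
}

.oneHot <- function(lab, K) {
  N <- length(lab)
  T <- matrix(0, N, K)
  T[cbind(seq_len(N), as.integer(lab) + 1L)] <- 1
  T
}

#' Weighted per-region cross-entropy loss
#'
#' Sum over voxels and regions of
#' `w_k * (-Phi log Phihat - (1 - Phi) log(1 - Phihat))`, with probabilities
#' clipped to `[eps, 1 - eps]` before the logarithms (so an exact one-hot
#' prediction of the truth scores ~0).
#'
#' @param pred per-voxel class probabilities: [N x K] matrix or an array
#'   with K as the last dimension.
#' @param truth a [SegmentationMap-class] or integer label array/vector.
#' @param cfg see [lossConfig()].
#' @return non-negative scalar.
#' @export
weightedCrossEntropy <- function(pred, truth, cfg) {
  if (is(truth, "SegmentationMap")) truth <- truth@labels
  if (is.array(pred) && length(dim(pred)) > 2L) {
    K <- dim(pred)[length(dim(pred))]
    pred <- matrix(pred, ncol = K)
  }
  K <- ncol(pred)
  if (length(cfg$weights) != K) stop("weight count does not match K")
  if (length(truth) != nrow(pred)) stop("prediction/truth shape mismatch")
  P <- pmin(pmax(pred, cfg$eps), 1 - cfg$eps)
  T <- .oneHot(as.integer(truth), K)
  ce <- -(T * log(P) + (1 - T) * log(1 - P))
  sum(sweep(ce, 2L, cfg$weights, "*"))
}

# loss gradient at the logits for the softmax + weighted binary CE head;
# returns list(loss, dZ) with loss the raw sum and dZ d(loss)/d(logits)
.lossAndGradZ <- function(P, lab, w, eps = 1e-7) {
  K <- ncol(P)
  T <- .oneHot(lab, K)
  Pc <- pmin(pmax(P, eps), 1 - eps)
  ce <- -(T * log(Pc) + (1 - T) * log(1 - Pc))
  loss <- sum(sweep(ce, 2L, w, "*"))
  inside <- (P > eps) & (P < 1 - eps)
  dP <- sweep((1 - T) / (1 - Pc) - T / Pc, 2L, w, "*") * inside
  dZ <- P * (dP - rowSums(dP * P))
  list(loss = loss, dZ = dZ)
}

.adamStep <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(g)) {
    for (nm in names(g)) {
      if (is.null(g[[nm]])) next
      r <- .adamStep(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t, b1, b2, eps)
      p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
    }
    return(list(p = p, m = m, v = v))
  }
  m2 <- b1 * m + (1 - b1) * g
  v2 <- b2 * v + (1 - b2) * g * g
  mh <- m2 / (1 - b1^t); vh <- v2 / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
}

# dataset sample -> [N x 2] input matrix (channel 1 scatter, channel 2
# photopeak) after per-volume max normalization
.segnetInput <- function(sc, pp) {
  cbind(as.numeric(normalizeInput(sc)), as.numeric(normalizeInput(pp)))
}

#' Region weights inversely proportional to voxel frequency
#'
#' `power = 1` gives plain inverse-frequency weights; `power = 0.5`
#' (square-root inverse frequency) tempers the emphasis on very small
#' regions, which otherwise dominate the loss at the expense of the large
#' organs.
#'
#' @param dataset list of training samples (each with `labels`).
#' @param K number of regions.
#' @param power exponent applied to the inverse frequencies.
#' @return weights normalized so they sum to K.
#' @export
inverseFrequencyWeights <- function(dataset, K = 6L, power = 1) {
  counts <- rep(0, K)
  for (s in dataset) counts <- counts + tabulate(as.integer(s$labels) + 1L, K)
  w <- (1 / pmax(counts, 1))^power
  w * K / sum(w)
}

#' Train the segmentation network
#'
#' Minimizes the weighted cross-entropy with Adam over mini-batches of
#' whole volumes.  Each sample is a list with elements `sc` and `pp`
#' (scatter- and photopeak-window reconstruction volumes; normalized
#' internally) and `labels` (integer ground-truth region volume).  With
#' `cvFolds` set, the epoch count is first selected by the minimum mean
#' cross-validation loss over the folds and the final model retrained on
#' the full data for that many epochs.  Training is deterministic given
#' `seed` (single-threaded deterministic kernels); the log records the mode.
#'
#' @param net an untrained [McEUN-class] from [buildMcEUN()].
#' @param dataset non-empty list of samples.
#' @param epochs (maximum) number of epochs.
#' @param lr Adam learning rate on the per-voxel mean loss scale.
#' @param batchSize volumes per Adam step.
#' @param weights K region weights, or NULL for inverse-frequency defaults.
#' @param validation optional held-out sample list for logged val loss.
#' @param cvFolds optional fold count for cross-validated epoch selection.
#' @param lrEnd optional final learning rate: the rate decays linearly
#'   from `lr` to `lrEnd` over the epochs.
#' @param patchSize optional cubic patch side (divisible by 4): each step
#'   trains on random sub-volumes instead of whole volumes.  The network is
#'   fully convolutional, so patch-trained weights apply to full volumes at
#'   inference; patches make many more optimizer steps affordable per unit
#'   of compute.  Patch centres favour foreground voxels (70%).
#' @param seed RNG seed (shuffling, dropout, patch sampling).
#' @param verbose print per-epoch losses.
#' @return the trained [McEUN-class] with a populated log.
#' @export
trainMcEUN <- function(net, dataset, epochs = 10L, lr = 1e-3, batchSize = 4L,
                       weights = NULL, validation = NULL, cvFolds = NULL,
                       patchSize = NULL, lrEnd = NULL, seed = 1L,
                       verbose = FALSE) {
  if (length(dataset) == 0L) stop("empty training dataset")
  K <- net@config$K
  if (is.null(weights)) weights <- inverseFrequencyWeights(dataset, K)
  if (!is.null(cvFolds)) {
    fold <- rep(seq_len(cvFolds), length.out = length(dataset))
    fold <- withSeed(seed, sample(fold))
    cvLoss <- matrix(NA_real_, epochs, cvFolds)
    for (f in seq_len(cvFolds)) {
      tr <- dataset[fold != f]
      va <- dataset[fold == f]
      fit <- trainMcEUN(net, tr, epochs = epochs, lr = lr,
                        batchSize = batchSize, weights = weights,
                        validation = va, patchSize = patchSize,
                        seed = deriveSeed(seed, f), verbose = verbose)
      cvLoss[, f] <- fit@log$valLoss
    }
    best <- which.min(rowMeans(cvLoss))
    out <- trainMcEUN(net, dataset, epochs = best, lr = lr,
                      batchSize = batchSize, weights = weights,
                      patchSize = patchSize, seed = seed, verbose = verbose)
    out@config$cvLoss <- cvLoss
    out@config$selectedEpochs <- best
    return(out)
  }
  params <- net@params
  mstate <- NULL; vstate <- NULL
  fullDims <- dim(dataset[[1]]$labels)
  # per-volume max normalization happens once, on the whole volume, so
  # patches keep the volume-level intensity scale
  volN <- lapply(dataset, function(s)
    list(sc = normalizeInput(s$sc), pp = normalizeInput(s$pp),
         lab = s$labels))
  usePatch <- !is.null(patchSize)
  if (usePatch) {
    patchSize <- as.integer(patchSize)
    if (patchSize %% 4L != 0L || any(patchSize > fullDims))
      stop("patchSize must be divisible by 4 and fit the volume")
    fgIdx <- lapply(volN, function(v)
      which(v$lab != K - 1L))  # non-background voxels
  }
  inputs <- lapply(volN, function(v)
    cbind(as.numeric(v$sc), as.numeric(v$pp)))
  labs <- lapply(dataset, function(s) as.integer(s$labels))
  drawSample <- function(i) {
    if (!usePatch)
      return(list(x = inputs[[i]], lab = labs[[i]], dims = fullDims))
    v <- volN[[i]]
    ctr <- if (runif(1) < 0.7 && length(fgIdx[[i]]))
      arrayInd(sample(fgIdx[[i]], 1L), fullDims)[1, ]
    else vapply(fullDims, function(d) sample.int(d, 1L), integer(1))
    lo <- pmin(pmax(ctr - patchSize %/% 2L, 1L), fullDims - patchSize + 1L)
    hi <- lo + patchSize - 1L
    sc <- v$sc[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    pp <- v$pp[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    list(x = cbind(as.numeric(sc), as.numeric(pp)),
         lab = as.integer(v$lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]),
         dims = rep(patchSize, 3L))
  }
  logRows <- vector("list", epochs)
  withSeed(seed, {
    stepT <- 0L
    for (ep in seq_len(epochs)) {
      lrEp <- if (is.null(lrEnd)) lr
              else lr + (lrEnd - lr) * (ep - 1) / max(1, epochs - 1)
      ord <- sample(length(dataset))
      epLoss <- 0
      for (b0 in seq(1, length(ord), by = batchSize)) {
        idx <- ord[b0:min(b0 + batchSize - 1L, length(ord))]
        acc <- NULL
        bLoss <- 0
        for (i in idx) {
          sm <- drawSample(i)
          fw <- .mceunForward(params, K, sm$x, sm$dims, training = TRUE,
                              dropout = net@config$dropout)
          lg <- .lossAndGradZ(fw$P, sm$lab, weights)
          if (!is.finite(lg$loss))
            stop(sprintf("non-finite loss at epoch %d; try a lower lr", ep))
          bLoss <- bLoss + lg$loss
          g <- .mceunBackward(params, K, fw,
                              lg$dZ / (prod(sm$dims) * length(idx)))
          acc <- if (is.null(acc)) g else .gmap2(`+`, acc, g)
        }
        epLoss <- epLoss + bLoss
        if (is.null(mstate)) { mstate <- .gzero(acc); vstate <- .gzero(acc) }
        stepT <- stepT + 1L
        up <- .adamStep(params, acc, mstate, vstate, lrEp, stepT)
        params <- up$p; mstate <- up$m; vstate <- up$v
      }
      valLoss <- NA_real_
      if (!is.null(validation)) {
        valLoss <- mean(vapply(validation, function(s) {
          fw <- .mceunForward(params, K, .segnetInput(s$sc, s$pp), fullDims)
          .lossAndGradZ(fw$P, as.integer(s$labels), weights)$loss
        }, numeric(1)))
      }
      logRows[[ep]] <- data.frame(epoch = ep,
                                  trainLoss = epLoss / length(dataset),
                                  valLoss = valLoss,
                                  mode = "deterministic-seeded")
      if (verbose)
        message(sprintf("epoch %d: train %.1f val %.1f", ep,
                        epLoss / length(dataset), valLoss))
    }
  })
  new("McEUN", params = params,
      config = c(net@config[setdiff(names(net@config), "weights")],
                 list(weights = weights)),
      log = do.call(rbind, logRows))
}

#' Predict attenuation-region segments
#'
#' Runs the network on a scatter- and photopeak-window reconstruction pair
#' (normalized internally; a warning is raised if inputs already exceed 1)
#' and takes the voxelwise argmax of the SoftMax output, yielding a one-hot
#' partition of the grid.
#'
#' @param sc,pp reconstruction volumes or [ReconImage-class] objects.
#' @param net a trained [McEUN-class].
#' @return a [SegmentationMap-class] with source "predicted".
#' @export
predictSegments <- function(sc, pp, net) {
  if (is(sc, "ReconImage")) sc <- sc@volume
  if (is(pp, "ReconImage")) pp <- pp@volume
  if (max(sc) > 1 + 1e-6 || max(pp) > 1 + 1e-6)
    warning("inputs exceed 1; applying per-volume max normalization")
  dims <- dim(sc)
  fw <- .mceunForward(net@params, net@config$K, .segnetInput(sc, pp), dims)
  lab <- array(max.col(fw$P, ties.method = "first") - 1L, dim = dims)
  new("SegmentationMap", labels = lab, K = net@config$K, source = "predicted")
}

# voxelwise class probabilities (used by tests)
.predictProbs <- function(sc, pp, net) {
  dims <- dim(sc)
  .mceunForward(net@params, net@config$K, .segnetInput(sc, pp), dims)$P
}
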