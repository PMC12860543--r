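# End-to-end synthetic observer study: cohort -> projections -> defect
# insertion -> three reconstruction arms (reference-mu AC, scatter-based AC,
# no AC) -> channelized Hotelling observer -> clustered statistics.

#' Build the test-sample manifest
#'
#' Each defect-present subject is crossed with every defect type; each
#' defect-absent subject contributes one replicate entry per defect type,
#' all sharing the subject's cluster id (replicates are carried, not
#' deduplicated; the cluster-aware variance treats them as one unit).
#'
#' @param nPresent,nAbsent subject counts (>= 1).
#' @param seed stored with the manifest (subject ordering is
#'   deterministic).
#' @param specs defect-type table (default the full 27 of
#'   [enumerateDefectTypes()]).
#' @param presentIds,absentIds optional subject-id vectors.
#' @param trainingIds subject ids reserved for training; overlap is an
#'   error.
#' @return data.frame manifest: one row per sample.
#' @export
#' @examples
#' nrow(buildTestSet(131, 135))  # 3537 + 3645
buildTestSet <- function(nPresent, nAbsent, seed = 1L,
                         specs = enumerateDefectTypes(),
                         presentIds = sprintf("P%04d", seq_len(nPresent)),
                         absentIds = sprintf("A%04d", seq_len(nAbsent)),
                         trainingIds = NULL) {
  if (nPresent < 1L || nAbsent < 1L) stop("need at least one subject per class")
  if (!is.null(trainingIds) &&
      length(intersect(c(presentIds, absentIds), trainingIds)))
    stop("test subjects overlap the training subjects")
  ns <- nrow(specs)
  present <- data.frame(
    subjectId = rep(presentIds, each = ns),
    clusterId = rep(presentIds, each = ns),
    label = 1L,
    specIndex = rep(seq_len(ns), times = nPresent),
    stringsAsFactors = FALSE)
  absent <- data.frame(
    subjectId = rep(absentIds, each = ns),
    clusterId = rep(absentIds, each = ns),
    label = 0L,
    specIndex = rep(seq_len(ns), times = nAbsent),
    stringsAsFactors = FALSE)
  man <- rbind(present, absent)
  man$extentDeg <- specs$extentDeg[man$specIndex]
  man$severity <- specs$severity[man$specIndex]
  man$location <- specs$location[man$specIndex]
  man$sampleId <- sprintf("%s_%02d", man$subjectId, man$specIndex)
  attr(man, "seed") <- seed
  man
}

#' Study configuration
#'
#' Defaults describe the full-size protocol (64-voxel grid, 8x6 OSEM, all
#' 27 defect types); [deskStudyConfig()] scales the study to a single-CPU
#' footprint.
#'
#' @param grid phantom/recon grid side.
#' @param nTrain training-cohort size.
#' @param nTestPresent,nTestAbsent test-cohort sizes.
#' @param specs defect-type table used for the test samples.
#' @param countScale Poisson counts per projection unit.
#' @param nIterations,nSubsets OSEM settings.
#' @param baseFilters,epochs,lr,batchSize network settings; training is a
#'   two-phase curriculum (see [trainSegmentationNetwork()]) and `epochs`
#'   counts the full-resolution fine-tuning epochs.
#' @param coarseEpochs epochs of the half-resolution curriculum phase
#'   (after restart selection).
#' @param nRestarts,restartEpochs number of random initializations probed
#'   for `restartEpochs` coarse epochs each; the one with the lowest
#'   training loss continues (deep rectifier stacks without batch
#'   normalization land in basins of very different quality).
#' @param initGain weight-initialization gain, see [buildMcEUN()].
#' @param weightPower loss-weight exponent, see
#'   [inverseFrequencyWeights()].
#' @param scatterScale scatter-window amplitude.
#' @param seed master seed.
#' @return configuration list for [runExperiment()].
#' @export
studyConfig <- function(grid = 64L, nTrain = 60L, nTestPresent = 20L,
                        nTestAbsent = 20L, specs = enumerateDefectTypes(),
                        countScale = 3, nIterations = 8L, nSubsets = 6L,
                        baseFilters = 8L, nRestarts = 3L, restartEpochs = 6L,
                        coarseEpochs = 26L, epochs = 1L,
                        lr = 1e-2, batchSize = 2L, initGain = 1.6,
                        weightPower = 0.5, scatterScale = 7, seed = 1L) {
  list(grid = as.integer(grid), nTrain = as.integer(nTrain),
       nTestPresent = as.integer(nTestPresent),
       nTestAbsent = as.integer(nTestAbsent), specs = specs,
       countScale = countScale, nIterations = as.integer(nIterations),
       nSubsets = as.integer(nSubsets), baseFilters = as.integer(baseFilters),
       nRestarts = as.integer(nRestarts),
       restartEpochs = as.integer(restartEpochs),
       coarseEpochs = as.integer(coarseEpochs),
       epochs = as.integer(epochs), lr = lr, batchSize = as.integer(batchSize),
       initGain = initGain, weightPower = weightPower,
       scatterScale = scatterScale, seed = as.integer(seed),
       arms = c("ctac", "ctless", "nac"))
}

#' Desk-scale study configuration
#'
#' A reduced protocol sized for a single CPU: 32-voxel grid, a defect
#' subset concentrating on the larger extents, and a short training
#' schedule.
#'
#' @param ... overrides passed to [studyConfig()].
#' @export
deskStudyConfig <- function(...) {
  specs <- enumerateDefectTypes()
  specs <- specs[specs$extentDeg == 90 & specs$severity == 0.50, ]
  rownames(specs) <- NULL
  defaults <- list(grid = 32L, nTrain = 60L, nTestPresent = 20L,
                   nTestAbsent = 20L, specs = specs)
  over <- list(...)
  do.call(studyConfig, utils::modifyList(defaults, over))
}

# scatter- and photopeak-window NAC reconstructions of a noisy projection
# set (the network inputs / mu-estimation front end); the clinical
# Butterworth post-filter is part of the reconstruction protocol
.nacReconPair <- function(noisy, cfg) {
  rc <- reconConfig(cfg$nIterations, cfg$nSubsets, mu = NULL)
  post <- function(r) {
    v <- butterworthFilter(reconVolume(r), voxelSizeCm = r@voxelSizeCm)
    v[v < 0] <- 0
    v
  }
  list(sc = post(osem(noisy, rc, window = "scatter")),
       pp = post(osem(noisy, rc, window = "photopeak")))
}

# training samples for the segmentation network from a cohort
.makeTrainingData <- function(cohort, cfg) {
  lapply(seq_along(cohort), function(i) {
    ph <- cohort[[i]]
    proj <- projectPhantom(ph, scatterScale = cfg$scatterScale)
    noisy <- addPoissonNoise(proj, cfg$countScale,
                             deriveSeed(cfg$seed, 100L + i))
    rec <- .nacReconPair(noisy, cfg)
    list(sc = rec$sc, pp = rec$pp, labels = ph@labels, id = subjectId(ph))
  })
}

# 2x mean-pooling of a volume (inputs) and majority pooling (labels)
.down2 <- function(a) {
  n <- dim(a)[1] %/% 2L
  b <- (a[seq(1, 2 * n, 2), , ] + a[seq(2, 2 * n, 2), , ]) / 2
  b <- (b[, seq(1, 2 * n, 2), ] + b[, seq(2, 2 * n, 2), ]) / 2
  (b[, , seq(1, 2 * n, 2)] + b[, , seq(2, 2 * n, 2)]) / 2
}

.down2labels <- function(a, K = 6L) {
  n <- dim(a)[1] %/% 2L
  # majority vote over each 2x2x2 block, computed by stacking the 8
  # corner sub-lattices and counting labels
  corners <- lapply(0:7, function(b) {
    a[seq(1 + b %% 2, 2 * n, 2),
      seq(1 + (b %/% 2) %% 2, 2 * n, 2),
      seq(1 + b %/% 4, 2 * n, 2)]
  })
  cnt <- matrix(0L, n^3, K)
  for (cc in corners) cnt[cbind(seq_len(n^3), as.integer(cc) + 1L)] <-
    cnt[cbind(seq_len(n^3), as.integer(cc) + 1L)] + 1L
  array(max.col(cnt, ties.method = "first") - 1L, dim = rep(n, 3L))
}

#' Train the study's segmentation network (two-phase curriculum)
#'
#' Phase one trains on 2x mean-pooled reconstructions (majority-pooled
#' labels) where optimizer steps cost an eighth of full resolution; phase
#' two fine-tunes on the full-resolution volumes at a third of the learning
#' rate.  The network is fully convolutional, so the same weights apply at
#' both scales.  Because this batch-normalization-free architecture lands
#' in optimization basins of very different quality depending on the
#' initialization, several random restarts are probed for a few coarse
#' epochs and the lowest-training-loss candidate continues.  Loss weights
#' follow the configured inverse-frequency power.
#'
#' @param trainingData samples from the cohort reconstruction front end
#'   (lists with `sc`, `pp`, `labels`).
#' @param cfg study configuration (see [studyConfig()]).
#' @param verbose print per-epoch losses.
#' @return a trained [McEUN-class].
#' @export
trainSegmentationNetwork <- function(trainingData, cfg, verbose = FALSE) {
  w <- inverseFrequencyWeights(trainingData, 6L, cfg$weightPower)
  coarse <- lapply(trainingData, function(s)
    list(sc = .down2(s$sc), pp = .down2(s$pp),
         labels = .down2labels(s$labels)))
  candidates <- lapply(seq_len(max(1L, cfg$nRestarts)), function(r) {
    net <- buildMcEUN(K = 6L, grid = cfg$grid, baseFilters = cfg$baseFilters,
                      initGain = cfg$initGain,
                      seed = deriveSeed(cfg$seed, 4L) + r - 1L)
    if (cfg$restartEpochs > 0L)
      net <- trainMcEUN(net, coarse, epochs = cfg$restartEpochs, lr = cfg$lr,
                        batchSize = cfg$batchSize, weights = w,
                        seed = deriveSeed(cfg$seed, 5L), verbose = verbose)
    net
  })
  losses <- vapply(candidates, function(n)
    if (nrow(n@log)) tail(n@log$trainLoss, 1) else Inf, numeric(1))
  net <- candidates[[which.min(losses)]]
  if (cfg$coarseEpochs > 0L)
    net <- trainMcEUN(net, coarse, epochs = cfg$coarseEpochs, lr = cfg$lr,
                      batchSize = cfg$batchSize, weights = w,
                      seed = deriveSeed(cfg$seed, 7L), verbose = verbose)
  if (cfg$epochs > 0L)
    net <- trainMcEUN(net, trainingData, epochs = cfg$epochs, lr = cfg$lr / 3,
                      batchSize = cfg$batchSize, weights = w,
                      seed = deriveSeed(cfg$seed, 6L), verbose = verbose)
  net
}

# per-subject scatter-based attenuation map estimate
.estimateMu <- function(phantom, net, cfg, noiseSeed) {
  proj <- projectPhantom(phantom, scatterScale = cfg$scatterScale)
  noisy <- addPoissonNoise(proj, cfg$countScale, noiseSeed)
  rec <- .nacReconPair(noisy, cfg)
  seg <- predictSegments(normalizeInput(rec$sc), normalizeInput(rec$pp), net)
  # predefined population coefficients, not the subject's own jittered values
  list(mu = muVolume(assembleMu(seg, defaultCoefficientTable())),
       seg = seg, proj = proj)
}

#' Run the end-to-end observer study
#'
#' Generates disjoint training and test cohorts, trains the segmentation
#' network on scatter/photopeak reconstructions, estimates per-subject
#' attenuation maps, reconstructs every test sample under three arms
#' (reference-mu AC using the phantom's true attenuation, scatter-based AC,
#' and no AC), applies the channelized Hotelling observer with
#' leave-one-out templates, and reports clustered AUCs, the
#' non-inferiority decision (margin 5% of the reference AUC),
#' Bonferroni-adjusted superiority tests against no-AC, fidelity metrics
#' with a cluster bootstrap, and AUCs stratified by defect extent and
#' severity.
#'
#' @param cfg configuration from [studyConfig()] or [deskStudyConfig()].
#' @param net optional pre-trained [McEUN-class] (skips training).
#' @param trainingData optional pre-built training samples.
#' @param verbose print stage progress.
#' @return report list (see Details in the vignette).
#' @export
runExperiment <- function(cfg = deskStudyConfig(), net = NULL,
                          trainingData = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  pp <- phantomParams(grid = cfg$grid)
  say("generating cohorts")
  trainCohort <- generateCohort(cfg$nTrain, pp, seed = deriveSeed(cfg$seed, 1L),
                                idPrefix = "T")
  presentCohort <- generateCohort(cfg$nTestPresent, pp,
                                  seed = deriveSeed(cfg$seed, 2L), idPrefix = "P")
  absentCohort <- generateCohort(cfg$nTestAbsent, pp,
                                 seed = deriveSeed(cfg$seed, 3L), idPrefix = "A")
  if (is.null(net)) {
    say("building training data (%d subjects)", cfg$nTrain)
    if (is.null(trainingData)) trainingData <- .makeTrainingData(trainCohort, cfg)
    say("training the segmentation network")
    net <- trainSegmentationNetwork(trainingData, cfg, verbose = verbose)
  }
  manifest <- buildTestSet(cfg$nTestPresent, cfg$nTestAbsent, cfg$seed,
                           specs = cfg$specs,
                           presentIds = vapply(presentCohort, subjectId, ""),
                           absentIds = vapply(absentCohort, subjectId, ""),
                           trainingIds = vapply(trainCohort, subjectId, ""))
  subjects <- c(presentCohort, absentCohort)
  names(subjects) <- vapply(subjects, subjectId, "")
  say("estimating attenuation maps for %d test subjects", length(subjects))
  subjectData <- lapply(seq_along(subjects), function(i) {
    ph <- subjects[[i]]
    est <- .estimateMu(ph, net, cfg, deriveSeed(cfg$seed, 200L + i))
    dice <- diceCoefficients(est$seg, groundTruthSegmentation(ph))
    list(phantom = ph, muHat = est$mu, proj = est$proj, dice = dice,
         lvMask = lvWallMask(ph),
         muRmse = sqrt(mean((est$mu - ph@mu)^2)),
         nacMuRmse = sqrt(mean(ph@mu^2)))
  })
  names(subjectData) <- names(subjects)
  U <- makeRsfChannels(grid = 32L, pixelCm = pp$voxelSizeCm)
  arms <- cfg$arms
  say("reconstructing %d samples x %d arms", nrow(manifest), length(arms))
  feats <- lapply(arms, function(a) matrix(NA_real_, nrow(manifest), ncol(U)))
  names(feats) <- arms
  rmse <- matrix(NA_real_, nrow(manifest), 2,
                 dimnames = list(NULL, c("ctless", "nac")))
  ssim <- rmse
  geomCache <- geometryForPhantom(subjectData[[1]]$phantom)
  for (r in seq_len(nrow(manifest))) {
    sd <- subjectData[[manifest$subjectId[r]]]
    spec <- defectSpec(manifest$extentDeg[r], manifest$severity[r],
                       manifest$location[r])
    if (manifest$label[r] == 1L) {
      ins <- insertDefect(sd$proj, sd$phantom, spec)
      ppSino <- photopeak(ins$proj)
      centroid <- ins$centroid
    } else {
      ppSino <- photopeak(sd$proj)
      centroid <- defectPerturbation(sd$phantom, spec)$centroid
    }
    ppSino <- addPoissonNoise(ppSino, cfg$countScale,
                              deriveSeed(cfg$seed, 1000L + r))
    vols <- list()
    for (a in arms) {
      mu <- switch(a, ctac = sd$phantom@mu, ctless = sd$muHat, nac = NULL)
      rec <- osem(ppSino, reconConfig(cfg$nIterations, cfg$nSubsets, mu),
                  geom = geomCache)
      vol <- butterworthFilter(reconVolume(rec),
                               voxelSizeCm = rec@voxelSizeCm)
      vol[vol < 0] <- 0
      vols[[a]] <- vol
      roi <- extractCardiacROI(vol, centroid, sd$lvMask)
      feats[[a]][r, ] <- applyChannels(roi, U)
    }
    for (a in c("ctless", "nac")) {
      fm <- fidelityMetrics(vols[[a]], vols[["ctac"]])
      rmse[r, a] <- fm$rmse; ssim[r, a] <- fm$ssim
    }
  }
  say("observer and statistics")
  labels <- manifest$label
  clusters <- manifest$clusterId
  t <- lapply(feats, function(f) looTestStatistics(f, labels))
  auc <- lapply(t, function(ti) aucCiCorrelated(ti, labels, clusters))
  dCtlessCtac <- pairedAucDiff(t$ctless, t$ctac, labels, clusters)
  dCtlessNac <- pairedAucDiff(t$ctless, t$nac, labels, clusters)
  dCtacNac <- pairedAucDiff(t$ctac, t$nac, labels, clusters)
  noninf <- noninferiorityTest(auc$ctless$auc, auc$ctac$auc,
                               dCtlessCtac$variance)
  sup <- list(ctless_vs_nac = superiorityTest(dCtlessNac$delta,
                                              dCtlessNac$variance, m = 2L),
              ctac_vs_nac = superiorityTest(dCtacNac$delta,
                                            dCtacNac$variance, m = 2L))
  strat <- .stratifiedAuc(t, manifest)
  fid <- list(
    rmse = list(ctless = mean(rmse[, "ctless"]), nac = mean(rmse[, "nac"]),
                diff = bootstrapDiff(rmse[, "nac"] - rmse[, "ctless"],
                                     clusters, seed = deriveSeed(cfg$seed, 9L))),
    ssim = list(ctless = mean(ssim[, "ctless"]), nac = mean(ssim[, "nac"]),
                diff = bootstrapDiff(ssim[, "ctless"] - ssim[, "nac"],
                                     clusters, seed = deriveSeed(cfg$seed, 10L))))
  dice <- do.call(rbind, lapply(subjectData, function(s) s$dice))
  muRmse <- data.frame(
    subjectId = names(subjectData),
    ctless = vapply(subjectData, function(s) s$muRmse, numeric(1)),
    nac = vapply(subjectData, function(s) s$nacMuRmse, numeric(1)),
    row.names = NULL)
  list(arms = arms, auc = auc, muRmse = muRmse,
       comparisons = list(ctless_vs_ctac = dCtlessCtac,
                          ctless_vs_nac = dCtlessNac,
                          ctac_vs_nac = dCtacNac),
       noninferiority = noninf, superiority = sup, stratified = strat,
       fidelity = fid, dice = dice, manifest = manifest, net = net,
       config = cfg,
       counts = c(nPresentSamples = sum(labels == 1L),
                  nAbsentSamples = sum(labels == 0L)))
}

# AUC stratified over the canonical extent x severity grid (NA where the
# study config carries no samples for a cell); defect-absent samples are
# shared across strata
.stratifiedAuc <- function(t, manifest) {
  out <- lapply(t, function(ti) {
    m <- matrix(NA_real_, 3, 3,
                dimnames = list(extent = paste0(.DEFECT_EXTENTS, "deg"),
                                severity = paste0(100 * .DEFECT_SEVERITIES, "pct")))
    for (i in seq_along(.DEFECT_EXTENTS)) for (j in seq_along(.DEFECT_SEVERITIES)) {
      sel <- manifest$label == 0L |
        (manifest$extentDeg == .DEFECT_EXTENTS[i] &
         manifest$severity == .DEFECT_SEVERITIES[j])
      if (any(manifest$label[sel] == 1L))
        m[i, j] <- rocAuc(ti[sel], manifest$label[sel])$auc
    }
    m
  })
  out
}

#' Write a study report to disk
#'
#' JSON summary plus CSV tables (scores would be written by the caller;
#' the report itself carries no large arrays except the manifest).
#'
#' @param report output of [runExperiment()].
#' @param dir output directory (created if needed).
#' @return invisibly, the JSON path.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  slim <- report[c("arms", "auc", "noninferiority", "superiority",
                   "fidelity", "counts")]
  slim$stratified <- lapply(report$stratified, function(m)
    as.data.frame(as.table(m)))
  path <- file.path(dir, "report.json")
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  write.csv(report$manifest, file.path(dir, "manifest.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(report$dice), file.path(dir, "dice.csv"))
  invisible(path)
}
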