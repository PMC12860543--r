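# CT-to-attenuation conversion, ground-truth region segmentation and
# piecewise-constant attenuation-map assembly.

#' Convert CT Hounsfield units to attenuation coefficients
#'
#' Bilinear model with a slope break at 0 HU, anchored at air
#' (mu(-1000 HU) = 0) and water (mu(0 HU) = `muWater`, default 0.15 1/cm at
#' 140 keV); above water the slope is reduced (bone mineral attenuates less
#' per Hounsfield unit at emission energies than at CT energies).  The map
#' is monotone non-decreasing; out-of-range HU values are clamped to
#' [-1024, 3000] with a warning.
#'
#' @param hu array or vector of Hounsfield units.
#' @param muWater attenuation of water at the emission energy, 1/cm.
#' @param slopeAbove slope above 0 HU, 1/cm per HU.
#' @return attenuation values, 1/cm, same shape as `hu`.
#' @export
#' @examples
#' ctToMu(c(-1000, 0, 1000))
ctToMu <- function(hu, muWater = 0.15, slopeAbove = 5e-5) {
  if (any(hu < -1024 | hu > 3000)) {
    warning("HU values outside [-1024, 3000] clamped")
    hu <- pmin(pmax(hu, -1024), 3000)
  }
  mu <- ifelse(hu <= 0, muWater * (hu + 1000) / 1000, muWater + slopeAbove * hu)
  mu[mu < 0] <- 0
  if (is.array(hu)) array(mu, dim = dim(hu)) else mu
}

#' Segment an attenuation volume into K regions
#'
#' Ground-truth style segmentation of a (possibly noisy) attenuation volume
#' into the K regions of the coefficient table.  `method = "mrf"` runs
#' iterated conditional modes with a Potts smoothing prior over the
#' 6-neighbourhood; `method = "threshold"` is plain nearest-mean
#' classification.  Class means are fixed at the table's population means
#' unless `means` is supplied.
#'
#' @param mu attenuation volume, 1/cm.
#' @param table coefficient table (K rows); see
#'   [defaultCoefficientTable()].
#' @param method "mrf" or "threshold".
#' @param means optional K class means overriding the table.
#' @param beta Potts interaction strength.
#' @param noiseSd assumed measurement noise, 1/cm (data-term scale).
#' @param nSweeps ICM sweeps.
#' @return a [SegmentationMap-class].
#' @export
segmentGroundTruth <- function(mu, table = defaultCoefficientTable(),
                               method = c("mrf", "threshold"), means = NULL,
                               beta = 1.0, noiseSd = 0.005, nSweeps = 10L) {
  method <- match.arg(method)
  if (is.null(means)) means <- table$mu
  K <- length(means)
  d <- dim(mu)
  lab <- cpp_icm(as.numeric(mu), as.integer(d), as.numeric(means), noiseSd,
                 if (method == "mrf") beta else 0.0,
                 if (method == "mrf") as.integer(nSweeps) else 0L)
  lab <- array(lab, dim = d)
  present <- tabulate(lab + 1L, nbins = K)
  if (any(present == 0L))
    warning(sprintf("empty region(s): %s",
                    paste(table$region[present == 0L], collapse = ", ")))
  new("SegmentationMap", labels = lab, K = as.integer(K),
      source = if (method == "mrf") "mrf" else "groundtruth")
}

#' Segmentation map from a phantom's true labels
#'
#' @param phantom a [Phantom-class].
#' @return a [SegmentationMap-class] with source "groundtruth".
#' @export
groundTruthSegmentation <- function(phantom) {
  new("SegmentationMap", labels = phantom@labels,
      K = as.integer(nrow(phantom@regionTable)), source = "groundtruth")
}

#' Assemble a piecewise-constant attenuation map from segments
#'
#' Every voxel receives the predefined coefficient of its region:
#' `mu_hat = sum_k mu_k Phi_k`, evaluated as a per-voxel table lookup
#' (identical to the sum because the supports partition the grid).
#'
#' @param segments a [SegmentationMap-class].
#' @param table coefficient table with K rows matching `segments@K`.
#' @return a [MuMap-class].
#' @export
#' @examples
#' ph <- generatePhantom(phantomParams(grid = 32), seed = 1)
#' mm <- assembleMu(groundTruthSegmentation(ph))
#' identical(muVolume(mm), attenuationMap(ph))
assembleMu <- function(segments, table = defaultCoefficientTable()) {
  if (nrow(table) != segments@K)
    stop("coefficient table region count does not match the segmentation")
  vol <- array(table$mu[segments@labels + 1L], dim = dim(segments@labels))
  new("MuMap", volume = vol, table = table, source = segments@source)
}

#' Dice overlap per region between two segmentations
#'
#' @param a,b [SegmentationMap-class] objects or integer label arrays.
#' @param K number of regions (inferred when possible).
#' @return named numeric vector of Dice coefficients (NaN for regions empty
#'   in both).
#' @export
diceCoefficients <- function(a, b, K = NULL) {
  if (is(a, "SegmentationMap")) { if (is.null(K)) K <- a@K; a <- a@labels }
  if (is(b, "SegmentationMap")) { if (is.null(K)) K <- b@K; b <- b@labels }
  if (is.null(K)) K <- max(a, b) + 1L
  vapply(seq_len(K) - 1L, function(k) {
    na <- sum(a == k); nb <- sum(b == k)
    2 * sum(a == k & b == k) / (na + nb)
  }, numeric(1)) -> d
  names(d) <- paste0("region", seq_len(K) - 1L)
  d
}
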