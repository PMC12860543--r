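# OSEM reconstruction and clinical post-processing (Butterworth filter,
# cardiac ROI extraction with dynamic-range mapping).

#' OSEM reconstruction settings
#'
#' @param nIterations OSEM iterations (clinical default 8).
#' @param nSubsets ordered subsets (clinical default 6); must divide the
#'   number of views.
#' @param mu optional attenuation volume: when given, attenuation is modeled
#'   in the forward and back projections (AC); when NULL, no AC.
#' @return list of settings for [osem()].
#' @export
reconConfig <- function(nIterations = 8L, nSubsets = 6L, mu = NULL) {
  list(nIterations = as.integer(nIterations), nSubsets = as.integer(nSubsets),
       mu = mu)
}

#' Ordered-subsets expectation-maximization reconstruction
#'
#' Classical multiplicative OSEM with interleaved subset view ordering and
#' uniform positive initialization: for subset S,
#' `f <- f * backproject(g_S / project(f)) / backproject(1)`.
#' With one subset this is exactly MLEM.  Non-negativity is preserved at
#' every sub-iteration; denominators are floored at 1e-12.
#'
#' @param sino sinogram array [bin, slice, view] or a
#'   [ProjectionSet-class] (its photopeak window is used unless
#'   `window = "scatter"`).
#' @param config see [reconConfig()]; `config$mu` selects AC vs NAC.
#' @param geom geometry (taken from a ProjectionSet automatically).
#' @param window which stored window to reconstruct for ProjectionSet input.
#' @return a [ReconImage-class].
#' @export
osem <- function(sino, config = reconConfig(), geom = acquisitionGeometry(),
                 window = c("photopeak", "scatter")) {
  window <- match.arg(window)
  muSource <- if (is.null(config$mu)) "none" else "given"
  if (is(sino, "ProjectionSet")) {
    geom <- sino@geometry
    sino <- if (window == "photopeak") sino@photopeak else sino@scatter
  }
  if (any(sino < 0)) stop("negative projection data")
  nv <- geom@nViews
  ns <- config$nSubsets
  if (nv %% ns != 0L) stop("number of views must be divisible by nSubsets")
  eps <- 1e-12
  dims <- c(dim(sino)[1], dim(sino)[1], dim(sino)[2])
  mu <- config$mu
  if (!is.null(mu) && !identical(dim(mu), dims))
    stop("mu grid does not match the reconstruction grid")
  subsets <- lapply(seq_len(ns), function(s) seq(s, nv, by = ns))  # interleaved
  att <- .attCache(mu, geom, dims)  # per-view factors, shared by all updates
  sens <- lapply(subsets, function(vs) {
    ones <- array(1, dim = c(dims[1], dims[3], length(vs)))
    .backprojectViews(ones, mu, geom, vs, dims, att)
  })
  f <- array(1, dim = dims)
  for (it in seq_len(config$nIterations)) {
    for (s in seq_len(ns)) {
      vs <- subsets[[s]]
      fp <- .projectViews(f, mu, geom, vs, att)
      ratio <- sino[, , vs, drop = FALSE] / pmax(fp, eps)
      bp <- .backprojectViews(ratio, mu, geom, vs, dims, att)
      f <- f * bp / pmax(sens[[s]], eps)
    }
  }
  new("ReconImage", volume = f, voxelSizeCm = geom@binSizeCm, window = window,
      muSource = muSource, iterations = config$nIterations,
      subsets = config$nSubsets)
}

#' Three-dimensional Butterworth filter
#'
#' Zero-phase frequency-domain filter with magnitude response
#' `|H(f)| = (1 + (f/fc)^(2 n))^(-1/2)` applied to the 3-D radial frequency.
#' Clinical defaults: order 5, cutoff 0.44 cycles/cm.
#'
#' @param image 3-D array or [ReconImage-class].
#' @param order filter order n.
#' @param cutoff cutoff frequency fc, cycles/cm.
#' @param voxelSizeCm voxel size (taken from a ReconImage automatically).
#' @return filtered object of the same type.
#' @export
butterworthFilter <- function(image, order = 5, cutoff = 0.44,
                              voxelSizeCm = 0.68) {
  if (is(image, "ReconImage")) {
    out <- image
    out@volume <- butterworthFilter(image@volume, order, cutoff,
                                    image@voxelSizeCm)
    return(out)
  }
  d <- dim(image)
  nyq <- 1 / (2 * voxelSizeCm)
  if (cutoff >= nyq)
    warning(sprintf("cutoff %.3f cycles/cm is at or above Nyquist (%.3f)",
                    cutoff, nyq))
  fr <- lapply(d, function(n) {
    k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
    k / (n * voxelSizeCm)
  })
  f2 <- outer(outer(fr[[1]]^2, fr[[2]]^2, "+"), fr[[3]]^2, "+")
  H <- 1 / sqrt(1 + (sqrt(f2) / cutoff)^(2 * order))
  Re(fft(fft(image) * H, inverse = TRUE)) / prod(d)
}

#' Extract the cardiac region of interest for the model observer
#'
#' Takes the transaxial (short-axis; phantoms are built axis-aligned) slice
#' through the defect centroid, extracts a 32 x 32 window centred on the
#' centroid (symmetric zero padding near edges), clips values to `[0, xLV]`
#' where xLV is the maximum value within the LV wall, and maps affinely to
#' [0, 255].
#'
#' @param image 3-D array or [ReconImage-class] (post-filtering).
#' @param centroid defect centroid, 1-based voxel coordinates (x, y, z).
#' @param lvMask logical LV-wall array on the same grid.
#' @param size ROI side length in pixels.
#' @return a [CardiacROI-class].
#' @export
extractCardiacROI <- function(image, centroid, lvMask, size = 32L) {
  if (is(image, "ReconImage")) image <- image@volume
  d <- dim(image)
  if (any(centroid < 1) || any(centroid > d))
    stop("centroid outside the volume")
  if (!any(lvMask)) stop("empty LV mask")
  xLV <- max(image[lvMask])
  if (xLV <= 0) xLV <- max(image)
  z <- floor(centroid[3])  # ties toward the lower slice index
  sl <- image[, , z]
  half <- size %/% 2L
  cx <- round(centroid[1]); cy <- round(centroid[2])
  out <- matrix(0, size, size)
  xs <- (cx - half + 1L):(cx + half)
  ys <- (cy - half + 1L):(cy + half)
  okx <- xs >= 1L & xs <= d[1]
  oky <- ys >= 1L & ys <= d[2]
  out[which(okx), which(oky)] <- sl[xs[okx], ys[oky]]
  out <- pmin(pmax(out, 0), xLV) * (255 / xLV)
  out <- pmin(out, 255)  # guard against floating-point overshoot of the map
  new("CardiacROI", pixels = out, xLV = xLV)
}
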