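#' @useDynLib ctless, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats rnorm runif rpois sd var quantile pnorm qnorm fft rbinom
#' @importFrom utils head write.csv
NULL

#' Acquisition geometry for a parallel-beam cardiac SPECT orbit
#'
#' Describes the step-and-shoot orbit (number of views and arc), the detector
#' binning, and the distance-linear Gaussian collimator-detector response
#' (CDR).  Defaults mirror a clinical cardiac protocol: 30 views over a 180
#' degree arc from 45 degrees right anterior oblique to 45 degrees left
#' posterior oblique, 0.68 cm bins, and a system resolution of 7.4 mm FWHM at
#' 100 mm from the collimator face.
#'
#' @slot nViews number of projection views.
#' @slot arcDeg angular span of the orbit in degrees.
#' @slot startDeg angle of the first view in degrees (45 RAO = -45).
#' @slot nBins transaxial detector bins per view.
#' @slot binSizeCm detector bin size in cm (matches the voxel size).
#' @slot radiusCm distance from the rotation axis to the detector plane, cm.
#' @slot fwhmInterceptCm CDR FWHM at zero distance, cm.
#' @slot fwhmSlope CDR FWHM increase per cm of distance (dimensionless).
#' @slot useCdr logical; model the CDR blur.
#' @slot energyWindows metadata-only keV windows (photopeak, scatter).
#' @export
setClass("AcquisitionGeometry", slots = c(
  nViews = "integer", arcDeg = "numeric", startDeg = "numeric",
  nBins = "integer", binSizeCm = "numeric", radiusCm = "numeric",
  fwhmInterceptCm = "numeric", fwhmSlope = "numeric", useCdr = "logical",
  energyWindows = "list"))

setValidity("AcquisitionGeometry", function(object) {
  if (object@nViews < 1L) return("nViews must be >= 1")
  if (object@binSizeCm <= 0) return("binSizeCm must be positive")
  if (object@fwhmInterceptCm <= 0) return("CDR FWHM intercept must be positive")
  if (object@fwhmInterceptCm + object@fwhmSlope * 100 <= 0)
    return("CDR FWHM must stay positive at all distances")
  TRUE
})

#' Synthetic torso phantom
#'
#' A voxelized subject: an integer region label volume (partition of the
#' grid into K attenuation regions), the attenuation volume in 1/cm, and the
#' tracer activity volume, plus the left-ventricular wall geometry used for
#' defect definition.
#'
#' @slot labels integer array, values 0..K-1 (region indices).
#' @slot mu attenuation volume, 1/cm.
#' @slot activity emission volume, arbitrary count-rate units.
#' @slot voxelSizeCm isotropic voxel size, cm.
#' @slot lvGeometry list: LV centre (voxels), outer/inner radii, wall z-range.
#' @slot subjectId opaque identifier.
#' @slot regionTable the coefficient table the phantom was built from.
#' @export
setClass("Phantom", slots = c(
  labels = "array", mu = "array", activity = "array",
  voxelSizeCm = "numeric", lvGeometry = "list", subjectId = "character",
  regionTable = "data.frame"))

setValidity("Phantom", function(object) {
  if (!identical(dim(object@labels), dim(object@mu)) ||
      !identical(dim(object@labels), dim(object@activity)))
    return("labels, mu and activity must share one grid")
  if (any(object@mu < 0)) return("mu must be non-negative")
  if (any(object@activity < 0)) return("activity must be non-negative")
  lab <- unique(as.integer(object@labels))
  if (any(lab < 0L) || any(lab >= nrow(object@regionTable)))
    return("labels must lie in 0..K-1")
  TRUE
})

#' Photopeak and scatter-window projection data
#'
#' Sinograms for both energy windows on a shared geometry.  Arrays are
#' [bin, slice, view].
#'
#' @slot photopeak photopeak-window sinogram array.
#' @slot scatter scatter-window sinogram array (same shape).
#' @slot geometry an [AcquisitionGeometry-class].
#' @slot isNoise logical; TRUE when a Poisson realization.
#' @slot noiseSeed seed used for the realization (NA when noise-free).
#' @export
setClass("ProjectionSet", slots = c(
  photopeak = "array", scatter = "array", geometry = "AcquisitionGeometry",
  isNoise = "logical", noiseSeed = "integer"))

setValidity("ProjectionSet", function(object) {
  if (!identical(dim(object@photopeak), dim(object@scatter)))
    return("photopeak and scatter sinograms must have identical shape")
  if (any(object@photopeak < 0) || any(object@scatter < 0))
    return("projection data must be non-negative")
  if (dim(object@photopeak)[3] != object@geometry@nViews)
    return("third array dimension must equal nViews")
  TRUE
})

#' Reconstructed emission image
#'
#' @slot volume non-negative activity volume.
#' @slot voxelSizeCm voxel size, cm.
#' @slot window which energy window was reconstructed ("photopeak"/"scatter").
#' @slot muSource attenuation handling: "none", "true" or "ctless".
#' @slot iterations,subsets OSEM settings used.
#' @export
setClass("ReconImage", slots = c(
  volume = "array", voxelSizeCm = "numeric", window = "character",
  muSource = "character", iterations = "integer", subsets = "integer"))

setValidity("ReconImage", function(object) {
  if (any(object@volume < 0)) return("reconstruction must be non-negative")
  TRUE
})

#' Region segmentation of a volume grid
#'
#' One integer label volume; the K binary supports are its one-hot view.
#'
#' @slot labels integer array with values 0..K-1.
#' @slot K number of regions.
#' @slot source "groundtruth", "mrf" or "predicted".
#' @export
setClass("SegmentationMap", slots = c(
  labels = "array", K = "integer", source = "character"))

setValidity("SegmentationMap", function(object) {
  lab <- as.integer(object@labels)
  if (any(lab < 0L) || any(lab >= object@K))
    return("labels must lie in 0..K-1")
  TRUE
})

#' Piecewise-constant assembled attenuation map
#'
#' @slot volume attenuation volume, 1/cm; every value is one of the table
#'   coefficients.
#' @slot table coefficient table used for assembly.
#' @slot source segmentation provenance.
#' @export
setClass("MuMap", slots = c(
  volume = "array", table = "data.frame", source = "character"))

#' Multi-channel-input multi-decoder segmentation U-net
#'
#' Container for the trainable parameters, architecture descriptor and
#' training log of the scatter+photopeak segmentation network.
#'
#' @slot params named list of layer weights and biases.
#' @slot config architecture and training configuration.
#' @slot log per-epoch training/validation loss records.
#' @export
setClass("McEUN", slots = c(params = "list", config = "list", log = "data.frame"))

#' Cardiac region of interest for the model observer
#'
#' A 32 x 32 short-axis patch centred on the defect centroid, clipped to
#' [0, xLV] and mapped to 8-bit range.
#'
#' @slot pixels 32 x 32 matrix with values in [0, 255].
#' @slot xLV maximum pixel value within the LV wall before mapping.
#' @export
setClass("CardiacROI", slots = c(pixels = "matrix", xLV = "numeric"))

setValidity("CardiacROI", function(object) {
  if (any(object@pixels < 0) || any(object@pixels > 255))
    return("ROI pixel values must lie in [0, 255]")
  TRUE
})
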