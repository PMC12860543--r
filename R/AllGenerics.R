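#' @name ctless-accessors
#' @title Accessors for ctless data containers
#' @description Slot accessors for the S4 containers; user code should use
#'   these rather than reaching into slots.
#' @param object,x an S4 object from this package.
#' @return The corresponding component.
NULL

#' @rdname ctless-accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname ctless-accessors
#' @export
setGeneric("regionLabels", function(object) standardGeneric("regionLabels"))
#' @rdname ctless-accessors
#' @export
setGeneric("attenuationMap", function(object) standardGeneric("attenuationMap"))
#' @rdname ctless-accessors
#' @export
setGeneric("activityMap", function(object) standardGeneric("activityMap"))
#' @rdname ctless-accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname ctless-accessors
#' @export
setGeneric("lvGeometry", function(object) standardGeneric("lvGeometry"))
#' @rdname ctless-accessors
#' @export
setGeneric("coefficientTable", function(object) standardGeneric("coefficientTable"))
#' @rdname ctless-accessors
#' @export
setGeneric("photopeak", function(object) standardGeneric("photopeak"))
#' @rdname ctless-accessors
#' @export
setGeneric("scatterWindow", function(object) standardGeneric("scatterWindow"))
#' @rdname ctless-accessors
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))
#' @rdname ctless-accessors
#' @export
setGeneric("viewAngles", function(object) standardGeneric("viewAngles"))
#' @rdname ctless-accessors
#' @export
setGeneric("reconVolume", function(object) standardGeneric("reconVolume"))
#' @rdname ctless-accessors
#' @export
setGeneric("muVolume", function(object) standardGeneric("muVolume"))
#' @rdname ctless-accessors
#' @export
setGeneric("roiPixels", function(object) standardGeneric("roiPixels"))

setMethod("voxelSize", "Phantom", function(object) object@voxelSizeCm)
setMethod("voxelSize", "ReconImage", function(object) object@voxelSizeCm)
setMethod("regionLabels", "Phantom", function(object) object@labels)
setMethod("regionLabels", "SegmentationMap", function(object) object@labels)
setMethod("attenuationMap", "Phantom", function(object) object@mu)
setMethod("activityMap", "Phantom", function(object) object@activity)
setMethod("subjectId", "Phantom", function(object) object@subjectId)
setMethod("lvGeometry", "Phantom", function(object) object@lvGeometry)
setMethod("coefficientTable", "Phantom", function(object) object@regionTable)
setMethod("coefficientTable", "MuMap", function(object) object@table)
setMethod("photopeak", "ProjectionSet", function(object) object@photopeak)
setMethod("scatterWindow", "ProjectionSet", function(object) object@scatter)
setMethod("geometry", "ProjectionSet", function(object) object@geometry)
setMethod("reconVolume", "ReconImage", function(object) object@volume)
setMethod("muVolume", "MuMap", function(object) object@volume)
setMethod("roiPixels", "CardiacROI", function(object) object@pixels)

#' View angles of an orbit
#'
#' @param object an [AcquisitionGeometry-class] or [ProjectionSet-class].
#' @return numeric vector of view angles in degrees.
#' @export
setMethod("viewAngles", "AcquisitionGeometry", function(object) {
  object@startDeg + (seq_len(object@nViews) - 1L) * object@arcDeg / object@nViews
})
setMethod("viewAngles", "ProjectionSet", function(object) viewAngles(object@geometry))

setMethod("show", "AcquisitionGeometry", function(object) {
  cat(sprintf("AcquisitionGeometry: %d views over %g deg (start %g deg)\n",
              object@nViews, object@arcDeg, object@startDeg))
  cat(sprintf("  %d bins x %g cm; detector radius %g cm; CDR %s (FWHM %g + %g d cm)\n",
              object@nBins, object@binSizeCm, object@radiusCm,
              if (object@useCdr) "on" else "off",
              object@fwhmInterceptCm, object@fwhmSlope))
})

setMethod("show", "Phantom", function(object) {
  d <- dim(object@labels)
  cat(sprintf("Phantom '%s': %dx%dx%d voxels @ %g cm\n", object@subjectId,
              d[1], d[2], d[3], object@voxelSizeCm))
  cat(sprintf("  regions: %s\n", paste(object@regionTable$region, collapse = ", ")))
})

setMethod("show", "ProjectionSet", function(object) {
  d <- dim(object@photopeak)
  cat(sprintf("ProjectionSet: %d bins x %d slices x %d views (%s)\n",
              d[1], d[2], d[3],
              if (object@isNoise) "Poisson realization" else "noise-free"))
})

setMethod("show", "ReconImage", function(object) {
  d <- dim(object@volume)
  cat(sprintf("ReconImage [%s window, mu: %s]: %dx%dx%d, OSEM %d it x %d subsets\n",
              object@window, object@muSource, d[1], d[2], d[3],
              object@iterations, object@subsets))
})

setMethod("show", "SegmentationMap", function(object) {
  d <- dim(object@labels)
  cat(sprintf("SegmentationMap (%s): %dx%dx%d, K = %d\n", object@source,
              d[1], d[2], d[3], object@K))
})

setMethod("show", "MuMap", function(object) {
  d <- dim(object@volume)
  cat(sprintf("MuMap (%s): %dx%dx%d, %d coefficient levels\n", object@source,
              d[1], d[2], d[3], length(unique(as.numeric(object@volume)))))
})

setMethod("show", "McEUN", function(object) {
  cfg <- object@config
  cat(sprintf("McEUN: %d-channel input, %d decoders, base filters %d%s\n",
              cfg$inChannels, cfg$K, cfg$baseFilters,
              if (nrow(object@log)) sprintf(", trained %d epochs", max(object@log$epoch))
              else " (untrained)"))
})

setMethod("show", "CardiacROI", function(object) {
  cat(sprintf("CardiacROI: %dx%d, xLV = %.3f\n", nrow(object@pixels),
              ncol(object@pixels), object@xLV))
})
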