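# Disk formats: volumes as NIfTI (one file per volume), acquisition
# geometry and coefficient tables as YAML sidecars.

#' Write a phantom to a directory
#'
#' Writes `labels.nii.gz` (unsigned integers), `mu.nii.gz`,
#' `activity.nii.gz` and a `phantom.yaml` sidecar with the voxel size, LV
#' geometry and coefficient table.
#'
#' @param phantom a [Phantom-class].
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
writePhantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ps <- rep(phantom@voxelSizeCm, 3)
  RNifti::writeNifti(RNifti::asNifti(phantom@labels, pixdim = ps,
                                     datatype = "uint8"),
                     file.path(dir, "labels.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(phantom@mu, pixdim = ps),
                     file.path(dir, "mu.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(phantom@activity, pixdim = ps),
                     file.path(dir, "activity.nii.gz"))
  meta <- list(subjectId = phantom@subjectId,
               voxelSizeCm = phantom@voxelSizeCm,
               lvGeometry = phantom@lvGeometry,
               regionTable = as.list(phantom@regionTable))
  yaml::write_yaml(meta, file.path(dir, "phantom.yaml"))
  invisible(dir)
}

#' Read a phantom written by [writePhantom()]
#'
#' @param dir directory containing the phantom files.
#' @return a [Phantom-class].
#' @export
readPhantom <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "phantom.yaml"))
  rd <- function(f) {
    v <- RNifti::readNifti(file.path(dir, f))
    array(as.numeric(v), dim = dim(v))
  }
  lab <- rd("labels.nii.gz")
  new("Phantom", labels = array(as.integer(lab), dim = dim(lab)),
      mu = rd("mu.nii.gz"), activity = rd("activity.nii.gz"),
      voxelSizeCm = meta$voxelSizeCm,
      lvGeometry = lapply(meta$lvGeometry, unlist),
      subjectId = meta$subjectId,
      regionTable = as.data.frame(meta$regionTable,
                                  stringsAsFactors = FALSE))
}

#' Write projections to a directory
#'
#' `photopeak.nii.gz` and `scatter.nii.gz` hold the [bin, slice, view]
#' arrays; `geometry.yaml` the acquisition geometry and noise provenance.
#'
#' @param proj a [ProjectionSet-class].
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
writeProjections <- function(proj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(RNifti::asNifti(proj@photopeak),
                     file.path(dir, "photopeak.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(proj@scatter),
                     file.path(dir, "scatter.nii.gz"))
  g <- proj@geometry
  yaml::write_yaml(list(
    nViews = g@nViews, arcDeg = g@arcDeg, startDeg = g@startDeg,
    nBins = g@nBins, binSizeCm = g@binSizeCm, radiusCm = g@radiusCm,
    fwhmInterceptCm = g@fwhmInterceptCm, fwhmSlope = g@fwhmSlope,
    useCdr = g@useCdr, energyWindows = g@energyWindows,
    isNoise = proj@isNoise, noiseSeed = proj@noiseSeed),
    file.path(dir, "geometry.yaml"))
  invisible(dir)
}

#' Read projections written by [writeProjections()]
#'
#' @param dir directory containing the projection files.
#' @return a [ProjectionSet-class].
#' @export
readProjections <- function(dir) {
  m <- yaml::read_yaml(file.path(dir, "geometry.yaml"))
  rd <- function(f) {
    v <- RNifti::readNifti(file.path(dir, f))
    array(as.numeric(v), dim = dim(v))
  }
  geom <- new("AcquisitionGeometry", nViews = as.integer(m$nViews),
              arcDeg = m$arcDeg, startDeg = m$startDeg,
              nBins = as.integer(m$nBins), binSizeCm = m$binSizeCm,
              radiusCm = m$radiusCm, fwhmInterceptCm = m$fwhmInterceptCm,
              fwhmSlope = m$fwhmSlope, useCdr = m$useCdr,
              energyWindows = lapply(m$energyWindows, unlist))
  new("ProjectionSet", photopeak = rd("photopeak.nii.gz"),
      scatter = rd("scatter.nii.gz"), geometry = geom,
      isNoise = isTRUE(m$isNoise),
      noiseSeed = if (is.null(m$noiseSeed)) NA_integer_
                  else as.integer(m$noiseSeed))
}

#' Write a volume as NIfTI
#'
#' @param volume 3-D array, [ReconImage-class] or [MuMap-class].
#' @param path output file (.nii or .nii.gz).
#' @param voxelSizeCm voxel size recorded in the header.
#' @return invisibly, `path`.
#' @export
writeVolume <- function(volume, path, voxelSizeCm = 0.68) {
  if (is(volume, "ReconImage")) {
    voxelSizeCm <- volume@voxelSizeCm; volume <- volume@volume
  }
  if (is(volume, "MuMap")) volume <- volume@volume
  RNifti::writeNifti(RNifti::asNifti(volume, pixdim = rep(voxelSizeCm, 3)),
                     path)
  invisible(path)
}
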