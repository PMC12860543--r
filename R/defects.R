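# Perfusion defect definition and projection-domain insertion.
#
# A defect is an angular sector of the LV wall (measured in the short-axis
# plane about the LV long axis) with reduced tracer uptake.  Defects are
# applied only to the photopeak-window projections, by subtracting the
# forward projection of the activity perturbation; the scatter window is
# left untouched.

.DEFECT_EXTENTS <- c(30, 60, 90)
.DEFECT_SEVERITIES <- c(0.10, 0.25, 0.50)
.DEFECT_LOCATIONS <- c("anterior", "inferior", "lateral")
.LOCATION_ANGLE <- c(anterior = 90, lateral = 180, inferior = 270)

#' Enumerate the defect types
#'
#' Full factorial of three radial extents (30/60/90 degrees around the LV
#' wall), three severities (10/25/50% activity reduction) and three
#' locations (anterior/inferior/lateral wall), in extent-major order, then
#' severity, then location.
#'
#' @return data.frame with 27 rows: `extentDeg`, `severity`, `location`.
#' @export
#' @examples
#' nrow(enumerateDefectTypes())
enumerateDefectTypes <- function() {
  grid <- expand.grid(location = .DEFECT_LOCATIONS,
                      severity = .DEFECT_SEVERITIES,
                      extentDeg = .DEFECT_EXTENTS,
                      stringsAsFactors = FALSE)
  data.frame(extentDeg = grid$extentDeg, severity = grid$severity,
             location = grid$location, stringsAsFactors = FALSE)
}

#' A single defect specification
#'
#' @param extentDeg angular extent around the LV wall, degrees (<= 360).
#' @param severity fractional activity reduction, in (0, 1].
#' @param location "anterior", "inferior" or "lateral".
#' @return list describing the defect.
#' @export
defectSpec <- function(extentDeg, severity, location) {
  location <- match.arg(location, .DEFECT_LOCATIONS)
  if (severity <= 0 || severity > 1) stop("severity must be in (0, 1]")
  if (extentDeg <= 0 || extentDeg > 360) stop("extent must be in (0, 360]")
  list(extentDeg = extentDeg, severity = severity, location = location)
}

# logical mask of the defect sector within the LV wall
.defectMask <- function(phantom, spec) {
  wall <- lvWallMask(phantom)
  g <- phantom@lvGeometry
  d <- dim(wall)
  idx <- which(wall, arr.ind = TRUE)
  ang <- atan2(idx[, 2] - g$center[2], idx[, 1] - g$center[1]) * 180 / pi
  delta <- (ang - .LOCATION_ANGLE[[spec$location]] + 180) %% 360 - 180
  sel <- abs(delta) <= spec$extentDeg / 2
  m <- array(FALSE, dim = d)
  m[idx[sel, , drop = FALSE]] <- TRUE
  m
}

#' Activity perturbation volume for a defect
#'
#' `severity * activity` inside the angular sector of the LV wall; zero
#' elsewhere.
#'
#' @param phantom a [Phantom-class].
#' @param spec a [defectSpec()].
#' @return list with the perturbation `volume` and the defect `centroid`
#'   (1-based voxel coordinates).
#' @export
defectPerturbation <- function(phantom, spec) {
  m <- .defectMask(phantom, spec)
  if (!any(m)) stop("defect sector does not intersect the LV wall")
  vol <- array(0, dim = dim(m))
  vol[m] <- spec$severity * phantom@activity[m]
  idx <- which(m, arr.ind = TRUE)
  list(volume = vol, centroid = colMeans(idx))
}

#' Insert a perfusion defect into photopeak projections
#'
#' Subtracts the attenuated forward projection of the defect perturbation
#' from the photopeak sinogram (clipped at zero).  The scatter-window
#' sinogram is returned bit-identical: scatter projections carry no
#' synthetic defects.  Insert defects before adding Poisson noise so
#' defect-present and defect-absent data are independent realizations.
#'
#' @param proj a noise-free [ProjectionSet-class] generated from `phantom`.
#' @param phantom the source [Phantom-class].
#' @param spec a [defectSpec()].
#' @return list: the modified [ProjectionSet-class] (`proj`) and the defect
#'   `centroid`.
#' @export
insertDefect <- function(proj, phantom, spec) {
  pert <- defectPerturbation(phantom, spec)
  dp <- forwardProject(pert$volume, phantom@mu, proj@geometry)
  pp <- pmax(proj@photopeak - dp, 0)
  list(proj = new("ProjectionSet", photopeak = pp, scatter = proj@scatter,
                  geometry = proj@geometry, isNoise = proj@isNoise,
                  noiseSeed = proj@noiseSeed),
       centroid = pert$centroid)
}
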