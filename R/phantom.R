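# Synthetic anthropomorphic torso phantoms.
#
# Anatomy is built from analytic solids (elliptical torso cylinder, lung and
# liver ellipsoids, spine/sternum rods, a hollow truncated-ellipsoid LV wall,
# a thin patient table) on an axis-aligned grid.  Shapes are parameterized in
# fractions of the field of view so any grid size >= 32 produces a consistent
# subject.  Axis convention: +x patient right, +y anterior, +z cranial; the
# LV sits in the left-anterior chest, so its lateral wall faces 180 degrees
# in the short-axis plane (anterior = 90, inferior = 270).

.REGIONS <- c("skin and subcutaneous adipose", "muscles and organs", "lungs",
              "bones", "patient table", "background")

#' Predefined attenuation-region coefficient table
#'
#' Six attenuation regions with the predefined coefficients assigned during
#' attenuation-map assembly (`mu`, 1/cm at 140 keV) and the population mean
#' and standard deviation used for cohort jitter.
#'
#' @return data.frame with columns `region`, `mu`, `mean`, `sd`.
#' @export
#' @examples
#' defaultCoefficientTable()
defaultCoefficientTable <- function() {
  data.frame(
    region = .REGIONS,
    mu   = c(0.13, 0.16, 0.03, 0.22, 0.09, 0),
    mean = c(0.1339, 0.1604, 0.0344, 0.2156, 0.0884, 0.004),
    sd   = c(0.0029, 0.0022, 0.0035, 0.0048, 0.0045, 0.005),
    stringsAsFactors = FALSE)
}

# region indices (0-based, as stored in label volumes)
.RG <- list(skin = 0L, muscle = 1L, lung = 2L, bone = 3L, table = 4L, bg = 5L)

#' Phantom geometry and uptake settings
#'
#' All linear shape parameters are fractions of the field of view (grid
#' extent in cm); uptake values are relative count rates with soft tissue
#' at 1.  Defaults emulate a modest adult torso with high myocardial uptake
#' typical of a Tc-99m perfusion study.
#'
#' @param grid voxels per axis (cubic grid, >= 32).
#' @param voxelSizeCm isotropic voxel size in cm.
#' @param bodyAxes torso half-axes (x, y) as FOV fractions.
#' @param skinThickness skin/adipose shell thickness, FOV fraction.
#' @param lvCenter LV centre (x, y, z), FOV fractions from the grid centre.
#' @param lvOuterRadius,lvWallThickness,lvHalfHeight LV wall shape, FOV
#'   fractions; the wall is a hollow ellipsoid truncated above the base.
#' @param uptake named relative activities per tissue.
#' @param table coefficient table, see [defaultCoefficientTable()].
#' @return list of settings for [generatePhantom()].
#' @export
phantomParams <- function(grid = 64L, voxelSizeCm = 0.68,
                          bodyAxes = c(0.40, 0.28), skinThickness = 0.03,
                          lvCenter = c(-0.15, 0.10, 0.02),
                          lvOuterRadius = 0.10, lvWallThickness = 0.042,
                          lvHalfHeight = 0.15,
                          uptake = c(tissue = 1, lung = 0.3, bone = 0.5,
                                     liver = 1.8, lv = 12, blood = 1),
                          table = defaultCoefficientTable()) {
  list(grid = as.integer(grid), voxelSizeCm = voxelSizeCm, bodyAxes = bodyAxes,
       skinThickness = skinThickness, lvCenter = lvCenter,
       lvOuterRadius = lvOuterRadius, lvWallThickness = lvWallThickness,
       lvHalfHeight = lvHalfHeight, uptake = uptake, table = table,
       bodyCenterY = 0.04, lungScale = 1, bodyScale = 1,
       muValues = NULL)  # NULL -> predefined table coefficients
}

# evaluate with an isolated RNG stream
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

# deterministic child seed below 2^31
deriveSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483629 + 1)
}

#' Generate a synthetic torso phantom
#'
#' Builds the label, attenuation and activity volumes for one subject.  With
#' default parameters the attenuation volume carries exactly the predefined
#' region coefficients, so assembling a map from the ground-truth labels
#' reproduces it identically.
#'
#' @param params settings from [phantomParams()].
#' @param seed integer seed (generation is deterministic per seed).
#' @param subjectId identifier stored in the phantom.
#' @return a [Phantom-class].
#' @export
#' @examples
#' ph <- generatePhantom(phantomParams(grid = 32), seed = 1)
#' table(regionLabels(ph))
generatePhantom <- function(params = phantomParams(), seed = 1L,
                            subjectId = sprintf("S%06d", seed %% 1000000L)) {
  n <- params$grid
  if (n < 32L)
    stop("grid too small to contain the configured LV geometry (need >= 32)")
  h <- params$voxelSizeCm
  u <- ((seq_len(n) - 0.5) / n) - 0.5       # FOV fractions, centre 0
  X <- array(rep(u, times = n * n), dim = c(n, n, n))
  Y <- array(rep(rep(u, each = n), times = n), dim = c(n, n, n))
  Z <- array(rep(u, each = n * n), dim = c(n, n, n))

  bs <- params$bodyScale
  ax <- params$bodyAxes[1] * bs; ay <- params$bodyAxes[2] * bs
  cy0 <- params$bodyCenterY
  body <- (X / ax)^2 + ((Y - cy0) / ay)^2 <= 1
  skin <- body & ((X / (ax - params$skinThickness))^2 +
                  ((Y - cy0) / (ay - params$skinThickness))^2 > 1)

  lab <- array(.RG$bg, dim = c(n, n, n))
  lab[body] <- .RG$muscle
  lab[skin] <- .RG$skin

  ls <- params$lungScale
  lungR <- ((X - 0.18) / (0.14 * ls))^2 + ((Y - 0.07) / (0.17 * ls))^2 +
           ((Z - 0.12) / (0.30 * ls))^2 <= 1
  lungL <- ((X + 0.20) / (0.12 * ls))^2 + ((Y - 0.07) / (0.15 * ls))^2 +
           ((Z - 0.12) / (0.28 * ls))^2 <= 1
  lungs <- (lungR | lungL) & lab == .RG$muscle
  lab[lungs] <- .RG$lung

  spine <- (X^2 + (Y - (cy0 - ay + 0.075))^2 <= 0.045^2) & body
  sternum <- (X^2 + (Y - (cy0 + ay - 0.065))^2 <= 0.022^2) & body & Z > -0.15 & Z < 0.25
  lab[(spine | sternum) & lab != .RG$skin] <- .RG$bone

  # LV wall: hollow ellipsoid truncated above the base plane, repainted as
  # muscle so the wall is a subset of the "muscles and organs" region
  lc <- params$lvCenter
  ro <- params$lvOuterRadius; rz <- params$lvHalfHeight
  ri <- ro - params$lvWallThickness; rzi <- rz - params$lvWallThickness
  outer <- ((X - lc[1]) / ro)^2 + ((Y - lc[2]) / ro)^2 + ((Z - lc[3]) / rz)^2 <= 1
  inner <- ((X - lc[1]) / ri)^2 + ((Y - lc[2]) / ri)^2 + ((Z - lc[3]) / rzi)^2 <= 1
  baseCut <- Z - lc[3] <= 0.55 * rz
  wall <- outer & !inner & baseCut
  cavity <- inner & baseCut
  lab[(wall | cavity)] <- .RG$muscle

  liver <- ((X - 0.14) / 0.16)^2 + ((Y - 0.03) / 0.12)^2 + ((Z + 0.22) / 0.16)^2 <= 1
  liver <- liver & lab == .RG$muscle

  tableMask <- lab == .RG$bg & Y >= -0.46 & Y <= -0.42 & abs(X) <= 0.45
  lab[tableMask] <- .RG$table

  tab <- params$table
  muv <- params$muValues
  if (is.null(muv)) muv <- tab$mu
  mu <- array(muv[lab + 1L], dim = dim(lab))

  up <- params$uptake
  act <- array(0, dim = dim(lab))
  act[lab == .RG$muscle | lab == .RG$skin] <- up[["tissue"]]
  act[lab == .RG$lung] <- up[["lung"]]
  act[lab == .RG$bone] <- up[["bone"]]
  act[liver] <- up[["liver"]]
  act[cavity] <- up[["blood"]]
  act[wall] <- up[["lv"]]

  lv <- list(center = (c(lc[1], lc[2], lc[3]) + 0.5) * n + 0.5,  # 1-based voxel
             outerRadius = ro * n, innerRadius = ri * n,
             halfHeight = rz * n, innerHalfHeight = rzi * n,
             baseCut = 0.55 * rz * n, voxelSizeCm = h)

  new("Phantom", labels = lab, mu = mu, activity = act, voxelSizeCm = h,
      lvGeometry = lv, subjectId = subjectId, regionTable = tab)
}

#' Logical mask of the LV wall voxels
#'
#' Re-evaluates the analytic LV wall condition stored in the phantom's
#' geometry.
#'
#' @param phantom a [Phantom-class].
#' @return logical array on the phantom grid.
#' @export
lvWallMask <- function(phantom) {
  g <- phantom@lvGeometry
  n <- dim(phantom@labels)[1]
  idx <- seq_len(n)
  X <- array(rep(idx, times = n * n), dim = rep(n, 3))
  Y <- array(rep(rep(idx, each = n), times = n), dim = rep(n, 3))
  Z <- array(rep(idx, each = n * n), dim = rep(n, 3))
  dx <- X - g$center[1]; dy <- Y - g$center[2]; dz <- Z - g$center[3]
  outer <- (dx / g$outerRadius)^2 + (dy / g$outerRadius)^2 + (dz / g$halfHeight)^2 <= 1
  inner <- (dx / g$innerRadius)^2 + (dy / g$innerRadius)^2 + (dz / g$innerHalfHeight)^2 <= 1
  outer & !inner & (dz <= g$baseCut)
}

#' Cohort variability settings
#'
#' Per-region attenuation jitter draws each subject's region coefficients
#' from the population normal in the coefficient table (truncated at 0);
#' anatomy scaling jitters torso, lung and LV size; uptake jitter varies the
#' myocardium-to-tissue contrast.  Setting all three to FALSE/0 produces
#' identical subjects.
#'
#' @param muJitter draw region coefficients from the table's (mean, sd).
#' @param anatomySd relative s.d. of torso/lung/LV linear scale factors.
#' @param uptakeSd relative s.d. of LV uptake.
#' @return list of settings for [generateCohort()].
#' @export
cohortVariability <- function(muJitter = TRUE, anatomySd = 0.04, uptakeSd = 0.1) {
  list(muJitter = muJitter, anatomySd = anatomySd, uptakeSd = uptakeSd)
}

#' Generate a cohort of phantoms
#'
#' @param n number of subjects (>= 1).
#' @param params base settings from [phantomParams()].
#' @param variability see [cohortVariability()].
#' @param seed master seed; the cohort is reproducible per seed.
#' @param idPrefix subject-id prefix.
#' @return list of [Phantom-class] objects with distinct subject ids.
#' @export
generateCohort <- function(n, params = phantomParams(),
                           variability = cohortVariability(), seed = 1L,
                           idPrefix = "S") {
  if (n < 1L) stop("n must be >= 1")
  withSeed(seed, {
    lapply(seq_len(n), function(i) {
      p <- params
      if (variability$anatomySd > 0) {
        sc <- function() max(0.85, min(1.15, rnorm(1, 1, variability$anatomySd)))
        p$bodyScale <- sc()
        p$lungScale <- sc()
        lvs <- sc()
        p$lvOuterRadius <- p$lvOuterRadius * lvs
        p$lvHalfHeight <- p$lvHalfHeight * lvs
        p$lvCenter <- p$lvCenter + runif(3, -0.012, 0.012)
      }
      if (variability$uptakeSd > 0) {
        p$uptake[["lv"]] <- max(4, rnorm(1, p$uptake[["lv"]],
                                         variability$uptakeSd * p$uptake[["lv"]]))
        p$uptake[["tissue"]] <- max(0.5, rnorm(1, 1, variability$uptakeSd))
      }
      if (isTRUE(variability$muJitter))
        p$muValues <- pmax(0, rnorm(nrow(p$table), p$table$mean, p$table$sd))
      generatePhantom(p, seed = deriveSeed(seed, i),
                      subjectId = sprintf("%s%04d", idPrefix, i))
    })
  })
}
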