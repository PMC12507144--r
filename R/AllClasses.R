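#' VelocityField: a 4D flow MRI velocity dataset
#'
#' Holds the three velocity component arrays, the magnitude (signal)
#' image, and the acquisition metadata of a 4D flow MRI scan. All four
#' arrays share one `[nx, ny, nz, nt]` shape. Velocities are stored in
#' m/s; voxel spacing in mm; temporal resolution in ms. The grid is
#' axis-aligned, voxel indices are mapped to world coordinates as
#' `(index - 1) * spacing` (no orientation matrix).
#'
#' @slot vx,vy,vz 4D numeric arrays, velocity components in m/s.
#' @slot mag 4D numeric array, signal magnitude (arbitrary units, >= 0).
#' @slot spacing numeric(3), voxel spacing in mm.
#' @slot dt numeric(1), temporal resolution in ms.
#' @slot venc numeric(1), velocity encoding in m/s (metadata only).
#' @export
setClass("VelocityField",
  representation(vx = "array", vy = "array", vz = "array", mag = "array",
                 spacing = "numeric", dt = "numeric", venc = "numeric"),
  validity = function(object) {
    d <- dim(object@vx)
    if (length(d) != 4L) return("velocity arrays must be 4D [nx,ny,nz,nt]")
    for (s in c("vy", "vz", "mag")) {
      if (!identical(dim(slot(object, s)), d))
        return(sprintf("array '%s' does not match the shape of vx", s))
    }
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive values (mm)")
    if (length(object@dt) != 1L || object@dt <= 0)
      return("dt must be a single positive value (ms)")
    if (d[4L] < 1L) return("at least one timeframe is required")
    if (any(object@mag < 0, na.rm = TRUE)) return("mag must be non-negative")
    TRUE
  })

#' Segmentation: a binary lumen mask
#'
#' @slot mask logical 3D array on the same spatial grid as its
#'   [VelocityField-class].
#' @slot spacing numeric(3), voxel spacing in mm.
#' @export
setClass("Segmentation",
  representation(mask = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@mask)) != 3L) return("mask must be a 3D array")
    if (!is.logical(object@mask)) return("mask must be logical")
    if (!any(object@mask)) return("mask has no foreground voxel")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive values (mm)")
    TRUE
  })

#' WallMesh: lumen wall points with inward normals
#'
#' One point per boundary voxel face of a [Segmentation-class], with the
#' unit inward normal (from the signed distance transform), the local
#' lumen diameter measured along that normal, the arc-length coordinate
#' of the nearest centerline sample, and the anatomical region label.
#' All coordinates and lengths are in meters.
#'
#' @slot points n x 3 matrix, wall point world coordinates (m).
#' @slot normals n x 3 matrix, unit inward normals.
#' @slot diameters numeric(n), local lumen diameter (m); `NA` = invalid.
#' @slot arclength numeric(n), centerline arc length (m); `NA` until
#'   regions are assigned.
#' @slot region character(n), one of `r toString(REGION_LEVELS)`.
#' @slot landmarks numeric, region boundary arc lengths (m), filled by
#'   [partitionRegions()].
#' @slot splitDir numeric, fallback inner/outer split direction used for
#'   straight (curvature-free) vessels; length 0 when unused.
#' @slot spacing numeric(3), voxel spacing (mm) of the source grid.
#' @export
setClass("WallMesh",
  representation(points = "matrix", normals = "matrix",
                 diameters = "numeric", arclength = "numeric",
                 region = "character", landmarks = "numeric",
                 splitDir = "numeric", spacing = "numeric"),
  validity = function(object) {
    n <- nrow(object@points)
    if (ncol(object@points) != 3L) return("points must be n x 3")
    if (!identical(dim(object@normals), dim(object@points)))
      return("normals must match points in shape")
    nrm <- sqrt(rowSums(object@normals^2))
    if (any(abs(nrm - 1) > 1e-6)) return("normals must be unit length")
    if (length(object@diameters) != n || length(object@region) != n ||
        length(object@arclength) != n)
      return("per-point slots must all have length nrow(points)")
    if (any(!is.na(object@diameters) & object@diameters <= 0))
      return("diameters must be positive or NA")
    if (!all(object@region %in% REGION_LEVELS))
      return("unknown region label")
    TRUE
  })

#' Centerline: an ordered vessel centerline
#'
#' @slot points n x 3 matrix, centerline sample coordinates (m).
#' @slot arclength numeric(n), cumulative arc length (m), strictly
#'   increasing from 0.
#' @slot tangents n x 3 matrix, unit tangent vectors.
#' @slot radius numeric(n), local lumen inradius (m) from the interior
#'   distance transform.
#' @export
setClass("Centerline",
  representation(points = "matrix", arclength = "numeric",
                 tangents = "matrix", radius = "numeric"),
  validity = function(object) {
    if (any(diff(object@arclength) <= 0))
      return("arclength must be strictly increasing")
    if (!identical(dim(object@tangents), dim(object@points)))
      return("tangents must match points in shape")
    nrm <- sqrt(rowSums(object@tangents^2))
    if (any(abs(nrm - 1) > 1e-6)) return("tangents must be unit length")
    TRUE
  })

#' WSSField: wall shear stress vectors at peak systole
#'
#' Per wall point of a [WallMesh-class]: the WSS vector (Pa, tangent to
#' the wall) and its magnitude. Invalid points carry `NA`, never 0.
#'
#' @slot vectors n x 3 matrix, WSS vectors (Pa); `NA` rows = missing.
#' @slot magnitude numeric(n), WSS magnitude (Pa).
#' @slot frame integer(1), the timeframe (1-based) the field refers to.
#' @slot mu numeric(1), dynamic viscosity (Pa s) used in the estimate.
#' @export
setClass("WSSField",
  representation(vectors = "matrix", magnitude = "numeric",
                 frame = "integer", mu = "numeric"),
  validity = function(object) {
    if (length(object@magnitude) != nrow(object@vectors))
      return("magnitude must have one value per vector row")
    if (any(object@magnitude < 0, na.rm = TRUE))
      return("magnitude must be non-negative")
    if (object@mu <= 0) return("mu must be positive")
    TRUE
  })

#' HemoAtlas: normative healthy-cohort atlas
#'
#' Voxelwise (velocity) and wall-pointwise (WSS) normative statistics on
#' a shared aortic geometry: mean vector, mean magnitude and the sample
#' SD of the magnitude, from which the upper 95% bound
#' `mean + 1.96 * SD` is derived. A location is defined only where at
#' least 80% of the cohort (and no fewer than 2 subjects) contribute;
#' undefined locations are `NA`.
#'
#' @slot seg shared [Segmentation-class].
#' @slot mesh shared [WallMesh-class] with regions assigned.
#' @slot voxelIdx integer, linear indices of the lumen voxels the
#'   velocity statistics refer to (in `which(mask)` order).
#' @slot voxelRegion character, region label per lumen voxel.
#' @slot velMean n x 3 matrix, mean velocity vector (m/s).
#' @slot velMagMean,velMagSD numeric(n), mean and SD of speed (m/s).
#' @slot velN integer(n), contributing subjects per voxel.
#' @slot wssMean m x 3 matrix, mean WSS vector (Pa).
#' @slot wssMagMean,wssMagSD numeric(m), mean and SD of WSS magnitude.
#' @slot wssN integer(m), contributing subjects per wall point.
#' @slot nSubjects integer(1), cohort size.
#' @export
setClass("HemoAtlas",
  representation(seg = "Segmentation", mesh = "WallMesh",
                 voxelIdx = "integer", voxelRegion = "character",
                 velMean = "matrix", velMagMean = "numeric",
                 velMagSD = "numeric", velN = "integer",
                 wssMean = "matrix", wssMagMean = "numeric",
                 wssMagSD = "numeric", wssN = "integer",
                 nSubjects = "integer"),
  validity = function(object) {
    n <- length(object@voxelIdx)
    if (length(object@velMagMean) != n || length(object@velMagSD) != n)
      return("velocity statistics must have one value per lumen voxel")
    if (any(object@velMagSD < 0, na.rm = TRUE) ||
        any(object@wssMagSD < 0, na.rm = TRUE))
      return("SD slots must be non-negative")
    if (object@nSubjects < 2L) return("an atlas needs at least 2 subjects")
    TRUE
  })

#' AbnormalityMap: voxel/wall-point abnormality flags for one patient
#'
#' Booleans per atlas location: magnitude above the upper 95% bound of
#' the atlas (`elevated*`) and vector direction deviating by more than
#' the angular threshold from the atlas mean vector (`misdirected*`).
#' `NA` marks locations that could not be evaluated (atlas undefined,
#' patient uncovered, or near-zero vectors for the direction test).
#'
#' @slot elevatedVelocity,misdirectedVelocity logical, per lumen voxel.
#' @slot elevatedWSS,misdirectedWSS logical, per wall point.
#' @slot angleThreshold numeric(1), direction threshold in degrees.
#' @slot ciFactor numeric(1), SD multiplier of the magnitude threshold.
#' @export
setClass("AbnormalityMap",
  representation(elevatedVelocity = "logical", elevatedWSS = "logical",
                 misdirectedVelocity = "logical", misdirectedWSS = "logical",
                 angleThreshold = "numeric", ciFactor = "numeric"),
  validity = function(object) {
    if (length(object@elevatedVelocity) != length(object@misdirectedVelocity))
      return("velocity flag vectors must have equal length")
    if (length(object@elevatedWSS) != length(object@misdirectedWSS))
      return("WSS flag vectors must have equal length")
    TRUE
  })

#' RigidTransform: a 6-DOF mask-to-mask registration result
#'
#' Maps moving-space world coordinates (mm) into fixed space as
#' `R (p - center) + center + translation`, where `R` is the rotation
#' built from the three Euler angles (radians, applied x-y-z).
#'
#' @slot rotation numeric(3), Euler angles in radians.
#' @slot translation numeric(3), translation in mm.
#' @slot center numeric(3), rotation center (moving centroid, mm).
#' @slot dice numeric(1), Dice overlap after registration.
#' @slot poor logical(1), `TRUE` when the final Dice is below 0.5.
#' @export
setClass("RigidTransform",
  representation(rotation = "numeric", translation = "numeric",
                 center = "numeric", dice = "numeric", poor = "logical"))

#' PhantomSpec: parameters of a pulsatile tube-flow phantom
#'
#' Describes a straight or U-bend tube carrying pulsatile Poiseuille
#' flow whose waveform propagates along the centerline at a prescribed
#' pulse wave velocity. The defaults mirror a thoracic-aorta 4D flow
#' acquisition: 2.5 mm isotropic voxels, 30 timeframes at 32 ms, peak
#' velocity 1 m/s, PWV 8 m/s, and Gaussian velocity noise at 1/20 of
#' the peak velocity.
#'
#' @slot geometry `"straight"` or `"u-bend"`.
#' @slot radius numeric(1), lumen radius R in mm.
#' @slot length numeric(1), straight length in mm (for `"u-bend"`, the
#'   length of each straight arm).
#' @slot bendRadius numeric(1), centerline bend radius Rc in mm
#'   (U-bend only).
#' @slot vmaxPeak numeric(1), peak centerline velocity in m/s.
#' @slot waveform numeric(nt), one cardiac cycle of the normalized flow
#'   waveform (maximum exactly 1); also sets the number of timeframes.
#' @slot pwvTrue numeric(1), ground-truth pulse wave velocity in m/s.
#' @slot noiseSD numeric(1), SD of the Gaussian velocity noise (m/s)
#'   added to every component, inside and outside the lumen.
#' @slot seed integer(1), RNG seed; all phantom randomness flows from it.
#' @slot spacing numeric(1), isotropic voxel spacing in mm.
#' @slot dt numeric(1), temporal resolution in ms.
#' @slot landmarks numeric(3), arc-length positions (mm) of the
#'   brachiocephalic-, left-subclavian- and diaphragm-equivalent levels.
#' @slot stepAt numeric(1), arc length (mm) after which `vmaxPeak` is
#'   multiplied by `stepFactor` (`NA` = no step).
#' @slot stepFactor numeric(1), the step multiplier.
#' @slot phaseOffset numeric(1), constant velocity offset (m/s) added to
#'   the first component, emulating an uncorrected background phase
#'   offset (0 by default).
#' @export
setClass("PhantomSpec",
  representation(geometry = "character", radius = "numeric",
                 length = "numeric", bendRadius = "numeric",
                 vmaxPeak = "numeric", waveform = "numeric",
                 pwvTrue = "numeric", noiseSD = "numeric",
                 seed = "integer", spacing = "numeric", dt = "numeric",
                 landmarks = "numeric", stepAt = "numeric",
                 stepFactor = "numeric", phaseOffset = "numeric"),
  validity = function(object) {
    if (!object@geometry %in% c("straight", "u-bend"))
      return("geometry must be 'straight' or 'u-bend'")
    if (object@radius <= 2 * object@spacing)
      return("radius must exceed 2 voxels for a resolvable lumen")
    if (abs(max(object@waveform) - 1) > 1e-8)
      return("waveform maximum must be exactly 1")
    if (length(object@waveform) < 1L) return("waveform must be non-empty")
    if (object@pwvTrue <= 0) return("pwvTrue must be positive")
    if (object@noiseSD < 0) return("noiseSD must be non-negative")
    if (length(object@landmarks) != 3L || any(diff(object@landmarks) <= 0))
      return("landmarks must be 3 strictly increasing arc lengths (mm)")
    TRUE
  })

#' CohortSpec: a cohort of phantom subjects
#'
#' Subjects share the template grid; per subject, the peak velocity and
#' (optionally) the lumen radius are perturbed by log-normal multipliers
#' `exp(N(0, sd^2))`, so that e.g. `vmaxSD = 0.1` yields roughly 10%
#' between-subject variability in centerline velocity.
#'
#' @slot n integer(1), number of subjects (>= 2).
#' @slot vmaxSD numeric(1), log-SD of the peak-velocity multiplier.
#' @slot radiusSD numeric(1), log-SD of the radius multiplier (0 keeps
#'   the geometry shared exactly).
#' @slot template [PhantomSpec-class] shared by the cohort.
#' @slot seed integer(1), cohort RNG seed.
#' @export
setClass("CohortSpec",
  representation(n = "integer", vmaxSD = "numeric", radiusSD = "numeric",
                 template = "PhantomSpec", seed = "integer"),
  validity = function(object) {
    if (object@n < 2L) return("a cohort needs at least 2 subjects")
    if (object@vmaxSD < 0 || object@radiusSD < 0)
      return("SD multipliers must be non-negative")
    TRUE
  })

#' PwvFit: pulse wave velocity from the delay-distance regression
#'
#' @slot sections data.frame with columns `arclength_m`, `delay_s`,
#'   `weight` (total wavelet cross-power).
#' @slot pwv numeric(1), estimated PWV in m/s (1/slope).
#' @slot r2 numeric(1), R^2 of the weighted delay-distance regression.
#' @slot valid logical(1), `FALSE` when the slope is non-positive or
#'   R^2 < 0.5.
#' @export
setClass("PwvFit",
  representation(sections = "data.frame", pwv = "numeric",
                 r2 = "numeric", valid = "logical"))
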