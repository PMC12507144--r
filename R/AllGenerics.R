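#' Accessors for aortaflow classes
#'
#' Small accessor set for the S4 containers: voxel `spacing()` (mm),
#' `timeStep()` (ms), `nFrames()`, the binary `lumenMask()`, wall-mesh
#' geometry (`wallPoints()`, `wallNormals()`, `lumenDiameters()`,
#' `regionLabels()`, `arcLengths()`), and WSS values (`wssVectors()`,
#' `wssMagnitudes()`).
#'
#' @param x an aortaflow object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("timeStep", function(x) standardGeneric("timeStep"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("lumenMask", function(x) standardGeneric("lumenMask"))
#' @rdname accessors
#' @export
setGeneric("wallPoints", function(x) standardGeneric("wallPoints"))
#' @rdname accessors
#' @export
setGeneric("wallNormals", function(x) standardGeneric("wallNormals"))
#' @rdname accessors
#' @export
setGeneric("lumenDiameters", function(x) standardGeneric("lumenDiameters"))
#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setGeneric("arcLengths", function(x) standardGeneric("arcLengths"))
#' @rdname accessors
#' @export
setGeneric("wssVectors", function(x) standardGeneric("wssVectors"))
#' @rdname accessors
#' @export
setGeneric("wssMagnitudes", function(x) standardGeneric("wssMagnitudes"))
#' @rdname accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname accessors
setMethod("spacing", "VelocityField", function(x) x@spacing)
#' @rdname accessors
setMethod("spacing", "Segmentation", function(x) x@spacing)
#' @rdname accessors
setMethod("timeStep", "VelocityField", function(x) x@dt)
#' @rdname accessors
setMethod("nFrames", "VelocityField", function(x) dim(x@vx)[4L])
#' @rdname accessors
setMethod("lumenMask", "Segmentation", function(x) x@mask)
#' @rdname accessors
setMethod("lumenMask", "HemoAtlas", function(x) x@seg@mask)
#' @rdname accessors
setMethod("wallPoints", "WallMesh", function(x) x@points)
#' @rdname accessors
setMethod("wallNormals", "WallMesh", function(x) x@normals)
#' @rdname accessors
setMethod("lumenDiameters", "WallMesh", function(x) x@diameters)
#' @rdname accessors
setMethod("regionLabels", "WallMesh", function(x) x@region)
#' @rdname accessors
setMethod("arcLengths", "WallMesh", function(x) x@arclength)
#' @rdname accessors
setMethod("arcLengths", "Centerline", function(x) x@arclength)
#' @rdname accessors
setMethod("wallPoints", "Centerline", function(x) x@points)
#' @rdname accessors
setMethod("wssVectors", "WSSField", function(x) x@vectors)
#' @rdname accessors
setMethod("wssMagnitudes", "WSSField", function(x) x@magnitude)
#' @rdname accessors
setMethod("nSubjects", "HemoAtlas", function(x) x@nSubjects)

setMethod("show", "VelocityField", function(object) {
  d <- dim(object@vx)
  cat(sprintf(
    "VelocityField: %d x %d x %d voxels, %d timeframes\n", d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing %.3g x %.3g x %.3g mm, dt %.3g ms, venc %.3g m/s\n",
              object@spacing[1], object@spacing[2], object@spacing[3],
              object@dt, object@venc))
})

setMethod("show", "Segmentation", function(object) {
  d <- dim(object@mask)
  cat(sprintf("Segmentation: %d x %d x %d voxels, %d in lumen\n",
              d[1], d[2], d[3], sum(object@mask)))
})

setMethod("show", "WallMesh", function(object) {
  cat(sprintf("WallMesh: %d wall points\n", nrow(object@points)))
  if (any(!is.na(object@diameters)))
    cat(sprintf("  median lumen diameter %.1f mm\n",
                1000 * median(object@diameters, na.rm = TRUE)))
  if (any(object@region != "none")) {
    tb <- table(factor(object@region, levels = REGION_LEVELS))
    cat("  regions:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  }
})

setMethod("show", "Centerline", function(object) {
  cat(sprintf("Centerline: %d samples, length %.1f mm\n",
              nrow(object@points), 1000 * max(object@arclength)))
})

setMethod("show", "WSSField", function(object) {
  ok <- !is.na(object@magnitude)
  cat(sprintf("WSSField at frame %d (mu = %.2e Pa s): %d/%d valid points\n",
              object@frame, object@mu, sum(ok), length(ok)))
  if (any(ok))
    cat(sprintf("  mean |WSS| %.3f Pa\n", mean(object@magnitude[ok])))
})

setMethod("show", "HemoAtlas", function(object) {
  cat(sprintf("HemoAtlas from %d subjects: %d lumen voxels, %d wall points\n",
              object@nSubjects, length(object@voxelIdx),
              nrow(object@wssMean)))
  cat(sprintf("  defined: %d voxels (velocity), %d points (WSS)\n",
              sum(!is.na(object@velMagMean)), sum(!is.na(object@wssMagMean))))
})

setMethod("show", "AbnormalityMap", function(object) {
  cat(sprintf("AbnormalityMap (>%g SD, >%g deg):\n",
              object@ciFactor, object@angleThreshold))
  cat(sprintf("  elevated velocity %d, elevated WSS %d, misdirected velocity %d, misdirected WSS %d\n",
              sum(object@elevatedVelocity, na.rm = TRUE),
              sum(object@elevatedWSS, na.rm = TRUE),
              sum(object@misdirectedVelocity, na.rm = TRUE),
              sum(object@misdirectedWSS, na.rm = TRUE)))
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: rot (%.2f, %.2f, %.2f) deg, t (%.2f, %.2f, %.2f) mm, Dice %.3f%s\n",
              object@rotation[1] * 180 / pi, object@rotation[2] * 180 / pi,
              object@rotation[3] * 180 / pi, object@translation[1],
              object@translation[2], object@translation[3], object@dice,
              if (object@poor) " (poor overlap)" else ""))
})

setMethod("show", "PwvFit", function(object) {
  cat(sprintf("PwvFit: PWV %.2f m/s, R^2 %.3f, %d sections%s\n",
              object@pwv, object@r2, nrow(object@sections),
              if (object@valid) "" else " (INVALID)"))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s tube, R %.1f mm, vmax %.2f m/s, PWV %.1f m/s, %d frames @ %.3g ms, noise %.3g m/s, seed %d\n",
              object@geometry, object@radius, object@vmaxPeak,
              object@pwvTrue, length(object@waveform), object@dt,
              object@noiseSD, object@seed))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d subjects, vmax log-SD %.3g, radius log-SD %.3g, seed %d\n",
              object@n, object@vmaxSD, object@radiusSD, object@seed))
})
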