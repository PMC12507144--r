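#' Apply the inverse of a rigid transform
#'
#' @param transform a [RigidTransform-class].
#' @param pts n x 3 matrix in fixed space (mm).
#' @return n x 3 matrix in moving space (mm).
#' @export
applyRigidInverse <- function(transform, pts) {
  R <- .eulerMatrix(transform@rotation)
  ctr <- transform@center
  sweep(sweep(pts, 2L, ctr + transform@translation) %*% R, 2L, ctr, "+")
}

#' Build a normative atlas from cohort samples on a shared geometry
#'
#' Voxelwise/pointwise mean vector, mean magnitude and sample SD
#' (n - 1 denominator) of velocity and WSS over a healthy cohort whose
#' values have been brought onto one shared geometry. The upper bound
#' of the 95% band is `mean + 1.96 * SD`. A location is defined only
#' where at least `minFrac` of the cohort (and no fewer than 2
#' subjects) contribute; elsewhere the statistics are `NA`.
#'
#' @param velList list (one per subject) of `n x 3` velocity-vector
#'   matrices at the shared lumen voxels (m/s); `NA` rows where the
#'   subject does not cover a voxel.
#' @param wssList list of `m x 3` WSS-vector matrices at the shared
#'   wall points (Pa); `NA` rows where invalid.
#' @param seg shared [Segmentation-class].
#' @param mesh shared [WallMesh-class] with regions assigned.
#' @param centerline shared [Centerline-class].
#' @param minFrac minimum fraction of contributing subjects.
#' @return A [HemoAtlas-class].
#' @export
buildAtlas <- function(velList, wssList, seg, mesh, centerline,
                       minFrac = 0.8) {
  ns <- length(velList)
  if (ns < 2L || length(wssList) != ns)
    stop("an atlas needs >= 2 subjects with matched velocity and WSS samples")
  voxelIdx <- which(seg@mask)
  n <- length(voxelIdx); m <- nrow(mesh@points)

  stat3 <- function(lst, n) {
    sum1 <- matrix(0, n, 3); cnt <- integer(n)
    magSum <- numeric(n); magSq <- numeric(n)
    for (v in lst) {
      okRow <- !is.na(v[, 1])
      sum1[okRow, ] <- sum1[okRow, ] + v[okRow, , drop = FALSE]
      mg <- sqrt(rowSums(v[okRow, , drop = FALSE]^2))
      magSum[okRow] <- magSum[okRow] + mg
      magSq[okRow] <- magSq[okRow] + mg^2
      cnt[okRow] <- cnt[okRow] + 1L
    }
    need <- max(2L, ceiling(minFrac * length(lst)))
    def <- cnt >= need
    meanVec <- sum1 / cnt
    meanMag <- magSum / cnt
    sdMag <- sqrt(pmax(magSq - cnt * meanMag^2, 0) / (cnt - 1L))
    meanVec[!def, ] <- NA_real_
    meanMag[!def] <- NA_real_
    sdMag[!def] <- NA_real_
    list(meanVec = meanVec, meanMag = meanMag, sdMag = sdMag, n = cnt)
  }
  sv <- stat3(velList, n)
  sw <- stat3(wssList, m)

  vpts <- indexToWorld(arrayInd(voxelIdx, dim(seg@mask)) - 1, seg@spacing)
  splitDir <- if (length(mesh@splitDir)) mesh@splitDir else NULL
  vreg <- .assignRegions(vpts, centerline, mesh@landmarks, splitDir)$region

  new("HemoAtlas", seg = seg, mesh = mesh, voxelIdx = as.integer(voxelIdx),
      voxelRegion = vreg, velMean = sv$meanVec, velMagMean = sv$meanMag,
      velMagSD = sv$sdMag, velN = as.integer(sv$n), wssMean = sw$meanVec,
      wssMagMean = sw$meanMag, wssMagSD = sw$sdMag,
      wssN = as.integer(sw$n), nSubjects = as.integer(ns))
}

#' Build the atlas for a phantom cohort
#'
#' Convenience orchestrator: derives the shared geometry (wall mesh,
#' diameters, centerline, regions) from the cohort template, then for
#' every subject detects peak systole, samples the peak-systolic
#' velocity vectors at the shared lumen voxels (a subject contributes
#' where its own lumen covers the voxel) and estimates WSS at the
#' shared wall points, and feeds everything to [buildAtlas()].
#'
#' @param cspec the [CohortSpec-class].
#' @param cohort optionally a pre-generated [makeCohort()] result.
#' @param mu dynamic viscosity (Pa s) for the WSS estimates.
#' @param splitDir inner/outer fallback direction for straight
#'   templates (see [partitionRegions()]).
#' @param minFrac minimum fraction of contributing subjects.
#' @return `list(atlas, geometry)` where `geometry` holds the shared
#'   `seg`, `mesh` and `centerline`.
#' @export
cohortAtlas <- function(cspec, cohort = NULL, mu = 3.2e-3,
                        splitDir = NULL, minFrac = 0.8) {
  stopifnot(is(cspec, "CohortSpec"))
  if (is.null(cohort)) cohort <- makeCohort(cspec)
  geo <- phantomGeometry(makePhantom(cspec@template), splitDir = splitDir)
  voxelIdx <- which(geo$seg@mask)
  nvol <- prod(dim(geo$seg@mask))
  velList <- vector("list", length(cohort))
  wssList <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    subj <- cohort[[i]]
    if (!identical(dim(subj$seg@mask), dim(geo$seg@mask)))
      stop("cohort subject ", i, " is not on the template grid")
    pf <- peakSystoleIndex(subj$field, subj$seg)
    off <- (pf - 1L) * nvol
    v <- cbind(subj$field@vx[voxelIdx + off],
               subj$field@vy[voxelIdx + off],
               subj$field@vz[voxelIdx + off])
    v[!subj$seg@mask[voxelIdx], ] <- NA_real_
    velList[[i]] <- v
    wssList[[i]] <- wssVectors(estimateWSS(subj$field, geo$mesh, pf, mu = mu))
  }
  atlas <- buildAtlas(velList, wssList, geo$seg, geo$mesh, geo$centerline,
                      minFrac = minFrac)
  list(atlas = atlas, geometry = geo)
}

#' Derive the full geometry of a phantom dataset
#'
#' Wall mesh with normals and diameters, centerline oriented from the
#' inlet, and the six-region partition using the phantom's ground-truth
#' landmarks.
#'
#' @param dataset a [makePhantom()] result.
#' @param splitDir inner/outer fallback direction for straight tubes.
#' @return `list(seg, mesh, centerline)`.
#' @export
phantomGeometry <- function(dataset, splitDir = NULL) {
  seg <- dataset$seg
  mesh <- extractWall(seg)
  mesh <- lumenDiameter(mesh, seg)
  g <- dataset$truth$layout
  inlet <- if (dataset$truth$spec@geometry == "straight")
    c(g$cx, g$cy, g$z0) / 1000 else c(g$x1, g$y0, g$z0) / 1000
  cl <- extractCenterline(seg, inlet = inlet)
  if (is.null(splitDir) && dataset$truth$spec@geometry == "straight")
    splitDir <- c(1, 0, 0)
  # ground-truth landmarks are analytic arc lengths; express them on
  # the measured centerline (which starts slightly inside the capped
  # ends) via the nearest measured sample to the analytic position
  lmPos <- as.matrix(dataset$truth$centerline[
    vapply(dataset$truth$landmarks,
           function(s) which.min(abs(dataset$truth$centerline$arclength_m - s)),
           1L), c("x", "y", "z")])
  lmMeasured <- vapply(seq_len(nrow(lmPos)), function(i) {
    d2 <- rowSums(sweep(cl@points, 2L, lmPos[i, ])^2)
    cl@arclength[which.min(d2)]
  }, 1)
  lmMeasured <- pmin(pmax(lmMeasured, 1e-6), max(cl@arclength))
  if (any(diff(lmMeasured) <= 0))
    stop("landmarks collapse on the measured centerline; vessel too short")
  mesh <- partitionRegions(mesh, cl, lmMeasured, splitDir = splitDir)
  list(seg = seg, mesh = mesh, centerline = cl)
}

#' Flag locations with elevated magnitude
#'
#' A location is elevated when the patient magnitude strictly exceeds
#' the upper bound of the atlas 95% band, `mean + ciFactor * SD`
#' (one-sided: decreased values are not flagged). Locations where the
#' atlas is undefined or the patient value missing are `NA` (counted as
#' uncovered, never flagged).
#'
#' @param patientMag numeric, patient magnitudes at the atlas locations.
#' @param meanMag,sdMag atlas magnitude mean and SD.
#' @param ciFactor SD multiplier (default 1.96).
#' @return logical vector with `NA` where not evaluable.
#' @export
flagElevated <- function(patientMag, meanMag, sdMag, ciFactor = 1.96) {
  out <- patientMag > meanMag + ciFactor * sdMag
  out[is.na(patientMag) | is.na(meanMag)] <- NA
  out
}

#' Flag locations with abnormally directed vectors
#'
#' A location is misdirected when the angle between the patient vector
#' and the atlas mean vector exceeds `angleThreshold` degrees
#' (`arccos` of the cosine similarity). Locations where either vector
#' magnitude is below `floor` are not evaluated — the angle is
#' numerically meaningless there.
#'
#' @param patientVec n x 3 patient vectors.
#' @param meanVec n x 3 atlas mean vectors.
#' @param angleThreshold degrees (default 120).
#' @param floor magnitude floor (0.01 m/s for velocity, 0.01 Pa for
#'   WSS).
#' @return logical vector with `NA` where not evaluable.
#' @export
flagMisdirected <- function(patientVec, meanVec, angleThreshold = 120,
                            floor = 0.01) {
  np <- rowNorms(patientVec)
  na <- rowNorms(meanVec)
  cosang <- rowSums(patientVec * meanVec) / (np * na)
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  out <- ang > angleThreshold
  out[is.na(np) | is.na(na) | np < floor | na < floor] <- NA
  out
}

#' Abnormality map of one patient against the atlas
#'
#' Samples the patient's peak-systolic velocity at the atlas lumen
#' voxels and estimates the patient's WSS at the atlas wall points,
#' then applies [flagElevated()] and [flagMisdirected()] for both
#' quantities. When the patient is not on the shared grid, supply the
#' rigid `registration` mapping atlas space into patient space
#' (atlas-to-patient nearest-neighbor lookup).
#'
#' @param field,seg the patient dataset.
#' @param atlas a [HemoAtlas-class].
#' @param registration optional [RigidTransform-class] mapping atlas
#'   world coordinates (mm) to patient world coordinates.
#' @param mu viscosity for the patient WSS estimate.
#' @param angleThreshold,ciFactor thresholds, see the flag functions.
#' @param frame optional patient timeframe; default peak systole.
#' @return An [AbnormalityMap-class].
#' @export
abnormalityMap <- function(field, seg, atlas, registration = NULL,
                           mu = 3.2e-3, angleThreshold = 120,
                           ciFactor = 1.96, frame = NULL) {
  stopifnot(is(atlas, "HemoAtlas"))
  if (is.null(frame)) frame <- peakSystoleIndex(field, seg)
  dP <- dim(seg@mask)
  nvol <- prod(dP)
  aPts <- indexToWorld(arrayInd(atlas@voxelIdx, dim(atlas@seg@mask)) - 1,
                       atlas@seg@spacing)  # m
  pPts <- if (is.null(registration)) aPts else
    applyRigid(registration, aPts * 1000) / 1000
  idx <- round(worldToIndex(pPts, seg@spacing)) + 1
  inG <- idx[, 1] >= 1 & idx[, 1] <= dP[1] & idx[, 2] >= 1 &
    idx[, 2] <= dP[2] & idx[, 3] >= 1 & idx[, 3] <= dP[3]
  lin <- rep(NA_integer_, nrow(idx))
  lin[inG] <- idx[inG, 1] + dP[1] * (idx[inG, 2] - 1) +
    dP[1] * dP[2] * (idx[inG, 3] - 1)
  covered <- inG & !is.na(lin) & seg@mask[ifelse(is.na(lin), 1L, lin)]
  off <- (frame - 1L) * nvol
  pv <- matrix(NA_real_, nrow(idx), 3)
  pv[covered, ] <- cbind(field@vx[lin[covered] + off],
                         field@vy[lin[covered] + off],
                         field@vz[lin[covered] + off])

  mesh <- atlas@mesh
  if (!is.null(registration)) {
    R <- .eulerMatrix(registration@rotation)
    mesh@points <- applyRigid(registration, mesh@points * 1000) / 1000
    mesh@normals <- mesh@normals %*% t(R)
  }
  pw <- estimateWSS(field, mesh, frame, mu = mu)

  new("AbnormalityMap",
      elevatedVelocity = flagElevated(rowNorms(pv), atlas@velMagMean,
                                      atlas@velMagSD, ciFactor),
      elevatedWSS = flagElevated(wssMagnitudes(pw), atlas@wssMagMean,
                                 atlas@wssMagSD, ciFactor),
      misdirectedVelocity = flagMisdirected(pv, atlas@velMean,
                                            angleThreshold, floor = 0.01),
      misdirectedWSS = flagMisdirected(wssVectors(pw), atlas@wssMean,
                                       angleThreshold, floor = 0.01),
      angleThreshold = angleThreshold, ciFactor = ciFactor)
}

#' Per-region abnormality flags for one patient
#'
#' A patient is abnormal in a region when at least one location of that
#' region is flagged; the region flag is the OR over its locations.
#' Regions without any evaluable location are `NA`.
#'
#' @param map an [AbnormalityMap-class].
#' @param atlas the [HemoAtlas-class] the map was computed against.
#' @return data.frame with columns `metric`, `region`, `flag`.
#' @export
patientRegionFlags <- function(map, atlas) {
  stopifnot(is(map, "AbnormalityMap"), is(atlas, "HemoAtlas"))
  regions <- REGION_LEVELS[REGION_LEVELS != "none"]
  metrics <- list(elevated_velocity = list(map@elevatedVelocity,
                                           atlas@voxelRegion),
                  elevated_wss = list(map@elevatedWSS, atlas@mesh@region),
                  misdirected_velocity = list(map@misdirectedVelocity,
                                              atlas@voxelRegion),
                  misdirected_wss = list(map@misdirectedWSS,
                                         atlas@mesh@region))
  out <- expand.grid(metric = names(metrics), region = regions,
                     stringsAsFactors = FALSE)
  out$flag <- NA
  for (i in seq_len(nrow(out))) {
    mm <- metrics[[out$metric[i]]]
    sel <- mm[[2]] == out$region[i] & !is.na(mm[[1]])
    if (any(sel)) out$flag[i] <- any(mm[[1]][sel])
  }
  out
}

#' Incidence map across a patient cohort
#'
#' Per atlas location, the percentage of patients flagged abnormal,
#' with the denominator restricted to the patients whose map covers the
#' location; locations covered by no patient are `NA`.
#'
#' @param maps list of [AbnormalityMap-class] objects on one shared
#'   atlas geometry.
#' @return list of four numeric vectors (percent, 0-100):
#'   `elevated_velocity`, `elevated_wss`, `misdirected_velocity`,
#'   `misdirected_wss`.
#' @export
incidenceMap <- function(maps) {
  stopifnot(length(maps) >= 1L)
  slotNames <- c(elevated_velocity = "elevatedVelocity",
                 elevated_wss = "elevatedWSS",
                 misdirected_velocity = "misdirectedVelocity",
                 misdirected_wss = "misdirectedWSS")
  out <- lapply(slotNames, function(sn) {
    m <- sapply(maps, function(x) slot(x, sn))
    cnt <- rowSums(!is.na(m))
    pct <- 100 * rowSums(m, na.rm = TRUE) / cnt
    pct[cnt == 0L] <- NA_real_
    pct
  })
  names(out) <- names(slotNames)
  out
}
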