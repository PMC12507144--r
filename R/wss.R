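#' Estimate wall shear stress at the wall
#'
#' Implements the near-wall velocity-gradient estimator: at each wall
#' point with local lumen diameter `D`, velocity is sampled by
#' trilinear interpolation at distances `D/4` and `D/2` along the
#' inward normal; together with the no-slip condition `v = 0` enforced
#' at the wall these are three points spanning half the lumen diameter.
#' Each sample is projected onto the wall-tangent plane (the normal
#' component is removed), a quadratic through the three points is the
#' unique interpolant per tangential component, and
#' `WSS = mu * dv/ds` at the wall. The quadratic derivative at zero is
#' `(4 v1 - v2) / (2 s1)` with `s1 = D/4`, exact for linear and
#' parabolic profiles. Points with an invalid diameter, with samples
#' outside the grid, or whose diameter ray runs along the lumen rather
#' than across it (diameter above `maxDiameterFactor` times the median
#' valid diameter — e.g. at clipped vessel ends) are marked missing
#' (`NA`), never 0.
#'
#' @param field a [VelocityField-class].
#' @param mesh a [WallMesh-class] with normals and diameters.
#' @param frame timeframe index (1-based), typically
#'   [peakSystoleIndex()].
#' @param mu dynamic viscosity in Pa s; 3.2e-3 is the conventional
#'   blood value.
#' @param maxDiameterFactor invalidate points whose local diameter
#'   exceeds this multiple of the median valid diameter (`Inf`
#'   disables the guard).
#' @return A [WSSField-class].
#' @export
estimateWSS <- function(field, mesh, frame, mu = 3.2e-3,
                        maxDiameterFactor = 3) {
  stopifnot(is(field, "VelocityField"), is(mesh, "WallMesh"))
  if (mu <= 0) stop("mu must be positive")
  nt <- dim(field@vx)[4L]
  if (frame < 1L || frame > nt) stop("frame out of range")
  n <- nrow(mesh@points)
  vec <- matrix(NA_real_, n, 3)

  D <- mesh@diameters
  ok <- !is.na(D)
  if (is.finite(maxDiameterFactor) && any(ok)) {
    medD <- median(D[ok])
    ok <- ok & D <= maxDiameterFactor * medD
  }
  if (any(ok)) {
    sp <- field@spacing
    vx3 <- field@vx[, , , frame]
    vy3 <- field@vy[, , , frame]
    vz3 <- field@vz[, , , frame]
    io <- which(ok)
    s1 <- D[io] / 4
    sampleAt <- function(dist) {
      p <- mesh@points[io, , drop = FALSE] +
        dist * mesh@normals[io, , drop = FALSE]
      idx <- worldToIndex(p, sp)
      cbind(trilinear(vx3, idx), trilinear(vy3, idx), trilinear(vz3, idx))
    }
    v1 <- sampleAt(s1)
    v2 <- sampleAt(2 * s1)
    good <- !is.na(v1[, 1]) & !is.na(v2[, 1])
    nrm <- mesh@normals[io, , drop = FALSE]
    proj <- function(v) v - rowSums(v * nrm) * nrm
    v1t <- proj(v1); v2t <- proj(v2)
    dvds <- (4 * v1t - v2t) / (2 * s1)
    dvds[!good, ] <- NA_real_
    vec[io, ] <- mu * dvds
  }
  mag <- rowNorms(vec)
  new("WSSField", vectors = vec, magnitude = mag,
      frame = as.integer(frame), mu = mu)
}

#' Per-region mean velocity and WSS at peak systole
#'
#' WSS is averaged over the valid wall points of each region; velocity
#' magnitude over the lumen voxels assigned to each region (same
#' longitudinal-class and curvature-side rule as the wall points,
#' applied to the voxel centers) at the given frame. Regions without a
#' single valid location yield `NA` with a warning.
#'
#' @param field a [VelocityField-class].
#' @param wss a [WSSField-class] on `mesh`.
#' @param mesh a [WallMesh-class] with regions assigned
#'   (see [partitionRegions()]).
#' @param seg the [Segmentation-class].
#' @param centerline the [Centerline-class] used for the partition.
#' @param frame timeframe index (1-based).
#' @return data.frame with columns `region`, `velocity_mps`, `wss_pa`,
#'   `n_voxels`, `n_wall_points`.
#' @export
regionMeans <- function(field, wss, mesh, seg, centerline, frame) {
  stopifnot(is(wss, "WSSField"), is(mesh, "WallMesh"))
  if (length(mesh@landmarks) != 3L)
    stop("mesh has no regions; run partitionRegions() first")
  regions <- REGION_LEVELS[REGION_LEVELS != "none"]

  idx <- which(seg@mask)
  vpts <- indexToWorld(arrayInd(idx, dim(seg@mask)) - 1, seg@spacing)
  splitDir <- if (length(mesh@splitDir)) mesh@splitDir else NULL
  vreg <- .assignRegions(vpts, centerline, mesh@landmarks, splitDir)$region
  nvol <- prod(dim(seg@mask))
  off <- (frame - 1L) * nvol
  speed <- sqrt(field@vx[idx + off]^2 + field@vy[idx + off]^2 +
                  field@vz[idx + off]^2)

  out <- data.frame(region = regions, velocity_mps = NA_real_,
                    wss_pa = NA_real_, n_voxels = 0L, n_wall_points = 0L)
  for (i in seq_along(regions)) {
    rv <- vreg == regions[i]
    rw <- mesh@region == regions[i] & !is.na(wss@magnitude)
    out$n_voxels[i] <- sum(rv)
    out$n_wall_points[i] <- sum(rw)
    if (any(rv)) out$velocity_mps[i] <- mean(speed[rv])
    if (any(rw)) out$wss_pa[i] <- mean(wss@magnitude[rw])
  }
  empty <- out$n_voxels == 0L & out$n_wall_points == 0L
  if (any(empty))
    warning("region(s) without any valid location: ",
            paste(out$region[empty], collapse = ", "))
  out
}
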