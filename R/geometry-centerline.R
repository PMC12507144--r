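#' Extract a vessel centerline from a tubular segmentation
#'
#' The centerline is traced as the ridge of the interior distance
#' transform: lumen voxels form a 26-connected graph whose edge weights
#' penalize proximity to the wall (`length / inradius`), the two tube
#' ends are found as the mutually farthest voxels (double sweep of
#' geodesic distances), and the minimal-cost path between them rides
#' the ridge. The path is smoothed with a 3-sample moving average and
#' resampled at regular arc-length intervals. Masks that are not simple
#' tubes (side branches, slabs) are rejected: every lumen voxel must
#' lie within the tube radius of the traced path.
#'
#' @param seg a [Segmentation-class] of a (pre-trimmed) tubular vessel.
#' @param inlet optional world coordinate (m) of the inlet; the
#'   centerline is oriented to start at the end nearest to it.
#' @param sampleSpacing resampling interval in m (default 2 mm).
#' @param smoothWindow moving-average window in samples (default 3).
#' @return A [Centerline-class] (points, cumulative arc length, unit
#'   tangents, and the local lumen inradius).
#' @export
extractCenterline <- function(seg, inlet = NULL, sampleSpacing = 0.002,
                              smoothWindow = 3L) {
  stopifnot(is(seg, "Segmentation"))
  mask <- seg@mask
  d <- dim(mask)
  sp <- seg@spacing
  dtIn <- distanceTo(!mask, sp)  # mm to background; > 0 inside lumen

  lin <- which(mask)
  nvox <- length(lin)
  id <- integer(length(mask))
  id[lin] <- seq_len(nvox)
  coord <- arrayInd(lin, d)

  # 26-neighborhood edges (13 positive offsets)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[(offs[, 1] + 3 * offs[, 2] + 9 * offs[, 3]) > 0, , drop = FALSE]
  from <- integer(0); to <- integer(0); elen <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    nbc <- sweep(coord, 2L, o, "+")
    ok <- nbc[, 1] >= 1 & nbc[, 1] <= d[1] & nbc[, 2] >= 1 &
      nbc[, 2] <= d[2] & nbc[, 3] >= 1 & nbc[, 3] <= d[3]
    nlin <- nbc[ok, 1] + d[1] * (nbc[ok, 2] - 1) + d[1] * d[2] * (nbc[ok, 3] - 1)
    hit <- mask[nlin]
    from <- c(from, id[lin[ok]][hit])
    to <- c(to, id[nlin[hit]])
    elen <- c(elen, rep(sqrt(sum((o * sp)^2)), sum(hit)))
  }
  g <- igraph::make_graph(rbind(from, to), n = nvox, directed = FALSE)

  # tube ends: double sweep of geodesic (length-weighted) distances,
  # then snap each end to the most interior voxel of its end region so
  # the path starts on the lumen axis rather than at a rim corner
  d1 <- igraph::distances(g, v = 1, weights = elen)[1, ]
  if (any(!is.finite(d1)))
    stop("segmentation mask is not connected; pre-trim the mask")
  e1 <- which.max(d1)
  d2 <- igraph::distances(g, v = e1, weights = elen)[1, ]
  e2 <- which.max(d2)
  inr <- dtIn[lin]
  snapEnd <- function(e) {
    de <- igraph::distances(g, v = e, weights = elen)[1, ]
    cand <- which(de <= 2 * max(inr))
    cand[which.max(inr[cand])]
  }
  e1 <- snapEnd(e1)
  e2 <- snapEnd(e2)

  # ridge weights: penalize wall proximity
  wRidge <- elen * (1 / inr[from] + 1 / inr[to]) / 2
  vp <- igraph::shortest_paths(g, from = e1, to = e2, weights = wRidge,
                               output = "vpath")$vpath[[1]]
  path <- as.integer(vp)
  if (length(path) < 3L) stop("mask is too small to carry a centerline")
  pc <- sweep(coord[path, , drop = FALSE] - 1, 2L, sp, "*")  # mm

  # tubularity / branch check: every lumen voxel must be near the path
  ptsAll <- sweep(coord - 1, 2L, sp, "*")
  devMax <- 0
  chunk <- 4000L
  for (i0 in seq(1L, nvox, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nvox)
    dd <- outer(rowSums(ptsAll[i0:i1, , drop = FALSE]^2), rowSums(pc^2), "+") -
      2 * ptsAll[i0:i1, , drop = FALSE] %*% t(pc)
    devMax <- max(devMax, sqrt(max(pmax(apply(dd, 1, min), 0))))
  }
  if (devMax > 1.5 * max(inr) + 2 * max(sp))
    stop("segmentation is not a simple tube (branching skeleton or ",
         "non-tubular mask); provide a pre-trimmed mask")

  # smooth (moving average) and resample at regular arc length
  sm <- function(v) {
    k <- smoothWindow
    if (k <= 1L || length(v) < k) return(v)
    f <- stats::filter(v, rep(1 / k, k), sides = 2)
    out <- as.numeric(f)
    out[is.na(out)] <- v[is.na(out)]  # keep the ends
    out
  }
  resampleArc <- function(pcs, ds) {
    seglen <- sqrt(rowSums(diff(pcs)^2))
    cum <- c(0, cumsum(seglen))
    keep <- c(TRUE, seglen > 1e-9)
    pcs <- pcs[keep, , drop = FALSE]
    cum <- cum[keep]
    total <- max(cum)
    sOut <- seq(0, total, by = ds)
    if (sOut[length(sOut)] < total - 1e-9) sOut <- c(sOut, total)
    cbind(approx(cum, pcs[, 1], xout = sOut)$y,
          approx(cum, pcs[, 2], xout = sOut)$y,
          approx(cum, pcs[, 3], xout = sOut)$y)
  }
  res <- resampleArc(apply(pc, 2L, sm), sampleSpacing * 1000)
  # second smoothing pass on the regular samples: removes the residual
  # voxel-scale zigzag that otherwise contaminates tangents and
  # curvature
  if (nrow(res) >= 5L) {
    k5 <- rep(1 / 5, 5)
    sm5 <- function(v) {
      f <- as.numeric(stats::filter(v, k5, sides = 2))
      f[is.na(f)] <- v[is.na(f)]
      f
    }
    res <- resampleArc(apply(res, 2L, sm5), sampleSpacing * 1000)
  }

  # sub-voxel refinement: move each sample to the inradius^2-weighted
  # centroid of the lumen voxels in its orthogonal slab, undoing the
  # voxel-center quantization of the traced path (which otherwise sits
  # up to half a voxel off the true axis, consistently to one side)
  nres0 <- nrow(res)
  st0 <- min(2L, nres0 - 1L)
  tg0 <- res[pmin(seq_len(nres0) + st0, nres0), , drop = FALSE] -
    res[pmax(seq_len(nres0) - st0, 1L), , drop = FALSE]
  tg0 <- tg0 / rowNorms(tg0)
  w2 <- inr^2
  for (i in seq_len(nres0)) {
    rel <- sweep(ptsAll, 2L, res[i, ])
    along <- rel %*% tg0[i, ]
    sel <- abs(along) <= max(sp) &
      rowSums(rel^2) - along^2 <= (2.5 * max(inr))^2
    if (sum(sel) >= 4L)
      res[i, ] <- colSums(ptsAll[sel, , drop = FALSE] * w2[sel]) /
        sum(w2[sel])
  }
  res <- resampleArc(res, sampleSpacing * 1000)

  # orient from the inlet
  if (!is.null(inlet)) {
    inletMM <- inlet * 1000
    dStart <- sum((res[1, ] - inletMM)^2)
    dEnd <- sum((res[nrow(res), ] - inletMM)^2)
    if (dEnd < dStart) {
      res <- res[nrow(res):1, , drop = FALSE]
    }
  }
  arc <- c(0, cumsum(sqrt(rowSums(diff(res)^2)))) / 1000  # m

  # tangents by wide central differences (+/- 3 samples, ~6 mm) so the
  # residual voxel-scale zigzag of the traced path does not leak into
  # the tangent field
  nres <- nrow(res)
  st <- min(3L, nres - 1L)
  hi <- pmin(seq_len(nres) + st, nres)
  lo <- pmax(seq_len(nres) - st, 1L)
  tang <- (res[hi, , drop = FALSE] - res[lo, , drop = FALSE])
  tang <- tang / rowNorms(tang)

  rad <- trilinear(dtIn, sweep(res, 2L, sp, "/")) / 1000  # m
  rad[is.na(rad) | rad < min(sp) / 2000] <- min(sp) / 2000
  new("Centerline", points = res / 1000, arclength = arc,
      tangents = tang, radius = rad)
}

# Region assignment shared by wall points and lumen voxels: the
# longitudinal class comes from the nearest centerline sample's arc
# length vs the three landmarks; the inner/outer side from the sign of
# (p - c) . d, where d is the local curvature normal (pointing toward
# the center of curvature = inner) or, where curvature is negligible
# (< 1 per meter), the direction from the sample toward the center of
# curvature at the arch apex; for entirely straight vessels an
# explicit split direction is required.
.assignRegions <- function(pts, centerline, landmarks, splitDir = NULL) {
  cp <- centerline@points
  nc <- nrow(cp)
  n <- nrow(pts)
  nearest <- integer(n)
  chunk <- 4000L
  cp2 <- rowSums(cp^2)
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    blk <- pts[i0:i1, , drop = FALSE]
    dd <- outer(rowSums(blk^2), cp2, "+") - 2 * blk %*% t(cp)
    nearest[i0:i1] <- max.col(-dd, ties.method = "first")
  }
  s <- centerline@arclength[nearest]

  if (any(landmarks < 0) || any(landmarks > max(centerline@arclength)))
    stop("landmarks fall outside the centerline arc-length range")

  # curvature vectors per centerline sample, over a vessel-scale
  # stencil (~10 mm) so voxel-scale tangent noise does not masquerade
  # as anatomy
  tg <- centerline@tangents
  st <- max(1L, min(5L, (nc - 1L) %/% 2L))
  hi <- pmin(seq_len(nc) + st, nc)
  lo <- pmax(seq_len(nc) - st, 1L)
  ds <- centerline@arclength[hi] - centerline@arclength[lo]
  kvec <- (tg[hi, , drop = FALSE] - tg[lo, , drop = FALSE]) / ds
  kmag <- rowNorms(kvec)

  dir <- matrix(NA_real_, nc, 3)
  # local curvature normals are trusted only where curvature is strong
  # both absolutely (1/m) and relative to the arch apex; elsewhere the
  # split direction points from the sample toward the apex's center of
  # curvature (the same direction in the curved segment, but immune to
  # the curvature noise of a voxel-traced centerline on straight
  # segments)
  curved <- kmag >= pmax(1, 0.5 * max(kmag))
  if (max(kmag) >= 1) {
    dir[curved, ] <- kvec[curved, , drop = FALSE] / kmag[curved]
    apex <- which.max(kmag)
    qc <- cp[apex, ] + kvec[apex, ] / kmag[apex]^2  # center of curvature
    if (any(!curved)) {
      dvec <- sweep(-cp[!curved, , drop = FALSE], 2L, qc, "+")
      tpar <- rowSums(dvec * tg[!curved, , drop = FALSE])
      dvec <- dvec - tpar * tg[!curved, , drop = FALSE]
      nn <- rowNorms(dvec)
      flat <- nn < 1e-9
      dvec <- dvec / ifelse(nn > 0, nn, 1)
      if (any(flat)) dvec[flat, ] <- matrix(dir[apex, ], sum(flat), 3,
                                            byrow = TRUE)
      dir[!curved, ] <- dvec
    }
  } else {
    if (is.null(splitDir))
      stop("vessel has no curved segment; supply splitDir to define ",
           "the inner/outer split")
    sd3 <- splitDir / sqrt(sum(splitDir^2))
    for (i in seq_len(nc)) {
      v <- sd3 - sum(sd3 * tg[i, ]) * tg[i, ]
      nv <- sqrt(sum(v^2))
      if (nv < 1e-9) stop("splitDir is parallel to the vessel axis")
      dir[i, ] <- v / nv
    }
  }

  rel <- pts - cp[nearest, , drop = FALSE]
  sideIn <- rowSums(rel * dir[nearest, , drop = FALSE]) > 0
  long <- ifelse(s < landmarks[1], "AAo",
          ifelse(s < landmarks[2], "arch",
          ifelse(s <= landmarks[3], "DAo", NA_character_)))
  out <- ifelse(is.na(long), "none",
                paste0(ifelse(sideIn, "inner_", "outer_"), long))
  list(region = out, arclength = s, nearest = nearest)
}

#' Partition the wall into the six anatomical regions
#'
#' Assigns each wall point to the inner or outer ascending aorta
#' (`*_AAo`, before the first landmark), arch (between the first two)
#' or descending aorta (`*_DAo`, up to the third landmark); points
#' beyond the last landmark are labelled `"none"`. The longitudinal
#' class follows the arc length of the nearest centerline sample; the
#' inner/outer side follows the local curvature normal (pointing toward
#' the center of curvature defines "inner"), with low-curvature samples
#' falling back to the direction toward the arch apex's center of
#' curvature. The paper-anatomical landmarks (brachiocephalic trunk,
#' left subclavian artery, diaphragm) are configuration inputs, not
#' detected.
#'
#' @param mesh a [WallMesh-class].
#' @param centerline a [Centerline-class].
#' @param landmarks numeric(3) strictly increasing arc lengths (m).
#' @param splitDir optional length-3 vector defining the inner side for
#'   entirely straight vessels (inner = positive half-space).
#' @return The mesh with `region`, `arclength`, `landmarks` and
#'   `splitDir` filled.
#' @export
partitionRegions <- function(mesh, centerline, landmarks, splitDir = NULL) {
  stopifnot(is(mesh, "WallMesh"), is(centerline, "Centerline"))
  if (length(landmarks) != 3L || any(diff(landmarks) <= 0))
    stop("landmarks must be 3 strictly increasing arc lengths (m)")
  asg <- .assignRegions(mesh@points, centerline, landmarks, splitDir)
  mesh@region <- asg$region
  mesh@arclength <- asg$arclength
  mesh@landmarks <- landmarks
  mesh@splitDir <- if (is.null(splitDir)) numeric(0) else splitDir
  validObject(mesh)
  mesh
}
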