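# Internal grid / array helpers. World coordinates of voxel centers are
# (index - 1) * spacing, with spacing in mm; geometry objects store
# coordinates in meters, so conversions happen at these helpers only.

# Euclidean distance (same unit as spacing) from every voxel to the
# nearest TRUE voxel.
distanceTo <- function(mask, spacing) {
  d <- dim(mask)
  out <- .edt3_sq(as.logical(mask), as.integer(d), as.numeric(spacing))
  array(sqrt(out), dim = d)
}

# Signed distance to the mask surface: negative inside, positive
# outside, in the unit of `spacing`.
signedDistance <- function(mask, spacing) {
  distanceTo(mask, spacing) - distanceTo(!mask, spacing)
}

# Fractional 0-based voxel index of world points (meters); pts is n x 3.
worldToIndex <- function(pts, spacingMM) {
  sweep(pts * 1000, 2L, spacingMM, "/")
}

indexToWorld <- function(idx0, spacingMM) {
  sweep(idx0, 2L, spacingMM, "*") / 1000
}

# Trilinear interpolation of a 3D array at fractional 0-based indices
# (n x 3). Points outside the grid return NA.
trilinear <- function(arr, idx0) {
  d <- dim(arr)
  n <- nrow(idx0)
  out <- rep(NA_real_, n)
  inside <- idx0[, 1] >= 0 & idx0[, 1] <= d[1] - 1 &
            idx0[, 2] >= 0 & idx0[, 2] <= d[2] - 1 &
            idx0[, 3] >= 0 & idx0[, 3] <= d[3] - 1
  if (!any(inside)) return(out)
  p <- idx0[inside, , drop = FALSE]
  i0 <- pmin(floor(p), rep(d - 2L, each = nrow(p)))
  i0 <- pmax(i0, 0)
  f <- p - i0
  # linear 1-based index of the lower corner
  base <- i0[, 1] + d[1] * (i0[, 2] + d[2] * i0[, 3]) + 1
  sx <- 1L; sy <- d[1]; sz <- d[1] * d[2]
  v000 <- arr[base];            v100 <- arr[base + sx]
  v010 <- arr[base + sy];       v110 <- arr[base + sx + sy]
  v001 <- arr[base + sz];       v101 <- arr[base + sx + sz]
  v011 <- arr[base + sy + sz];  v111 <- arr[base + sx + sy + sz]
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[inside] <- c0 * (1 - fz) + c1 * fz
  out
}

# Central-difference gradient of a 3D array (one-sided at the borders),
# per unit of `spacing`.
gradient3 <- function(arr, spacing) {
  d <- dim(arr)
  g <- vector("list", 3L)
  for (ax in 1:3) {
    n <- d[ax]
    hi <- c(2:n, n)
    lo <- c(1L, 1:(n - 1L))
    denom <- (hi - lo) * spacing[ax]
    gax <- switch(ax,
      (arr[hi, , , drop = FALSE] - arr[lo, , , drop = FALSE]) /
        array(denom, dim = d),
      (arr[, hi, , drop = FALSE] - arr[, lo, , drop = FALSE]) /
        aperm(array(denom, dim = d[c(2, 1, 3)]), c(2, 1, 3)),
      (arr[, , hi, drop = FALSE] - arr[, , lo, drop = FALSE]) /
        aperm(array(denom, dim = d[c(3, 1, 2)]), c(2, 3, 1)))
    g[[ax]] <- gax
  }
  g
}

# Number of 6-connected foreground components (frontier flood fill).
countComponents <- function(mask) {
  d <- dim(mask)
  strides <- c(1L, d[1], d[1] * d[2])
  remaining <- which(mask)
  seen <- logical(length(mask))
  ncomp <- 0L
  # precomputed index coordinates to guard wrap-around at the faces
  coord <- arrayInd(seq_along(mask), d)
  while (length(remaining) > 0L) {
    ncomp <- ncomp + 1L
    frontier <- remaining[1L]
    seen[frontier] <- TRUE
    while (length(frontier) > 0L) {
      nxt <- integer(0)
      for (ax in 1:3) {
        for (dir in c(-1L, 1L)) {
          ok <- if (dir == 1L) coord[frontier, ax] < d[ax]
                else coord[frontier, ax] > 1L
          cand <- frontier[ok] + dir * strides[ax]
          cand <- cand[mask[cand] & !seen[cand]]
          seen[cand] <- TRUE
          nxt <- c(nxt, cand)
        }
      }
      frontier <- unique(nxt)
    }
    remaining <- remaining[!seen[remaining]]
  }
  ncomp
}

# Separable [1 2 1]/4 smoothing of a 3D array (replicated borders).
smooth3 <- function(a) {
  d <- dim(a)
  for (ax in 1:3) {
    n <- d[ax]
    hi <- c(2:n, n); lo <- c(1L, 1:(n - 1L))
    a <- switch(ax,
      0.25 * a[lo, , , drop = FALSE] + 0.5 * a + 0.25 * a[hi, , , drop = FALSE],
      0.25 * a[, lo, , drop = FALSE] + 0.5 * a + 0.25 * a[, hi, , drop = FALSE],
      0.25 * a[, , lo, drop = FALSE] + 0.5 * a + 0.25 * a[, , hi, drop = FALSE])
  }
  a
}

# Round half away from zero (report convention; base round() is
# round-half-even).
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

rowNorms <- function(m) sqrt(rowSums(m^2))

normalizeRows <- function(m) {
  n <- rowNorms(m)
  n[n == 0] <- NA_real_
  m / n
}
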