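# Rotation matrix from Euler angles (radians), applied Rx %*% Ry %*% Rz.
.eulerMatrix <- function(ang) {
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Rx %*% Ry %*% Rz
}

#' Apply a rigid transform to world points
#'
#' @param transform a [RigidTransform-class].
#' @param pts n x 3 matrix of points in mm (moving space).
#' @return n x 3 matrix in fixed space (mm).
#' @export
applyRigid <- function(transform, pts) {
  R <- .eulerMatrix(transform@rotation)
  ctr <- transform@center
  sweep(sweep(pts, 2L, ctr) %*% t(R), 2L, ctr + transform@translation, "+")
}

#' Rigid mask-to-mask registration
#'
#' Registers a moving segmentation to a fixed one with a 6-DOF rigid
#' transform maximizing mask overlap: centroid initialization followed
#' by Nelder-Mead refinement of the three rotations and three
#' translations against a soft (trilinearly interpolated) overlap
#' score. Segmentations, not images, are registered — matching how
#' follow-up aortic geometry is aligned to baseline.
#'
#' @param moving,fixed [Segmentation-class] objects.
#' @param maxit Nelder-Mead iteration budget.
#' @param subsample at most this many moving voxels enter the
#'   objective (deterministic thinning).
#' @return A [RigidTransform-class]; `poor = TRUE` flags a final Dice
#'   below 0.5.
#' @export
rigidRegister <- function(moving, fixed, maxit = 400L, subsample = 4000L) {
  stopifnot(is(moving, "Segmentation"), is(fixed, "Segmentation"))
  spM <- moving@spacing; spF <- fixed@spacing
  mIdx <- which(moving@mask)
  fIdx <- which(fixed@mask)
  mPts <- sweep(arrayInd(mIdx, dim(moving@mask)) - 1, 2L, spM, "*")
  fPts <- sweep(arrayInd(fIdx, dim(fixed@mask)) - 1, 2L, spF, "*")
  ctr <- colMeans(mPts)
  t0 <- colMeans(fPts) - ctr

  keep <- seq(1L, nrow(mPts), by = max(1L, nrow(mPts) %/% subsample))
  mSub <- mPts[keep, , drop = FALSE]
  fMask <- array(as.numeric(fixed@mask), dim = dim(fixed@mask))

  objective <- function(par) {
    R <- .eulerMatrix(par[1:3])
    p <- sweep(sweep(mSub, 2L, ctr) %*% t(R), 2L, ctr + par[4:6], "+")
    v <- trilinear(fMask, sweep(p, 2L, spF, "/"))
    v[is.na(v)] <- 0
    -mean(v)
  }
  fit <- optim(c(0, 0, 0, t0), objective, method = "Nelder-Mead",
               control = list(maxit = maxit,
                              parscale = c(rep(0.05, 3), rep(max(spF), 3)),
                              reltol = 1e-8))
  par <- fit$par

  tr <- new("RigidTransform", rotation = par[1:3], translation = par[4:6],
            center = ctr, dice = NA_real_, poor = FALSE)
  # hard Dice on the full moving set
  p <- applyRigid(tr, mPts)
  idx <- round(sweep(p, 2L, spF, "/")) + 1
  dF <- dim(fixed@mask)
  inG <- idx[, 1] >= 1 & idx[, 1] <= dF[1] & idx[, 2] >= 1 &
    idx[, 2] <= dF[2] & idx[, 3] >= 1 & idx[, 3] <= dF[3]
  hits <- 0L
  if (any(inG)) {
    lin <- idx[inG, 1] + dF[1] * (idx[inG, 2] - 1) +
      dF[1] * dF[2] * (idx[inG, 3] - 1)
    hits <- sum(fixed@mask[lin])
  }
  dice <- 2 * hits / (nrow(mPts) + length(fIdx))
  tr@dice <- dice
  if (dice < 0.5) {
    tr@poor <- TRUE
    warning(sprintf("registration overlap is poor (Dice %.2f)", dice))
  }
  tr
}
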