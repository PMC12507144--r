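#' Default pulsatile flow waveform
#'
#' One cardiac cycle of a normalized flow waveform: a smooth systolic
#' pulse (Gaussian bump peaking at 25% of the cycle, width 8% of the
#' cycle) on a small diastolic baseline, scaled so its maximum is
#' exactly 1. Being smooth and periodic it is well represented by a few
#' Fourier harmonics, which matters for the temporal resampling and the
#' wavelet delay stages.
#'
#' @param nt number of timeframes per cycle.
#' @return numeric(nt) with `max == 1`.
#' @export
defaultWaveform <- function(nt = 30L) {
  phi <- (seq_len(nt) - 1) / nt
  w <- 0.05 + 0.95 * exp(-0.5 * ((phi - 0.25) / 0.08)^2)
  w / max(w)
}

#' Construct a PhantomSpec
#'
#' See [PhantomSpec-class] for the meaning of every parameter. Defaults
#' describe a study-like acquisition: 2.5 mm isotropic voxels, 30
#' timeframes at 32 ms (a 960 ms cycle), peak centerline velocity
#' 1 m/s, PWV 8 m/s and velocity noise 0.05 m/s (SNR 20 relative to the
#' peak velocity). When `landmarks` is `NULL`, the three region
#' boundaries are placed at 30/45/90% of the centerline for a straight
#' tube, and at the two bend junctions plus 5 mm short of the outlet
#' for a U-bend.
#'
#' @param geometry `"straight"` or `"u-bend"`.
#' @param radius lumen radius, mm.
#' @param length straight length (straight) or arm length (U-bend), mm.
#' @param bendRadius centerline bend radius, mm (U-bend).
#' @param vmaxPeak peak centerline velocity, m/s.
#' @param waveform normalized cycle waveform (max 1); its length sets
#'   the number of timeframes.
#' @param pwvTrue ground-truth pulse wave velocity, m/s.
#' @param noiseSD Gaussian velocity noise SD, m/s.
#' @param seed RNG seed (mandatory).
#' @param spacing isotropic voxel spacing, mm.
#' @param dt temporal resolution, ms.
#' @param landmarks arc-length positions (mm) of the three region
#'   boundaries, or `NULL` for geometry-dependent defaults.
#' @param stepAt,stepFactor optional step of the peak velocity: beyond
#'   arc length `stepAt` (mm), `vmaxPeak` is multiplied by `stepFactor`.
#' @param phaseOffset constant offset (m/s) added to the first velocity
#'   component, emulating an uncorrected background phase offset.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(geometry = c("straight", "u-bend"), radius = 10,
                        length = 300, bendRadius = 25, vmaxPeak = 1,
                        waveform = defaultWaveform(30L), pwvTrue = 8,
                        noiseSD = 0.05, seed, spacing = 2.5, dt = 32,
                        landmarks = NULL, stepAt = NA_real_,
                        stepFactor = 1, phaseOffset = 0) {
  geometry <- match.arg(geometry)
  if (missing(seed)) stop("a seed is mandatory for phantom generation")
  total <- if (geometry == "straight") length else
    2 * length + pi * bendRadius
  if (is.null(landmarks)) {
    landmarks <- if (geometry == "straight")
      total * c(0.30, 0.45, 0.90)
    else c(length, length + pi * bendRadius, total - 5)
  }
  new("PhantomSpec", geometry = geometry, radius = radius, length = length,
      bendRadius = bendRadius, vmaxPeak = vmaxPeak, waveform = waveform,
      pwvTrue = pwvTrue, noiseSD = noiseSD, seed = as.integer(seed),
      spacing = spacing, dt = dt, landmarks = landmarks,
      stepAt = stepAt, stepFactor = stepFactor, phaseOffset = phaseOffset)
}

#' Construct a CohortSpec
#'
#' @param n number of subjects.
#' @param template a [PhantomSpec-class] shared by the cohort.
#' @param vmaxSD log-SD of the per-subject peak-velocity multiplier
#'   (default 0.1, i.e. ~10% between-subject velocity variability).
#' @param radiusSD log-SD of the per-subject radius multiplier (default
#'   0: the geometry stays shared exactly, so voxelwise statistics need
#'   no registration).
#' @param seed cohort RNG seed; subject phantoms use
#'   `template seed + subject index`.
#' @return A [CohortSpec-class].
#' @export
cohortSpec <- function(n, template, vmaxSD = 0.1, radiusSD = 0, seed) {
  if (missing(seed)) stop("a seed is mandatory for cohort generation")
  new("CohortSpec", n = as.integer(n), vmaxSD = vmaxSD,
      radiusSD = radiusSD, template = template, seed = as.integer(seed))
}

# Tube-following coordinates of arbitrary world points (mm): the
# distance r to the centerline, the arc length s (mm), the local unit
# tangent, and the primitive (1 inlet arm, 2 bend, 3 outlet arm) the
# point projects to. Shared by the generator and the ground-truth side
# labelling so both use the same geometry.
.tubeCoords <- function(spec, pts, layout = NULL) {
  g <- if (is.null(layout)) .phantomLayout(spec) else layout
  n <- nrow(pts)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  if (spec@geometry == "straight") {
    zc <- pmin(pmax(z, g$z0), g$z1)
    r <- sqrt((x - g$cx)^2 + (y - g$cy)^2 + (z - zc)^2)
    s <- zc - g$z0
    tang <- cbind(0, 0, rep(1, n))
    return(list(r = r, s = s, tangent = tang, prim = rep(1L, n),
                inseg = z >= g$z0 & z <= g$z1))
  }
  # U-bend in the x-z plane
  zc <- pmin(pmax(z, g$z0), g$z1)
  d1 <- (x - g$x1)^2 + (y - g$y0)^2 + (z - zc)^2
  s1 <- zc - g$z0
  d3 <- (x - g$x2)^2 + (y - g$y0)^2 + (z - zc)^2
  s3 <- g$La + pi * g$Rc + (g$z1 - zc)
  u <- x - g$bcx; w <- z - g$bcz
  theta <- pmin(pmax(atan2(w, u), 0), pi)
  px <- g$bcx + g$Rc * cos(theta)
  pz <- g$bcz + g$Rc * sin(theta)
  d2 <- (x - px)^2 + (y - g$y0)^2 + (z - pz)^2
  s2 <- g$La + (pi - theta) * g$Rc
  dall <- cbind(d1, d2, d3)
  prim <- max.col(-dall, ties.method = "first")
  r <- sqrt(dall[cbind(seq_len(n), prim)])
  s <- cbind(s1, s2, s3)[cbind(seq_len(n), prim)]
  tang <- matrix(0, n, 3)
  tang[prim == 1L, 3] <- 1
  tang[prim == 3L, 3] <- -1
  ib <- prim == 2L
  tang[ib, 1] <- sin(theta[ib])
  tang[ib, 3] <- -cos(theta[ib])
  # inside the segment the winning primitive projects to (no clamped
  # overhang): arms need z within range, the bend needs w >= 0
  insegArm <- z >= g$z0 & z <= g$z1
  inseg <- ifelse(prim == 2L, w >= 0, insegArm)
  list(r = r, s = s, tangent = tang, prim = prim, inseg = inseg)
}

# Grid layout (mm) for a phantom: grid dims and the analytic centerline
# parameters, with a 2-voxel air margin on every side so the lumen
# never touches the grid boundary. The tube is deliberately placed off
# the voxel lattice (sub-voxel offsets spacing/pi, spacing/e,
# spacing/sqrt(5)) so validation never exploits or suffers the
# degenerate symmetric alignments a grid-commensurate geometry
# produces (e.g. a whole ring of voxel centers exactly on the wall).
.phantomLayout <- function(spec) {
  sp <- spec@spacing; R <- spec@radius
  m <- 2 * sp  # margin, mm
  off <- sp * c(1 / pi, exp(-1), 5^-0.5)
  if (spec@geometry == "straight") {
    nx <- ceiling((2 * R + 2 * m) / sp) + 2L
    nz <- ceiling((spec@length + 2 * m) / sp) + 2L
    return(list(nx = nx, ny = nx, nz = nz,
                cx = m + R + off[1], cy = m + R + off[2],
                z0 = m + off[3], z1 = m + off[3] + spec@length,
                total = spec@length))
  }
  Rc <- spec@bendRadius; La <- spec@length
  nx <- ceiling((2 * Rc + 2 * R + 2 * m) / sp) + 2L
  ny <- ceiling((2 * R + 2 * m) / sp) + 2L
  nz <- ceiling((La + Rc + R + 2 * m) / sp) + 2L
  x1 <- m + R + off[1]
  list(nx = nx, ny = ny, nz = nz, y0 = m + R + off[2],
       x1 = x1, x2 = x1 + 2 * Rc, bcx = x1 + Rc, bcz = m + off[3] + La,
       z0 = m + off[3], z1 = m + off[3] + La, La = La, Rc = Rc,
       total = 2 * La + pi * Rc)
}

#' Generate a 4D flow phantom with analytic ground truth
#'
#' Builds a straight or U-bend tube carrying pulsatile laminar
#' (Poiseuille) flow: the axial velocity at distance `r` from the
#' centerline is `vmax * w(t - s/PWV) * (1 - r^2/R^2)`, where `w` is
#' the periodic cycle waveform (linearly interpolated between its
#' samples) and `s` the centerline arc length, so the waveform
#' propagates along the vessel at exactly `pwvTrue` with zero
#' dispersion. Gaussian noise of SD `noiseSD` is added to every
#' velocity component, inside and outside the lumen; the magnitude
#' image is 1 everywhere. All randomness flows from `spec@seed`:
#' identical specs give bit-identical datasets.
#'
#' @param spec a [PhantomSpec-class].
#' @param layout optional grid layout (from another spec) forcing the
#'   phantom onto a shared grid, as [makeCohort()] does; the tube must
#'   still fit inside it.
#' @return `list(field, seg, truth)` where `truth` records the analytic
#'   ground truth: `peakFrame` (1-based), the wall shear rate
#'   `2 vmax(s) / R` (1/s), peak flow rate `Q(s) = pi R^2 vmax(s) / 2`
#'   (m^3/s), the per-arc-length waveform delay `s / PWV` (s), landmark
#'   arc lengths (m), the analytic centerline, and the phantom layout.
#' @export
makePhantom <- function(spec, layout = NULL) {
  stopifnot(is(spec, "PhantomSpec"))
  g <- if (is.null(layout)) .phantomLayout(spec) else layout
  sp <- spec@spacing
  nt <- length(spec@waveform)
  dims <- c(g$nx, g$ny, g$nz)
  nvol <- prod(dims)

  # voxel-center world coordinates (mm)
  xs <- (seq_len(g$nx) - 1) * sp
  ys <- (seq_len(g$ny) - 1) * sp
  zs <- (seq_len(g$nz) - 1) * sp
  pts <- cbind(rep(xs, times = g$ny * g$nz),
               rep(rep(ys, each = g$nx), times = g$nz),
               rep(zs, each = g$nx * g$ny))
  tc <- .tubeCoords(spec, pts, layout = g)
  lumen <- tc$r <= spec@radius & tc$inseg
  if (!any(lumen)) stop("tube does not intersect the grid")
  lum3 <- array(lumen, dim = dims)
  if (any(lum3[c(1, g$nx), , ]) || any(lum3[, c(1, g$ny), ]) ||
      any(lum3[, , c(1, g$nz)]))
    stop("tube is not fully inside the grid")
  idx <- which(lumen)

  set.seed(spec@seed)
  mk <- function() {
    if (spec@noiseSD > 0)
      array(rnorm(nvol * nt, 0, spec@noiseSD), dim = c(dims, nt))
    else array(0, dim = c(dims, nt))
  }
  vx <- mk(); vy <- mk(); vz <- mk()
  if (spec@phaseOffset != 0) vx <- vx + spec@phaseOffset

  sMM <- tc$s[idx]
  vmaxS <- rep(spec@vmaxPeak, length(idx))
  if (!is.na(spec@stepAt)) vmaxS[sMM > spec@stepAt] <- spec@vmaxPeak * spec@stepFactor
  profile <- 1 - (tc$r[idx] / spec@radius)^2
  tang <- tc$tangent[idx, , drop = FALSE]
  Tcyc <- nt * spec@dt / 1000
  wv <- spec@waveform
  interpW <- function(tau) {
    phi <- (tau / Tcyc) %% 1
    xw <- phi * nt
    i0 <- floor(xw)
    fr <- xw - i0
    wv[(i0 %% nt) + 1] * (1 - fr) + wv[((i0 + 1) %% nt) + 1] * fr
  }
  meanSpeed <- numeric(nt)
  for (f in seq_len(nt)) {
    tf <- (f - 1) * spec@dt / 1000
    wval <- interpW(tf - (sMM / 1000) / spec@pwvTrue)
    speed <- vmaxS * wval * profile
    off <- (f - 1L) * nvol
    vx[idx + off] <- vx[idx + off] + speed * tang[, 1]
    vy[idx + off] <- vy[idx + off] + speed * tang[, 2]
    vz[idx + off] <- vz[idx + off] + speed * tang[, 3]
    meanSpeed[f] <- mean(abs(speed))
  }

  field <- VelocityField(vx, vy, vz, spacing = rep(sp, 3), dt = spec@dt,
                         venc = 2)
  seg <- Segmentation(array(lumen, dim = dims), spacing = rep(sp, 3),
                      checkConnected = FALSE)

  sFine <- seq(0, g$total, by = min(1, sp / 2))
  Rm <- spec@radius / 1000
  vmaxFine <- rep(spec@vmaxPeak, length(sFine))
  if (!is.na(spec@stepAt))
    vmaxFine[sFine > spec@stepAt] <- spec@vmaxPeak * spec@stepFactor
  truth <- list(
    peakFrame = which.max(meanSpeed),
    wallShearRate = 2 * vmaxFine / Rm,   # peak, per arc-length sample
    flowRatePeak = 0.5 * pi * Rm^2 * vmaxFine,  # m^3/s at the waveform peak
    delay = data.frame(arclength_m = sFine / 1000,
                       delay_s = (sFine / 1000) / spec@pwvTrue),
    arclengthFine = sFine / 1000,
    centerline = .makePhantomTruthCenterline(spec, g, sFine),
    landmarks = spec@landmarks / 1000,
    totalLength = g$total / 1000,
    radius = Rm,
    vmaxPeak = spec@vmaxPeak,
    pwvTrue = spec@pwvTrue,
    layout = g,
    spec = spec)
  list(field = field, seg = seg, truth = truth)
}

# Analytic centerline point (mm) at arc length sMM for a layout g.
.tubePoint <- function(spec, g, sMM) {
  if (spec@geometry == "straight")
    return(cbind(g$cx, g$cy, g$z0 + sMM))
  out <- matrix(NA_real_, length(sMM), 3)
  a1 <- sMM <= g$La
  a2 <- sMM > g$La & sMM <= g$La + pi * g$Rc
  a3 <- sMM > g$La + pi * g$Rc
  out[a1, ] <- cbind(g$x1, g$y0, g$z0 + sMM[a1])
  th <- pi - (sMM[a2] - g$La) / g$Rc
  out[a2, ] <- cbind(g$bcx + g$Rc * cos(th), g$y0, g$bcz + g$Rc * sin(th))
  out[a3, ] <- cbind(g$x2, g$y0, g$z1 - (sMM[a3] - g$La - pi * g$Rc))
  out
}

.makePhantomTruthCenterline <- function(spec, g, sFine) {
  pts <- .tubePoint(spec, g, sFine)
  data.frame(arclength_m = sFine / 1000, x = pts[, 1] / 1000,
             y = pts[, 2] / 1000, z = pts[, 3] / 1000)
}

#' Ground-truth inner/outer side of wall points of a U-bend phantom
#'
#' The inner wall is the side facing the bend center: within the bend,
#' points whose in-plane distance to the bend center is below the bend
#' radius; along the straight arms, the side toward the other arm.
#'
#' @param truth the ground-truth list of [makePhantom()].
#' @param pts n x 3 matrix of world coordinates in meters.
#' @return character(n), `"inner"` or `"outer"`.
#' @export
phantomTrueSide <- function(truth, pts) {
  spec <- truth$spec
  if (spec@geometry != "u-bend")
    stop("ground-truth sides are defined for u-bend phantoms only")
  g <- truth$layout
  mm <- pts * 1000
  tc <- .tubeCoords(spec, mm, layout = g)
  side <- character(nrow(mm))
  a1 <- tc$prim == 1L; a2 <- tc$prim == 2L; a3 <- tc$prim == 3L
  side[a1] <- ifelse(mm[a1, 1] > g$x1, "inner", "outer")
  rho <- sqrt((mm[, 1] - g$bcx)^2 + (mm[, 3] - g$bcz)^2)
  side[a2] <- ifelse(rho[a2] < g$Rc, "inner", "outer")
  side[a3] <- ifelse(mm[a3, 1] < g$x2, "inner", "outer")
  side
}

#' Generate a cohort of phantom subjects on a shared grid
#'
#' Subject `i` uses `vmaxPeak` and `radius` multiplied by log-normal
#' perturbations `exp(N(0, sd^2))` drawn from the cohort seed, and a
#' phantom seed of `template seed + i`, so the whole cohort is
#' reproducible from the two seeds in the spec.
#'
#' @param cspec a [CohortSpec-class].
#' @return List of `n` phantom datasets (each a `list(field, seg,
#'   truth)`), with the multipliers attached as attributes
#'   `vmaxMultipliers` and `radiusMultipliers`.
#' @export
makeCohort <- function(cspec) {
  stopifnot(is(cspec, "CohortSpec"))
  set.seed(cspec@seed)
  vm <- exp(rnorm(cspec@n, 0, cspec@vmaxSD))
  rm <- exp(rnorm(cspec@n, 0, cspec@radiusSD))
  tmpl <- cspec@template
  layout <- .phantomLayout(tmpl)  # shared template grid
  out <- vector("list", cspec@n)
  for (i in seq_len(cspec@n)) {
    si <- tmpl
    si@vmaxPeak <- tmpl@vmaxPeak * vm[i]
    si@radius <- tmpl@radius * rm[i]
    si@seed <- tmpl@seed + i
    out[[i]] <- makePhantom(si, layout = layout)
  }
  attr(out, "vmaxMultipliers") <- vm
  attr(out, "radiusMultipliers") <- rm
  out
}
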