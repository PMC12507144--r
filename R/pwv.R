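# Fourier (periodic) resampling of the columns of a matrix whose rows
# sample one full cycle uniformly. Exact for band-limited periodic
# signals; preserves the cycle mean to machine precision.
.fourierResample <- function(x, ntNew) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (ntNew == n) return(x)
  X <- mvfft(x)
  Y <- matrix(0 + 0i, ntNew, ncol(x))
  kmax <- min((n - 1) %/% 2, (ntNew - 1) %/% 2)
  Y[1, ] <- X[1, ]
  if (kmax >= 1) {
    ks <- seq_len(kmax)
    Y[ks + 1, ] <- X[ks + 1, , drop = FALSE]
    Y[ntNew - ks + 1, ] <- X[n - ks + 1, , drop = FALSE]
  }
  if (n %% 2 == 0 && ntNew > n) {
    # split the Nyquist bin of the coarser grid
    ny <- X[n / 2 + 1, ] / 2
    Y[n / 2 + 1, ] <- ny
    Y[ntNew - n / 2 + 1, ] <- ny
  } else if (ntNew %% 2 == 0 && ntNew < n) {
    # fold onto the Nyquist bin of the finer grid
    Y[ntNew / 2 + 1, ] <- Re(X[ntNew / 2 + 1, ] + X[n - ntNew / 2 + 1, ])
  }
  Re(mvfft(Y, inverse = TRUE)) / n
}

#' Resample a velocity field to a fixed temporal resolution
#'
#' Periodic (cardiac-cycle) Fourier interpolation of all arrays onto a
#' uniform grid of `round(cycle / dtTarget)` frames; the effective
#' frame spacing is `cycle / nNew`, equal to `dtTarget` whenever the
#' target divides the cycle. Fourier interpolation preserves the
#' harmonics the wavelet delay stage uses and keeps the cycle mean to
#' machine precision.
#'
#' @param field a [VelocityField-class] with at least 4 timeframes.
#' @param dtTarget target temporal resolution in ms (default 20).
#' @return A resampled [VelocityField-class].
#' @export
resampleTemporal <- function(field, dtTarget = 20) {
  stopifnot(is(field, "VelocityField"))
  if (dtTarget <= 0) stop("dtTarget must be positive")
  d <- dim(field@vx)
  nt <- d[4L]
  if (nt < 4L) stop("temporal resampling needs at least 4 timeframes")
  cycle <- nt * field@dt
  ntNew <- max(4L, as.integer(round(cycle / dtTarget)))
  if (ntNew == nt) return(field)
  dtNew <- cycle / ntNew
  resample4 <- function(a) {
    m <- t(matrix(a, nrow = prod(d[1:3]), ncol = nt))  # time in rows
    array(t(.fourierResample(m, ntNew)), dim = c(d[1:3], ntNew))
  }
  VelocityField(resample4(field@vx), resample4(field@vy),
                resample4(field@vz), pmax(resample4(field@mag), 0),
                spacing = field@spacing, dt = dtNew, venc = field@venc)
}

#' Flow waveforms at cross-sections along the centerline
#'
#' At centerline samples spaced `sectionSpacing` apart, the volumetric
#' flow rate through the orthogonal cross-section is integrated per
#' timeframe: lumen voxels within half a voxel of the plane (along the
#' local tangent, and within 2.5 local inradii of the centerline so an
#' adjacent vessel limb cannot leak into the plane) contribute
#' `(v . tangent) * voxelVolume / slabThickness`. Sections with fewer
#' than 4 lumen voxels are dropped, as are sections within `endBuffer`
#' of either end where the cross-section is truncated by the capped
#' tube ends.
#'
#' @param field a [VelocityField-class].
#' @param centerline a [Centerline-class].
#' @param seg the [Segmentation-class].
#' @param sectionSpacing section spacing in m (default 0.010).
#' @param endBuffer arc length (m) excluded at both vessel ends.
#' @return list with `arclength_m` (per section), `flow_mls` (sections
#'   x timeframes matrix, ml/s) and `dt_s`.
#' @export
flowWaveforms <- function(field, centerline, seg, sectionSpacing = 0.010,
                          endBuffer = 0.005) {
  stopifnot(is(field, "VelocityField"), is(centerline, "Centerline"))
  sp <- seg@spacing
  d <- dim(seg@mask)
  nt <- dim(field@vx)[4L]
  nvol <- prod(d)
  arc <- centerline@arclength
  targets <- seq(endBuffer, max(arc) - endBuffer, by = sectionSpacing)
  if (length(targets) < 1L) stop("centerline too short for any section")
  secIdx <- vapply(targets, function(s) which.min(abs(arc - s)), 1L)
  secIdx <- unique(secIdx)

  idx <- which(seg@mask)
  vpts <- indexToWorld(arrayInd(idx, d) - 1, sp)  # m
  voxVol <- prod(sp)  # mm^3

  keepArc <- numeric(0)
  rows <- list()
  for (si in secIdx) {
    c0 <- centerline@points[si, ]
    tg <- centerline@tangents[si, ]
    rel <- sweep(vpts, 2L, c0)
    along <- rel %*% tg
    halfSlab <- sum(abs(tg) * sp) / 2 / 1000  # m
    inPlane2 <- rowSums(rel^2) - along^2
    rmax <- 2.5 * centerline@radius[si]
    sel <- abs(along) <= halfSlab & inPlane2 <= rmax^2
    if (sum(sel) < 4L) next
    vsel <- idx[sel]
    q <- numeric(nt)
    areaF <- voxVol / (2 * halfSlab * 1000)  # mm^2
    for (f in seq_len(nt)) {
      off <- (f - 1L) * nvol
      vdot <- field@vx[vsel + off] * tg[1] + field@vy[vsel + off] * tg[2] +
        field@vz[vsel + off] * tg[3]
      # mm^2 * m/s = 1e-6 m^3/s = 1 ml/s
      q[f] <- sum(vdot) * areaF
    }
    keepArc <- c(keepArc, arc[si])
    rows[[length(rows) + 1L]] <- q
  }
  if (length(rows) == 0L) stop("no section had enough lumen voxels")
  list(arclength_m = keepArc, flow_mls = do.call(rbind, rows),
       dt_s = field@dt / 1000)
}

# Complex Morlet continuous wavelet transform of a periodic signal
# (circular convolution via FFT), rows = scales, columns = time.
.morletCWT <- function(q, dt, scales, omega0 = 6) {
  n <- length(q)
  qh <- fft(q - mean(q))
  k <- 0:(n - 1)
  omega <- 2 * pi * ifelse(k <= n / 2, k, k - n) / (n * dt)
  W <- matrix(0 + 0i, length(scales), n)
  for (i in seq_along(scales)) {
    s <- scales[i]
    psi <- pi^(-0.25) * sqrt(2 * pi * s / dt) *
      exp(-0.5 * (s * omega - omega0)^2) * (omega > 0)
    W[i, ] <- fft(qh * psi, inverse = TRUE) / n
  }
  W
}

#' Delay between two flow waveforms by wavelet cross-spectrum
#'
#' Both waveforms are transformed with a complex Morlet continuous
#' wavelet (center frequency `omega0 = 6`) over scales whose Fourier
#' periods span `2 dt` to half the cycle. The cross-spectrum
#' `C = W_ref * conj(W_i)` is reduced to a single delay as the
#' cross-power-weighted average of `phase(C) / omega` over the
#' time-scale points whose `|C|` reaches at least `maskFrac` of the
#' maximum; the returned weight is the total `|C|` over that region. A
#' positive delay means `q` lags `qRef` (arrives later). Flat
#' waveforms give an undefined delay with weight 0.
#'
#' @param qRef,q equal-length waveforms sampling one full cycle.
#' @param dt sample interval in seconds.
#' @param omega0 Morlet center frequency.
#' @param nScales number of log-spaced scales.
#' @param maskFrac cross-power mask threshold (fraction of max).
#' @return `list(delay_s, weight)`.
#' @export
waveletDelay <- function(qRef, q, dt, omega0 = 6, nScales = 24L,
                         maskFrac = 0.5) {
  n <- length(qRef)
  if (length(q) != n) stop("waveforms must have equal length")
  if (sd(qRef) < 1e-12 || sd(q) < 1e-12)
    return(list(delay_s = NA_real_, weight = 0))
  cycle <- n * dt
  fourierFactor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  periods <- exp(seq(log(2 * dt), log(cycle / 2), length.out = nScales))
  scales <- periods / fourierFactor
  Wr <- .morletCWT(qRef, dt, scales, omega0)
  Wi <- .morletCWT(q, dt, scales, omega0)
  C <- Wr * Conj(Wi)
  a <- Mod(C)
  m <- a >= maskFrac * max(a)
  omega <- 2 * pi / periods  # rad/s per scale
  phase <- Arg(C)
  delays <- sweep(phase, 1L, omega, "/")
  list(delay_s = sum(a[m] * delays[m]) / sum(a[m]), weight = sum(a[m]))
}

#' Delay-distance table for all sections
#'
#' Computes the wavelet delay of every section's waveform relative to
#' the most proximal valid section (the fixed reference choice keeps
#' results reproducible).
#'
#' @param waveforms a [flowWaveforms()] result.
#' @param ... passed to [waveletDelay()].
#' @return data.frame with `arclength_m`, `delay_s`, `weight`.
#' @export
delayDistance <- function(waveforms, ...) {
  qm <- waveforms$flow_mls
  ns <- nrow(qm)
  ref <- qm[1, ]
  out <- data.frame(arclength_m = waveforms$arclength_m,
                    delay_s = NA_real_, weight = 0)
  for (i in seq_len(ns)) {
    wd <- waveletDelay(ref, qm[i, ], waveforms$dt_s, ...)
    out$delay_s[i] <- wd$delay_s
    out$weight[i] <- wd$weight
  }
  out
}

#' Pulse wave velocity from the delay-distance regression
#'
#' Weighted ordinary least squares of delay on arc length (weights =
#' wavelet cross-power); `PWV = 1 / slope`. The result is marked
#' invalid when the slope is non-positive or the fit R^2 is below 0.5.
#'
#' @param sections a [delayDistance()] data.frame; at least 3 sections
#'   with positive weight are required.
#' @return A [PwvFit-class].
#' @export
fitPWV <- function(sections) {
  use <- sections[!is.na(sections$delay_s) & sections$weight > 0, ]
  if (nrow(use) < 3L) stop("fewer than 3 usable sections for the PWV fit")
  fit <- lm(delay_s ~ arclength_m, data = use, weights = use$weight)
  slope <- unname(coef(fit)[2])
  wbar <- sum(use$weight * use$delay_s) / sum(use$weight)
  sst <- sum(use$weight * (use$delay_s - wbar)^2)
  sse <- sum(use$weight * stats::residuals(fit)^2)
  r2 <- if (sst > 0) 1 - sse / sst else 0
  pwv <- if (slope > 0) 1 / slope else NA_real_
  new("PwvFit", sections = use, pwv = pwv, r2 = r2,
      valid = isTRUE(slope > 0 && r2 >= 0.5))
}

#' End-to-end PWV estimation for one dataset
#'
#' Resamples the field to the target temporal resolution, extracts
#' cross-sectional flow waveforms along the centerline, computes
#' wavelet delays against the most proximal section and fits the
#' delay-distance regression.
#'
#' @param field,seg the dataset.
#' @param centerline a [Centerline-class]; extracted from `seg` when
#'   `NULL`.
#' @param dtTarget temporal resampling target, ms.
#' @param sectionSpacing section spacing, m.
#' @param ... passed to [waveletDelay()].
#' @return A [PwvFit-class].
#' @export
estimatePWV <- function(field, seg, centerline = NULL, dtTarget = 20,
                        sectionSpacing = 0.010, ...) {
  if (is.null(centerline)) centerline <- extractCenterline(seg)
  f2 <- resampleTemporal(field, dtTarget)
  wf <- flowWaveforms(f2, centerline, seg, sectionSpacing = sectionSpacing)
  # orient sections along the mean flow direction, so "proximal" is
  # upstream regardless of how the centerline happened to be traced
  if (mean(wf$flow_mls) < 0) {
    ord <- order(-wf$arclength_m)
    wf$arclength_m <- max(wf$arclength_m) - wf$arclength_m[ord]
    wf$flow_mls <- -wf$flow_mls[ord, , drop = FALSE]
  }
  fitPWV(delayDistance(wf, ...))
}
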