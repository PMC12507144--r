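test_that("linear shear flow gives WSS = mu * gamma to interpolation accuracy", {
  # u_z(y) = gamma * y above a wall at y = y0; synthetic mesh on the wall
  d <- c(8, 24, 8); spc <- rep(1, 3)  # 1 mm voxels
  gamma <- 100  # 1/s
  y0 <- 4 / 1000  # wall plane, m
  yco <- ((seq_len(d[2]) - 1) * spc[2]) / 1000
  vz <- array(0, c(d, 1))
  for (j in seq_len(d[2])) vz[, j, , 1] <- gamma * max(0, yco[j] - y0)
  f <- VelocityField(array(0, c(d, 1)), array(0, c(d, 1)),
                     vz, spacing = spc, dt = 30)
  set.seed(99)
  n <- 9
  pts <- cbind(runif(n, 0.002, 0.005), y0, runif(n, 0.002, 0.005))
  mesh <- new("WallMesh", points = pts,
              normals = matrix(rep(c(0, 1, 0), n), ncol = 3, byrow = TRUE),
              diameters = rep(0.012, n), arclength = rep(NA_real_, n),
              region = rep("none", n), landmarks = numeric(0),
              splitDir = numeric(0), spacing = spc)
  w <- estimateWSS(f, mesh, 1L, mu = 3.2e-3, maxDiameterFactor = Inf)
  expect_equal(wssMagnitudes(w), rep(0.32, n), tolerance = 0.02)
  # WSS vector is tangent to the wall
  expect_lt(max(abs(wssVectors(w)[, 2])), 0.05 * 0.32)
})

test_that("Poiseuille WSS magnitude approaches 2 mu vmax / R", {
  ph <- steadyTube()
  mesh <- steadyTubeMesh()
  w <- estimateWSS(ph$field, mesh, 1L, mu = 3.2e-3)
  m <- mean(wssMagnitudes(w), na.rm = TRUE)
  expect_lt(abs(m - 0.64) / 0.64, 0.15)
  # end-cap points, whose diameter ray runs along the lumen, are
  # predominantly flagged missing by the diameter guard (never zero)
  capIdx <- which(abs(wallNormals(mesh)[, 3]) > 0.95)
  expect_gt(mean(is.na(wssMagnitudes(w)[capIdx])), 0.7)
  expect_true(all(wssMagnitudes(w)[capIdx] > 0, na.rm = TRUE))
})

test_that("WSS is linear in viscosity and velocity scale; zero flow is zero", {
  ph <- steadyTube()
  mesh <- steadyTubeMesh()
  w1 <- estimateWSS(ph$field, mesh, 1L, mu = 3.2e-3)
  w2 <- estimateWSS(ph$field, mesh, 1L, mu = 6.4e-3)
  expect_equal(wssMagnitudes(w2), 2 * wssMagnitudes(w1), tolerance = 1e-9)
  fScaled <- VelocityField(3 * ph$field@vx, 3 * ph$field@vy,
                           3 * ph$field@vz, spacing = spacing(ph$seg),
                           dt = ph$field@dt)
  w3 <- estimateWSS(fScaled, mesh, 1L, mu = 3.2e-3)
  expect_equal(wssMagnitudes(w3), 3 * wssMagnitudes(w1), tolerance = 1e-9)
  zero <- VelocityField(0 * ph$field@vx, 0 * ph$field@vy, 0 * ph$field@vz,
                        spacing = spacing(ph$seg), dt = ph$field@dt)
  w0 <- estimateWSS(zero, mesh, 1L)
  expect_equal(max(wssMagnitudes(w0), na.rm = TRUE), 0)
  expect_error(estimateWSS(ph$field, mesh, 1L, mu = -1), "mu")
  expect_error(estimateWSS(ph$field, mesh, 99L), "frame")
})

test_that("WSS vectors stay tangent to the wall", {
  ph <- ubendPhantom()
  pf <- peakSystoleIndex(ph$field, ph$seg)
  w <- estimateWSS(ph$field, ph$geo$mesh, pf)
  ok <- !is.na(wssMagnitudes(w)) & wssMagnitudes(w) > 1e-3
  cosang <- abs(rowSums(wssVectors(w)[ok, ] * wallNormals(ph$geo$mesh)[ok, ])) /
    wssMagnitudes(w)[ok]
  expect_lt(max(cosang), 0.05)
})

test_that("SNR-20 noise changes regional mean WSS by less than 10%", {
  ph0 <- ubendPhantom()
  phN <- ubendPhantom(noiseSD = 0.05)
  geo <- ph0$geo
  pf <- peakSystoleIndex(ph0$field, ph0$seg)
  w0 <- estimateWSS(ph0$field, geo$mesh, pf)
  wN <- estimateWSS(phN$field, geo$mesh, pf)
  r0 <- regionMeans(ph0$field, w0, geo$mesh, ph0$seg, geo$centerline, pf)
  rN <- regionMeans(phN$field, wN, geo$mesh, phN$seg, geo$centerline, pf)
  expect_true(all(abs(rN$wss_pa - r0$wss_pa) / r0$wss_pa < 0.10))
})

test_that("region means summarize uniform fields exactly and step fields closely", {
  ph <- ubendPhantom()
  geo <- ph$geo
  pf <- peakSystoleIndex(ph$field, ph$seg)
  n <- nrow(wallPoints(geo$mesh))
  uni <- new("WSSField", vectors = matrix(0.5 / sqrt(3), n, 3),
             magnitude = rep(0.5, n), frame = pf, mu = 3.2e-3)
  rm <- regionMeans(ph$field, uni, geo$mesh, ph$seg, geo$centerline, pf)
  expect_equal(rm$wss_pa, rep(0.5, 6))

  # all points of one region invalid: that region NA, others intact
  inv <- uni
  kill <- regionLabels(geo$mesh) == "inner_DAo"
  inv@vectors[kill, ] <- NA_real_
  inv@magnitude[kill] <- NA_real_
  rm2 <- regionMeans(ph$field, inv, geo$mesh, ph$seg, geo$centerline, pf)
  expect_true(is.na(rm2$wss_pa[rm2$region == "inner_DAo"]))
  expect_equal(rm2$wss_pa[rm2$region != "inner_DAo"], rep(0.5, 5))

  # vmax stepped by 1.2 beyond the arch: regional means reflect the
  # step (stepped / unstepped ratio on identical geometry)
  lmMM <- ph$truth$spec@landmarks
  mkStep <- function(stepAt) makePhantom(phantomSpec(
    "u-bend", radius = 8, length = 30, bendRadius = 22, vmaxPeak = 1,
    noiseSD = 0, seed = 5, waveform = 1, dt = 40, pwvTrue = 1e5,
    stepAt = stepAt, stepFactor = 1.2))
  ph0 <- mkStep(NA_real_); ph1 <- mkStep(lmMM[2])
  geos <- phantomGeometry(ph0)
  r0 <- regionMeans(ph0$field, estimateWSS(ph0$field, geos$mesh, 1L),
                    geos$mesh, ph0$seg, geos$centerline, 1L)
  r1 <- regionMeans(ph1$field, estimateWSS(ph1$field, geos$mesh, 1L),
                    geos$mesh, ph1$seg, geos$centerline, 1L)
  vr <- r1$velocity_mps / r0$velocity_mps
  dao <- r0$region %in% c("inner_DAo", "outer_DAo")
  aao <- r0$region %in% c("inner_AAo", "outer_AAo")
  expect_true(all(abs(vr[dao] - 1.2) / 1.2 < 0.03))
  expect_true(all(abs(vr[aao] - 1.0) < 0.03))
  wr <- r1$wss_pa / r0$wss_pa
  expect_true(all(abs(wr[dao] - 1.2) / 1.2 < 0.03))
})
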