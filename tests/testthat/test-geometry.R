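test_that("cylinder wall normals point radially inward", {
  ph <- steadyTube()
  mesh <- extractWall(ph$seg)
  p <- wallPoints(mesh); nrm <- wallNormals(mesh)
  ax <- analyticCylinderAxis(ph)
  rad <- cbind(p[, 1] - ax[1], p[, 2] - ax[2], 0)
  rr <- sqrt(rowSums(rad^2))
  g <- ph$truth$layout
  zmm <- p[, 3] * 1000
  lateral <- rr > 0.004 & zmm > g$z0 + 10 & zmm < g$z1 - 10
  inward <- -rad[lateral, ] / rr[lateral]
  dots <- rowSums(nrm[lateral, ] * inward)
  expect_gt(mean(dots), 0.98)
  expect_lt(mean(abs(nrm[lateral, 3])), 0.15)
})

test_that("cube walls give one point per exposed face, axis-aligned at face centers", {
  mask <- array(FALSE, c(7, 7, 7)); mask[3:5, 3:5, 3:5] <- TRUE
  seg <- Segmentation(mask, rep(2, 3))
  mesh <- extractWall(seg)
  expect_identical(nrow(wallPoints(mesh)), 6L * 9L)
  # face-center points (centroid of each cube face) have axis-aligned normals
  ctr <- c(3, 3, 3) * 2  # world center of the cube (0-based index 3)
  p <- wallPoints(mesh) * 1000
  nrm <- wallNormals(mesh)
  for (axis in 1:3) {
    for (dir in c(-1, 1)) {
      tgt <- ctr; tgt[axis] <- tgt[axis] + dir * 3
      i <- which.min(rowSums(sweep(p, 2, tgt)^2))
      expFaceN <- c(0, 0, 0); expFaceN[axis] <- -dir  # inward
      expect_equal(nrm[i, ], expFaceN, tolerance = 1e-6)
    }
  }
})

test_that("sphere normals agree with the analytic radial direction", {
  d <- c(19, 19, 19); spc <- rep(2, 3)
  ctr <- (c(9, 9, 9) + c(0.31, 0.27, 0.41)) * 2
  co <- (arrayInd(seq_len(prod(d)), d) - 1) * 2
  rr <- sqrt(rowSums(sweep(co, 2, ctr)^2))
  seg <- Segmentation(array(rr <= 12, d), spc)
  mesh <- extractWall(seg)
  p <- wallPoints(mesh) * 1000
  rad <- sweep(p, 2, ctr)
  inward <- -rad / sqrt(rowSums(rad^2))
  cosang <- rowSums(wallNormals(mesh) * inward)
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  expect_lt(mean(ang), 5)
})

test_that("masks touching the grid boundary are rejected with voxel list", {
  mask <- array(FALSE, c(6, 6, 6)); mask[1:3, 3:4, 3:4] <- TRUE
  seg <- Segmentation(mask, rep(2, 3))
  expect_error(extractWall(seg), "boundary.*1,")
})

test_that("local lumen diameter recovers the cylinder diameter", {
  mesh <- steadyTubeMesh()
  ph <- steadyTube()
  D <- lumenDiameters(mesh)
  g <- ph$truth$layout
  zmm <- wallPoints(mesh)[, 3] * 1000
  lateral <- !is.na(D) & zmm > g$z0 + 10 & zmm < g$z1 - 10 &
    abs(wallNormals(mesh)[, 3]) < 0.3
  # constant to within one voxel across >= 90% of lateral points
  expect_gt(mean(abs(D[lateral] * 1000 - 20) <= 2.5), 0.90)
  # end-cap points see the tube length along their ray, not a diameter
  caps <- !is.na(D) & abs(wallNormals(mesh)[, 3]) > 0.95
  expect_gt(median(D[caps]) * 1000, 60)
})

test_that("slab diameter equals slab thickness along its normal", {
  mask <- array(FALSE, c(9, 9, 9)); mask[3:7, 3:7, 4:6] <- TRUE
  seg <- Segmentation(mask, rep(2, 3))
  mesh <- lumenDiameter(extractWall(seg), seg)
  nrm <- wallNormals(mesh)
  faceZ <- abs(nrm[, 3]) > 0.99
  D <- lumenDiameters(mesh)
  expect_equal(unname(median(D[faceZ & !is.na(D)])) * 1000, 3 * 2,
               tolerance = 0.2)
})

test_that("straight-tube centerline stays on the analytic axis", {
  ph <- steadyTube()
  cl <- extractCenterline(ph$seg)
  ax <- analyticCylinderAxis(ph)
  dev <- sqrt((cl@points[, 1] - ax[1])^2 + (cl@points[, 2] - ax[2])^2)
  expect_lt(max(dev) * 1000, 2.5)  # < 1 voxel
  expect_true(all(diff(arcLengths(cl)) > 0))
  expect_equal(rowSums(cl@tangents^2), rep(1, nrow(cl@tangents)),
               tolerance = 1e-9)
})

test_that("U-bend centerline length matches the analytic arc between landmarks", {
  ph <- ubendPhantom()
  geo <- ph$geo
  lmM <- geo$mesh@landmarks
  lmA <- ph$truth$landmarks
  expect_lt(abs((lmM[3] - lmM[1]) - (lmA[3] - lmA[1])) / (lmA[3] - lmA[1]),
            0.05)
})

test_that("non-tubular masks are rejected", {
  slab <- array(FALSE, c(10, 10, 4)); slab[2:9, 2:9, 2] <- TRUE
  expect_error(extractCenterline(Segmentation(slab, rep(2, 3))),
               "tube|tubular")
  # T-branch
  tb <- array(FALSE, c(13, 9, 13))
  tb[2:12, 4:6, 6:8] <- TRUE
  tb[6:8, 4:6, 2:12] <- TRUE
  expect_error(extractCenterline(Segmentation(tb, rep(2, 3),
                                              checkConnected = FALSE)),
               "tube|branch")
})

test_that("U-bend regions split inner/outer consistently with ground truth", {
  ph <- ubendPhantom()
  mesh <- ph$geo$mesh
  lab <- regionLabels(mesh)
  sel <- lab != "none"
  truthSide <- phantomTrueSide(ph$truth, wallPoints(mesh))
  estSide <- ifelse(grepl("^inner", lab), "inner", "outer")
  expect_gte(mean(estSide[sel][truthSide[sel] == "inner"] == "inner"), 0.95)
  # six region label sets are disjoint and cover all labelled points
  expect_true(all(lab %in% c("inner_AAo", "outer_AAo", "inner_arch",
                             "outer_arch", "inner_DAo", "outer_DAo",
                             "none")))
  expect_true(all(table(lab[sel]) > 0))
})

test_that("straight tube with a configured split direction divides evenly", {
  ph <- steadyTube()
  mesh <- lumenDiameter(extractWall(ph$seg), ph$seg)
  cl <- extractCenterline(ph$seg)
  lm <- max(arcLengths(cl)) * c(0.3, 0.5, 0.95)
  mesh <- partitionRegions(mesh, cl, lm, splitDir = c(1, 0, 0))
  lab <- regionLabels(mesh)
  nin <- sum(grepl("^inner", lab)); nout <- sum(grepl("^outer", lab))
  expect_lt(abs(nin - nout) / max(nin, nout), 0.10)
  # landmarks beyond the centerline range error
  expect_error(partitionRegions(mesh, cl, c(0.01, 0.02, 1.5),
                                splitDir = c(1, 0, 0)), "landmark")
  # no curvature and no split direction errors
  expect_error(partitionRegions(mesh, cl, lm), "splitDir")
})

test_that("rigid registration recovers identity, translation and rotation", {
  ph <- ubendPhantom()
  seg <- ph$seg
  spc <- spacing(seg)
  trI <- rigidRegister(seg, seg)
  expect_lt(sqrt(sum(trI@translation^2)), 0.5)
  expect_lt(max(abs(trI@rotation)) * 180 / pi, 0.5)
  expect_gte(trI@dice, 0.99)

  shiftMask <- function(a, v) {
    d <- dim(a); b <- array(FALSE, d)
    b[max(1, 1 + v[1]):min(d[1], d[1] + v[1]),
      max(1, 1 + v[2]):min(d[2], d[2] + v[2]),
      max(1, 1 + v[3]):min(d[3], d[3] + v[3])] <-
      a[max(1, 1 - v[1]):min(d[1], d[1] - v[1]),
        max(1, 1 - v[2]):min(d[2], d[2] - v[2]),
        max(1, 1 - v[3]):min(d[3], d[3] - v[3])]
    b
  }
  mv <- Segmentation(shiftMask(seg@mask, c(2, -1, 1)), spc,
                     checkConnected = FALSE)
  tr <- rigidRegister(mv, seg)
  expect_lt(max(abs(tr@translation - c(-5, 2.5, -2.5))), 1)

  # 10 degree rotation about z (nearest-voxel resampled)
  d <- dim(seg@mask)
  idx <- seq_len(prod(d))
  co <- (arrayInd(idx, d) - 1) * rep(spc, each = length(idx))
  ctr <- colMeans((arrayInd(which(seg@mask), d) - 1) *
                    rep(spc, each = sum(seg@mask)))
  th <- -10 * pi / 180
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, byrow = TRUE)
  src <- sweep(sweep(co, 2, ctr) %*% t(Rz), 2, ctr, "+")
  si <- round(sweep(src, 2, spc, "/")) + 1
  ok <- si[, 1] >= 1 & si[, 1] <= d[1] & si[, 2] >= 1 & si[, 2] <= d[2] &
    si[, 3] >= 1 & si[, 3] <= d[3]
  m2 <- array(FALSE, d)
  m2[idx[ok]] <- seg@mask[cbind(si[ok, 1], si[ok, 2], si[ok, 3])]
  tr2 <- rigidRegister(Segmentation(m2, spc, checkConnected = FALSE), seg)
  expect_lt(abs(tr2@rotation[3] * 180 / pi - (-10)), 1.5)
})
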