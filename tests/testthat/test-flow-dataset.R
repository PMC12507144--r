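test_that("PC-MRA reduces to mean(mag * speed) with its invariances", {
  d <- c(4, 4, 4, 3)
  ones <- array(1, d); zeros <- array(0, d)
  # mag = 1, constant unit velocity: PC-MRA is 1 everywhere
  f <- VelocityField(ones, zeros, zeros, spacing = c(2, 2, 2), dt = 30)
  expect_equal(computePCMRA(f), array(1, d[1:3]))
  # zero velocity: PC-MRA is 0
  f0 <- VelocityField(zeros, zeros, zeros, spacing = c(2, 2, 2), dt = 30)
  expect_equal(computePCMRA(f0), array(0, d[1:3]))
  # mag = 2, alternating sign: |v| makes the sign irrelevant
  valt <- ones
  valt[, , , 2] <- -1
  falt <- VelocityField(valt, zeros, zeros, mag = 2 * ones,
                        spacing = c(2, 2, 2), dt = 30)
  expect_equal(computePCMRA(falt), array(2, d[1:3]))
  # invariance under sign flip and timeframe permutation
  set.seed(7)
  rnd <- function() array(rnorm(prod(d)), d)
  fr <- VelocityField(rnd(), rnd(), rnd(), mag = abs(rnd()),
                      spacing = c(2, 2, 2), dt = 30)
  ffl <- VelocityField(-fr@vx, -fr@vy, -fr@vz, mag = fr@mag,
                       spacing = c(2, 2, 2), dt = 30)
  perm <- c(3, 1, 2)
  fpm <- VelocityField(fr@vx[, , , perm], fr@vy[, , , perm],
                       fr@vz[, , , perm], mag = fr@mag[, , , perm],
                       spacing = c(2, 2, 2), dt = 30)
  expect_equal(computePCMRA(ffl), computePCMRA(fr))
  expect_equal(computePCMRA(fpm), computePCMRA(fr))
})

test_that("peak systole is the argmax of lumen-mean speed", {
  d <- c(5, 5, 5)
  mask <- array(FALSE, d); mask[2:4, 2:4, 2:4] <- TRUE
  seg <- Segmentation(mask, c(2.5, 2.5, 2.5))
  one <- array(0.3, c(d, 1))
  f1 <- VelocityField(one, one, one, spacing = rep(2.5, 3), dt = 30)
  expect_identical(peakSystoleIndex(f1, seg), 1L)
  # constructed argmax at frame 2 with scaling (0.2, 1.0, 0.5)
  sc <- c(0.2, 1.0, 0.5)
  v <- array(rep(sc, each = prod(d)), c(d, 3))
  f3 <- VelocityField(v, 0 * v, 0 * v, spacing = rep(2.5, 3), dt = 30)
  expect_identical(peakSystoleIndex(f3, seg), 2L)
  # invariant to uniform rescaling
  f3b <- VelocityField(13.7 * v, 0 * v, 0 * v, spacing = rep(2.5, 3), dt = 30)
  expect_identical(peakSystoleIndex(f3b, seg), peakSystoleIndex(f3, seg))
  # grid mismatch errors
  segBad <- Segmentation(array(TRUE, c(4, 4, 4)), rep(2.5, 3))
  expect_error(peakSystoleIndex(f3, segBad), "grid")
})

test_that("phantom ground truth records the detected peak frame", {
  ph <- makePhantom(phantomSpec("straight", radius = 10, length = 60,
                                vmaxPeak = 1, noiseSD = 0.05, seed = 42,
                                waveform = defaultWaveform(30), dt = 32))
  expect_identical(peakSystoleIndex(ph$field, ph$seg),
                   as.integer(ph$truth$peakFrame))
})

test_that("dataset I/O round-trips bitwise and validates its inputs", {
  set.seed(11)
  d <- c(8, 8, 8, 4)
  rnd <- function() array(rnorm(prod(d)), d)
  f <- VelocityField(rnd(), rnd(), rnd(), mag = abs(rnd()),
                     spacing = c(2.5, 2.5, 2.0), dt = 31.25, venc = 1.75)
  mask <- array(FALSE, d[1:3]); mask[3:6, 3:6, 3:6] <- TRUE
  seg <- Segmentation(mask, f@spacing)
  dir <- withr::local_tempdir()
  writeFlowDataset(f, seg, dir)
  back <- readFlowDataset(dir)
  expect_identical(back$field@vx, f@vx)
  expect_identical(back$field@vy, f@vy)
  expect_identical(back$field@vz, f@vz)
  expect_identical(back$field@mag, f@mag)
  expect_identical(back$seg@mask, seg@mask)
  expect_equal(back$field@spacing, f@spacing)
  expect_equal(back$field@dt, f@dt)
  expect_equal(back$field@venc, f@venc)

  # sidecar missing a key errors naming the key
  sc <- jsonlite::read_json(file.path(dir, "dataset.json"))
  sc$dt_ms <- NULL
  jsonlite::write_json(sc, file.path(dir, "dataset.json"), auto_unbox = TRUE)
  expect_error(readFlowDataset(dir), "dt_ms")

  # mask with a different grid shape errors
  writeFlowDataset(f, seg, dir)
  bad <- RNifti::asNifti(array(1L, c(4, 4, 4)), datatype = "uint8")
  RNifti::writeNifti(bad, file.path(dir, "mask.nii.gz"))
  expect_error(readFlowDataset(dir), "shape|grid")

  # missing component file errors
  file.remove(file.path(dir, "vy.nii.gz"))
  expect_error(readFlowDataset(dir), "vy")
})

test_that("container validity catches malformed inputs", {
  d <- c(4, 4, 4, 2)
  a <- array(0, d)
  expect_error(VelocityField(a, a, a, spacing = c(-1, 2, 2), dt = 30),
               "spacing")
  expect_error(VelocityField(a, a, array(0, c(4, 4, 4, 3)),
                             spacing = rep(2, 3), dt = 30), "shape|vx")
  expect_error(VelocityField(a, a, a, spacing = rep(2, 3), dt = 0), "dt")
  expect_error(Segmentation(array(FALSE, c(4, 4, 4)), rep(2, 3)),
               "foreground")
  twoBlobs <- array(FALSE, c(7, 3, 3))
  twoBlobs[1:2, 2, 2] <- TRUE
  twoBlobs[6:7, 2, 2] <- TRUE
  expect_warning(Segmentation(twoBlobs, rep(2, 3)), "connected")
})
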