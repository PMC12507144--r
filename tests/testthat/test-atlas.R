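test_that("atlas statistics match hand arithmetic", {
  ph <- ubendPhantom()
  geo <- ph$geo
  n <- sum(ph$seg@mask); m <- nrow(wallPoints(geo$mesh))
  v1 <- cbind(rep(0.4, n), 0, 0)
  v2 <- cbind(rep(0.6, n), 0, 0)
  w0 <- cbind(rep(1, m), 0, 0)
  at <- buildAtlas(list(v1, v2), list(w0, w0), ph$seg, geo$mesh,
                   geo$centerline)
  expect_equal(at@velMagMean, rep(0.5, n))
  expect_equal(at@velMagSD, rep(sd(c(0.4, 0.6)), n))
  expect_equal(unique(at@wssMagSD), 0)
  # identical subjects: SD 0, mean = subject value
  at2 <- buildAtlas(rep(list(v1), 5), rep(list(w0), 5), ph$seg, geo$mesh,
                    geo$centerline)
  expect_equal(at2@velMagMean, rep(0.4, n))
  expect_equal(unique(at2@velMagSD), 0)
  # < 2 subjects is an error
  expect_error(buildAtlas(list(v1), list(w0), ph$seg, geo$mesh,
                          geo$centerline), "2 subjects")
})

test_that("atlas coverage rule leaves sparsely covered voxels undefined", {
  ph <- ubendPhantom()
  geo <- ph$geo
  n <- sum(ph$seg@mask); m <- nrow(wallPoints(geo$mesh))
  v <- cbind(rep(0.5, n), 0, 0)
  w0 <- cbind(rep(1, m), 0, 0)
  vMissing <- v; vMissing[1:10, ] <- NA_real_
  # 5 subjects, voxels 1:10 covered by only 3 (< 80% of 5): undefined
  at <- buildAtlas(c(list(vMissing, vMissing), rep(list(v), 3)),
                   rep(list(w0), 5), ph$seg, geo$mesh, geo$centerline)
  expect_true(all(is.na(at@velMagMean[1:10])))
  expect_true(all(!is.na(at@velMagMean[-(1:10)])))
})

test_that("cohort atlas voxelwise SD sits in the chi-square sampling band", {
  aa <- atlasFixture()
  # with vmaxSD = 0.1 (log scale) and noise 0.05 m/s, the per-voxel SD
  # at strong-signal voxels is sqrt((0.1 v)^2 + 0.05^2) to first order;
  # the n = 25 sample SD must sit in the chi-square 95% band around it
  at <- aa$atlas
  strong <- which(!is.na(at@velMagMean) & at@velMagMean > 0.6)
  expect_gt(length(strong), 50)
  expected <- sqrt((0.1 * at@velMagMean[strong])^2 + 0.05^2)
  band <- sqrt(qchisq(c(0.025, 0.975), 24) / 24)
  ratio <- at@velMagSD[strong] / expected
  # individual voxels fluctuate; the bulk must respect the band
  expect_gt(mean(ratio > band[1] & ratio < band[2]), 0.80)
})

test_that("elevation flags are a strict one-sided 1.96 SD rule", {
  meanMag <- c(1, 1, 1, NA)
  sdMag <- c(0.1, 0.1, 0.1, 0.1)
  pat <- c(1.0, 1.197, 1.2, 1.5)
  fl <- flagElevated(pat, meanMag, sdMag)
  expect_identical(fl, c(FALSE, TRUE, TRUE, NA))
  # exactly the boosted voxel is flagged
  pat2 <- c(1, 1, 1 + 3 * 0.1, NA)
  expect_identical(which(flagElevated(pat2, meanMag, sdMag)), 3L)
  # monotone in the threshold factor
  aa <- atlasFixture()
  at <- aa$atlas
  set.seed(77)
  patMag <- at@velMagMean * exp(rnorm(length(at@velMagMean), 0, 0.15))
  n1 <- sum(flagElevated(patMag, at@velMagMean, at@velMagSD, 1.0),
            na.rm = TRUE)
  n2 <- sum(flagElevated(patMag, at@velMagMean, at@velMagSD, 1.96),
            na.rm = TRUE)
  n3 <- sum(flagElevated(patMag, at@velMagMean, at@velMagSD, 3.0),
            na.rm = TRUE)
  expect_true(n1 >= n2 && n2 >= n3)
})

test_that("direction flags obey the 120-degree threshold", {
  rot <- function(deg) {
    th <- deg * pi / 180
    cbind(cos(th), sin(th), 0)
  }
  atlasVec <- cbind(1, 0, 0)
  expect_true(flagMisdirected(rot(130), atlasVec))
  expect_false(flagMisdirected(rot(110), atlasVec))
  expect_true(flagMisdirected(-atlasVec, atlasVec))   # 180 degrees
  # near-zero vectors are not evaluated
  expect_true(is.na(flagMisdirected(cbind(0.001, 0, 0), atlasVec)))
  # monotone: raising the angle threshold flags fewer locations
  set.seed(31)
  n <- 400
  v <- matrix(rnorm(3 * n), n, 3)
  a <- matrix(rep(c(1, 0, 0), n), n, 3, byrow = TRUE)
  expect_gte(sum(flagMisdirected(v, a, 100), na.rm = TRUE),
             sum(flagMisdirected(v, a, 140), na.rm = TRUE))
})

test_that("a held-out healthy subject is rarely flagged against the atlas", {
  aa <- atlasFixture()
  tmpl <- aa$template
  set.seed(900)
  hs <- tmpl
  hs@vmaxPeak <- tmpl@vmaxPeak * exp(rnorm(1, 0, 0.1))
  hs@seed <- 999L
  hd <- makePhantom(hs, layout = aortaflow:::.phantomLayout(tmpl))
  map <- abnormalityMap(hd$field, hd$seg, aa$atlas)
  expect_lt(mean(map@elevatedVelocity, na.rm = TRUE), 0.10)
  expect_lt(mean(map@elevatedWSS, na.rm = TRUE), 0.10)
  # a patient identical to the atlas mean yields all-false maps
  d <- dim(lumenMask(aa$atlas))
  nvol <- prod(d)
  mkArr <- function(col) {
    a <- array(0, c(d, 1))
    a[aa$atlas@voxelIdx] <- ifelse(is.na(aa$atlas@velMean[, col]), 0,
                                   aa$atlas@velMean[, col])
    a
  }
  fMean <- VelocityField(mkArr(1), mkArr(2), mkArr(3),
                         spacing = spacing(aa$geometry$seg), dt = 40)
  mapMean <- abnormalityMap(fMean, aa$geometry$seg, aa$atlas, frame = 1L)
  expect_identical(sum(mapMean@elevatedVelocity, na.rm = TRUE), 0L)
  expect_identical(sum(mapMean@misdirectedVelocity, na.rm = TRUE), 0L)
  flags <- patientRegionFlags(mapMean, aa$atlas)
  ev <- flags$flag[flags$metric == "elevated_velocity"]
  expect_true(all(!ev | is.na(ev)))
})

test_that("region flags OR their locations", {
  aa <- atlasFixture()
  at <- aa$atlas
  nv <- length(at@voxelIdx); m <- nrow(at@wssMean)
  mk <- function(ev, ew = rep(FALSE, m))
    new("AbnormalityMap", elevatedVelocity = ev, elevatedWSS = ew,
        misdirectedVelocity = rep(FALSE, nv),
        misdirectedWSS = rep(FALSE, m), angleThreshold = 120,
        ciFactor = 1.96)
  oneVox <- rep(FALSE, nv)
  target <- which(at@voxelRegion == "inner_DAo")[1]
  oneVox[target] <- TRUE
  fl <- patientRegionFlags(mk(oneVox), at)
  ev <- fl[fl$metric == "elevated_velocity", ]
  expect_true(ev$flag[ev$region == "inner_DAo"])
  expect_true(all(!ev$flag[ev$region != "inner_DAo"]))
  flNone <- patientRegionFlags(mk(rep(FALSE, nv)), at)
  expect_true(all(!flNone$flag[flNone$metric == "elevated_velocity"]))
  flAll <- patientRegionFlags(mk(rep(TRUE, nv), rep(TRUE, m)), at)
  expect_true(all(flAll$flag[flAll$metric %in%
                               c("elevated_velocity", "elevated_wss")]))
})

test_that("incidence maps average flags over covering patients", {
  nv <- 50; m <- 20
  mk <- function(ev) new("AbnormalityMap", elevatedVelocity = ev,
                         elevatedWSS = rep(FALSE, m),
                         misdirectedVelocity = rep(FALSE, nv),
                         misdirectedWSS = rep(FALSE, m),
                         angleThreshold = 120, ciFactor = 1.96)
  maps <- lapply(1:10, function(i) mk(c(rep(i <= 4, 1), rep(FALSE, nv - 1))))
  inc <- incidenceMap(maps)
  expect_equal(inc$elevated_velocity[1], 40)
  expect_equal(inc$elevated_velocity[2], 0)
  # identical maps: incidence is 0 or 100 only
  incSame <- incidenceMap(rep(list(mk(rep(c(TRUE, FALSE), nv / 2))), 7))
  expect_true(all(incSame$elevated_velocity %in% c(0, 100)))
  # independent flags at p = 0.5: mean incidence ~ 50%
  set.seed(5)
  mapsP <- lapply(1:40, function(i) mk(runif(nv) < 0.5))
  incP <- incidenceMap(mapsP)
  expect_lt(abs(mean(incP$elevated_velocity) - 50), 5)
  # uncovered locations are NA
  withNA <- mk(c(NA, rep(FALSE, nv - 1)))
  incNA <- incidenceMap(list(withNA))
  expect_true(is.na(incNA$elevated_velocity[1]))
})
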