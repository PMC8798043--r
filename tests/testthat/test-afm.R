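test_that("plane leveling removes tilt and preserves patch heights", {
  # pure tilted plane -> residual below numerical tolerance
  tiltOnly <- patchMap(rPx = 0)
  lev <- levelPlane(tiltOnly)
  expect_lt(max(abs(heights(lev))), 1e-8)

  # plane + 47 nm patch: height preserved within 2%
  pm <- patchMap(rPx = 12, height = 47)
  lev2 <- levelPlane(pm)
  inner <- punctakit:::discPixelMask(dim(heights(lev2)), 64, 64, 9)
  expect_equal(median(heights(lev2)[inner]), 47, tolerance = 0.02)

  # already level map: unchanged within tolerance
  flat <- HeightMap(matrix(rnorm(64 * 64, 0, 0.5), 64, 64), 4)
  lev3 <- levelPlane(flat)
  expect_equal(heights(lev3), heights(flat), tolerance = 0.05,
               ignore_attr = TRUE)

  # leveling is idempotent
  lev4 <- levelPlane(lev2)
  expect_equal(heights(lev4), heights(lev2), tolerance = 1e-6)
})

test_that("an exclusion mask covering nearly everything is rejected", {
  m <- HeightMap(matrix(0, 32, 32), 4)
  mask <- matrix(TRUE, 32, 32); mask[1, 1:10] <- FALSE
  expect_error(levelPlane(m, mask), "insufficient background")
})

test_that("cluster segmentation recovers planted geometry", {
  flat <- HeightMap(matrix(rnorm(64 * 64, 0, 0.3), 64, 64), 4)
  expect_equal(nrow(segmentClusters(levelPlane(flat))), 0L)

  g <- generateHeightMap(afmSpec(nPatches = 1L, patchHeightNm = 47,
                                 patchAreaUm2 = 0.005, seed = 6))
  cl <- segmentClusters(levelPlane(g$map))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$areaUm2, g$truth$areaUm2, tolerance = 0.10)
  expect_equal(cl$heightNm, 47, tolerance = 2 / 47)  # within roughness

  # two patches of distinct heights keep their ordering
  g2 <- generateHeightMap(afmSpec(nPatches = 2L,
                                  patchHeightNm = c(47, 15), seed = 8))
  cl2 <- segmentClusters(levelPlane(g2$map))
  expect_equal(nrow(cl2), 2L)
  expect_equal(sort(cl2$heightNm), c(15, 47), tolerance = 0.1)
})

test_that("segmentation is translation-equivariant", {
  z <- matrix(0, 96, 96)
  z[punctakit:::discPixelMask(c(96, 96), 30, 30, 8)] <- 20
  m1 <- segmentClusters(HeightMap(z, 4), heightThreshold = 10)
  z2 <- matrix(0, 96, 96)
  z2[punctakit:::discPixelMask(c(96, 96), 45, 52, 8)] <- 20
  m2 <- segmentClusters(HeightMap(z2, 4), heightThreshold = 10)
  expect_equal(m2$y - m1$y, 15)
  expect_equal(m2$x - m1$x, 22)
  expect_equal(m1$areaUm2, m2$areaUm2)
})

test_that("a sub-noise threshold warns about over-segmentation", {
  noisy <- HeightMap(matrix(rnorm(64 * 64), 64, 64), 4)
  expect_warning(segmentClusters(noisy, heightThreshold = 0.5),
                 "noise floor")
})

test_that("cross-sections return calibrated profiles", {
  flat <- HeightMap(matrix(3, 32, 32), 2)
  cs <- crossSection(flat, rbind(c(5, 2), c(5, 28)))
  expect_lt(diff(range(cs$mean)), 1e-12)
  expect_equal(diff(cs$positions)[1], 2)   # nm per px step

  pm <- patchMap(shape = c(64L, 64L), tilt = c(0, 0), cy = 32, cx = 32,
                 rPx = 10, height = 47)
  cs2 <- crossSection(pm, rbind(c(32, 2), c(32, 61)))
  expect_equal(max(cs2$mean), 47)
  onTop <- cs2$mean > 23.5
  expect_equal(sum(onTop), 2 * 10 / 1, tolerance = 2)  # top-hat width

  cs0 <- crossSection(flat, rbind(c(5, 5), c(5, 5)))
  expect_equal(length(cs0$mean), 1L)
})

test_that("tracking follows stationary and separated particles exactly", {
  # single stationary particle spans the whole movie
  fr <- array(0, c(10, 48, 48))
  for (f in 1:10) {
    z <- matrix(0, 48, 48)
    z[punctakit:::discPixelMask(c(48, 48), 20, 20, 3)] <- 5
    fr[f, , ] <- z
  }
  mv <- HeightMovie(fr, 8, 2)
  tr <- trackParticles(mv, 2, maxLinkDistance = 3)
  expect_equal(length(unique(tr$tracks$trackId)), 1L)
  expect_equal(nrow(tr$tracks), 10L)
  expect_equal(tr$births$birthFrame, 1L)
  expect_equal(tr$births$deathFrame, 10L)
  expect_equal(max(tr$heatmap), 10)

  # two particles always far apart -> two unbroken tracks
  fr2 <- array(0, c(8, 64, 64))
  for (f in 1:8) {
    z <- matrix(0, 64, 64)
    z[punctakit:::discPixelMask(c(64, 64), 12 + f, 12, 2.5)] <- 5
    z[punctakit:::discPixelMask(c(64, 64), 50 - f, 50, 2.5)] <- 5
    fr2[f, , ] <- z
  }
  tr2 <- trackParticles(HeightMovie(fr2, 8, 2), 2, maxLinkDistance = 3)
  expect_equal(length(unique(tr2$tracks$trackId)), 2L)
  expect_equal(unname(table(tr2$tracks$trackId)), c(8L, 8L),
               ignore_attr = TRUE)

  # empty movie -> no tracks, zero heat map
  tr3 <- trackParticles(HeightMovie(array(0, c(5, 32, 32)), 8, 2), 2)
  expect_equal(nrow(tr3$tracks), 0L)
  expect_true(all(tr3$heatmap == 0))
})

test_that("tracking reproduces planted docking tracks", {
  g <- generateDockingMovie(dockingSpec(nFrames = 150L, seed = 12))
  tr <- trackParticles(levelMovie(g$movie), detectionThreshold = 1.5,
                       maxLinkDistance = 3)
  expect_equal(nrow(tr$births), nrow(g$truth))
  # birth times match the planted arrival frames
  expectedBirth <- (ceiling(g$truth$time / frameInterval(g$movie))) *
    frameInterval(g$movie)
  expect_equal(sort(tr$births$birthTime), sort(expectedBirth))
})

test_that("particle sizing returns the half-maximum equivalent diameter", {
  z <- matrix(0, 64, 64)
  z[punctakit:::discPixelMask(c(64, 64), 32, 32, 2)] <- 4  # 32 nm at 8 nm/px
  m <- HeightMap(z, 8)
  ps <- particleSize(m, c(32, 32))
  expect_equal(ps$diameterNm, 32, tolerance = 8 / 32)  # within a pixel
  expect_equal(ps$flag, "ok")

  # rotating a radially symmetric particle changes nothing
  z90 <- t(z)[, rev(seq_len(64))]
  ps90 <- particleSize(HeightMap(z90, 8), c(32, 32))
  expect_equal(ps90$diameterNm, ps$diameterNm)

  # below 2 px -> unresolvable
  z2 <- matrix(0, 64, 64); z2[32, 32] <- 4
  expect_equal(particleSize(HeightMap(z2, 8), c(31, 31))$flag,
               "unresolvable")

  # touching particles are flagged ambiguous
  z3 <- matrix(0, 64, 64)
  z3[punctakit:::discPixelMask(c(64, 64), 32, 30, 4)] <- 4
  z3[punctakit:::discPixelMask(c(64, 64), 32, 36, 4)] <- 4
  ps3 <- particleSize(HeightMap(z3, 8), c(32, 30),
                      otherCentroids = rbind(c(32, 36)))
  expect_equal(ps3$flag, "ambiguous")
})

test_that("docking intervals summarize event times", {
  di <- dockingIntervals(c(0, 100, 200))
  expect_equal(di$intervals, c(100, 100))
  expect_equal(di$meanInterval, 100)
  expect_equal(di$sdInterval, 0)
  expect_error(dockingIntervals(c(50)), "insufficient events")
})

test_that("height versus force compares setpoint conditions", {
  lo <- data.frame(heightNm = rnorm(20, 47, 1))
  hi <- data.frame(heightNm = rnorm(20, 15, 1))
  hv <- heightVsForce(lo, lo)
  expect_equal(hv$difference, 0)
  hv2 <- heightVsForce(lo, hi)
  expect_equal(hv2$difference, 32, tolerance = 0.1)
  expect_lt(hv2$test$p, 1e-4)
  expect_error(heightVsForce(lo, lo[0, , drop = FALSE]),
               "insufficient data")
})
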