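test_that("puncta generator is deterministic and returns exact truth", {
  g1 <- generatePunctaImage(punctaSpec(nSpots = 5L, seed = 42))
  g2 <- generatePunctaImage(punctaSpec(nSpots = 5L, seed = 42))
  expect_identical(pixels(g1$image), pixels(g2$image))
  expect_identical(spots(g1$truth), spots(g2$truth))

  g0 <- generatePunctaImage(punctaSpec(nSpots = 0L, poissonGain = 0,
                                       readNoiseSd = 0, seed = 1))
  expect_equal(length(g0$truth), 0L)
  expect_true(all(getPlane(g0$image, 1, "protein") == 20))
})

test_that("noise-free spots are disjoint blobs at the returned centers", {
  g <- generatePunctaImage(punctaSpec(nSpots = 5L, poissonGain = 0,
                                      readNoiseSd = 0, seed = 7))
  tr <- spots(g$truth)
  p <- getPlane(g$image, 1, "protein")
  for (i in seq_len(5)) {
    # planted center is a local maximum at its own peak height
    v <- p[round(tr$y[i]) + 1, round(tr$x[i]) + 1]
    expect_gt(v, 20 + 0.9 * tr$peak[i])
  }
  # disjoint: centers further apart than the sum of radii
  d <- as.matrix(dist(tr[, c("y", "x")]))
  diag(d) <- Inf
  expect_true(all(d > outer(tr$radiusPx, tr$radiusPx, "+")))
})

test_that("planted area distribution matches the requested distribution", {
  # compare the generator's truth to a direct sample of the same
  # truncated-normal radius distribution
  set.seed(11)
  spec <- punctaSpec(nSpots = 60L, shape = c(512L, 512L), seed = 11)
  tr <- spots(generatePunctaImage(spec)$truth)
  ref <- rnorm(20000, spec$radiusMeanUm, spec$radiusSdUm)
  ref <- ref[ref >= spec$pixelSize]
  refMean <- mean(pi * ref^2)
  se <- sqrt(sd(pi * ref^2)^2 / length(ref) +
               sd(tr$areaUm2)^2 / nrow(tr))
  expect_lt(abs(mean(tr$areaUm2) - refMean), 4 * se)
  expect_equal(mean(tr$areaUm2), 0.067, tolerance = 0.15)
})

test_that("impossible placements raise a placement error", {
  expect_error(generatePunctaImage(punctaSpec(shape = c(32L, 32L),
                                              nSpots = 200L, seed = 1)),
               "placement error")
  expect_error(generateHeightMap(afmSpec(shape = c(32L, 32L),
                                         patchAreaUm2 = 0.05, seed = 1)),
               "placement error")
})

test_that("recruitment stack follows the saturating kinetics exactly", {
  pn <- punctaSpec(nSpots = 10L, poissonGain = 0, readNoiseSd = 0, seed = 2)
  k <- generateRecruitmentStack(kineticsSpec(plateau = 80, tau = 60,
                                             seed = 2), pn)
  mg <- vapply(seq_len(nFrames(k$image)),
               function(f) mean(getPlane(k$image, f, "protein")), numeric(1))
  expect_equal(mg, 80 * (1 - exp(-k$truth$times / 60)), tolerance = 1e-10)

  # tau -> 0 limit: first frame already at plateau
  k0 <- generateRecruitmentStack(kineticsSpec(plateau = 80, tau = 0,
                                              seed = 2), pn)
  expect_equal(mean(getPlane(k0$image, 1, "protein")), 80, tolerance = 1e-10)

  # plateau 0: flat zero protein channel
  kz <- generateRecruitmentStack(kineticsSpec(plateau = 0, tau = 60,
                                              seed = 2), pn)
  expect_true(all(pixels(kz$image)[, 2, , ] == 0))
})

test_that("height-map generator plants recoverable patches", {
  g <- generateHeightMap(afmSpec(nPatches = 0L, roughnessSd = 0, seed = 3))
  lev <- levelPlane(g$map)
  expect_lt(max(abs(heights(lev))), 1e-6)  # pure plane levels to zero

  g2 <- generateHeightMap(afmSpec(nPatches = 2L,
                                  patchHeightNm = c(47, 15), seed = 3))
  expect_equal(nrow(g2$truth), 2L)
  expect_setequal(g2$truth$heightNm, c(47, 15))
  lev2 <- levelPlane(g2$map)
  expect_equal(max(heights(lev2)), 47, tolerance = 0.15)
})

test_that("docking-event truth follows the requested renewal process", {
  spec <- dockingSpec(nFrames = 250L, seed = 9)
  g <- generateDockingMovie(spec)
  iv <- attr(g$truth, "intervals")
  expect_gt(length(iv), 20)
  se <- 115 / sqrt(length(iv))
  expect_lt(abs(mean(iv) - 115), 3 * se)
  # fixed seed reproduces event times exactly
  g2 <- generateDockingMovie(dockingSpec(nFrames = 250L, seed = 9))
  expect_identical(g$truth$time, g2$truth$time)
  # a movie much shorter than the mean interval may hold no event
  g3 <- generateDockingMovie(dockingSpec(meanInterval = 1e7, nFrames = 5L,
                                         seed = 1))
  expect_equal(nrow(g3$truth), 0L)
})

test_that("dome images realize the requested lateral profiles", {
  un <- generateDomeImage(domeSpec(profile = "uniform", seed = 1))
  ratio <- getPlane(un$image, 1, "protein") / getPlane(un$image, 1, "reference")
  expect_lt(diff(range(ratio)), 1e-12)

  rim <- generateDomeImage(domeSpec(profile = "rim", seed = 1))
  pr <- domeProfileAverage(rim$image, rim$centers, rim$radiusPx)
  expect_equal(pr$ratio$positions[which.max(pr$ratio$mean)],
               150, tolerance = 0.1)

  ex <- generateDomeImage(domeSpec(profile = "excluded", seed = 1))
  p <- getPlane(ex$image, 1, "protein")
  c1 <- ex$centers[1, ]
  foot <- punctakit:::discPixelMask(dim(p), c1$y, c1$x, 0.7 * ex$radiusPx)
  expect_lt(mean(p[foot]), 0.3 * 100)
})
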