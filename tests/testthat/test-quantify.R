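test_that("normalized binding reduces to channel ratios", {
  px <- array(0, c(1, 2, 16, 16))
  px[1, 1, , ] <- 50           # membrane
  px[1, 2, , ] <- 50           # protein identical
  s <- ImageStack(px, 0.05, channelLabels = c("membrane", "protein"))
  expect_equal(normalizedBinding(s, steadyStateTime = 0), 1.0)

  px[1, 2, , ] <- 100
  s2 <- ImageStack(px, 0.05, channelLabels = c("membrane", "protein"))
  expect_equal(normalizedBinding(s2, steadyStateTime = 0), 2.0)

  px[1, 1, , ] <- 0
  s3 <- ImageStack(px, 0.05, channelLabels = c("membrane", "protein"))
  expect_error(normalizedBinding(s3, steadyStateTime = 0),
               "undefined normalization")
})

test_that("binding on a synthetic recruitment stack recovers plateau/membrane", {
  pn <- punctaSpec(nSpots = 10L, seed = 4)   # default noise model
  k <- generateRecruitmentStack(kineticsSpec(plateau = 120, tau = 30,
                                             seed = 4), pn)
  v <- normalizedBinding(k$image, steadyStateTime = 240)
  expect_equal(v, 120 / pn$membraneLevel, tolerance = 0.03)
})

test_that("spot intensities are measured on the disc footprint", {
  ss <- SpotSet(data.frame(y = c(10, 30), x = c(10, 30),
                           radiusPx = c(3, 3), areaUm2 = 1), 0.05)
  u <- matrix(7, 48, 48)
  s <- spotIntensityDistribution(ss, u)
  expect_equal(s$values, c(7, 7))

  # two planted intensities are recovered bimodally
  p <- matrix(0, 48, 48)
  p[punctakit:::discPixelMask(c(48, 48), 10, 10, 3)] <- 100
  p[punctakit:::discPixelMask(c(48, 48), 30, 30, 3)] <- 10
  s2 <- spotIntensityDistribution(ss, p)
  expect_equal(sort(s2$values), c(10, 100))

  # empty spot set -> empty summary
  s3 <- spotIntensityDistribution(SpotSet(data.frame(
    y = numeric(0), x = numeric(0), radiusPx = numeric(0),
    areaUm2 = numeric(0)), 0.05), u)
  expect_equal(s3$n, 0L)

  # footprint beyond the edge warns
  ssEdge <- SpotSet(data.frame(y = 1, x = 1, radiusPx = 5, areaUm2 = 1), 0.05)
  expect_warning(spotIntensityDistribution(ssEdge, u), "clipped")
})

test_that("reference-normalized intensity recovers planted enrichment", {
  ss <- SpotSet(data.frame(y = c(15, 40), x = c(15, 40),
                           radiusPx = c(4, 4), areaUm2 = 1), 0.05)
  bg <- matrix(50, 64, 64)
  expect_equal(normalizedIntensityOnReference(ss, bg, bg)$values, c(1, 1))

  enriched <- bg
  for (i in c(15, 40))
    enriched[punctakit:::discPixelMask(c(64, 64), i, i, 4)] <- 100
  v <- normalizedIntensityOnReference(ss, enriched, enriched)$values
  expect_equal(v, c(2, 2), tolerance = 1e-10)

  empty <- SpotSet(data.frame(y = numeric(0), x = numeric(0),
                              radiusPx = numeric(0), areaUm2 = numeric(0)),
                   0.05)
  expect_equal(normalizedIntensityOnReference(empty, bg, bg)$n, 0L)
})

test_that("fold change behaves as a ratio of means", {
  a <- conditionSummary(c(4, 4, 4), "a")
  b <- conditionSummary(c(2, 2, 2), "b")
  expect_equal(foldChange(a, a)$ratio, 1)
  expect_equal(foldChange(a, b)$ratio, 2)
  expect_equal(foldChange(a, b)$ratio * foldChange(b, a)$ratio, 1)
  expect_error(foldChange(a, conditionSummary(c(0, 0), "z")),
               "undefined ratio")
  expect_error(foldChange(a, conditionSummary(numeric(0), "e")), "non-empty")
})

test_that("normalized quantities are invariant under intensity scaling", {
  set.seed(8)
  g <- generatePunctaImage(punctaSpec(nSpots = 6L, seed = 8))
  p <- getPlane(g$image, 1, "protein")
  ss <- detectSpots(p, pixelSize = 0.05)
  v1 <- normalizedIntensityOnReference(ss, p, p)$values
  v2 <- normalizedIntensityOnReference(ss, 3.7 * p, 3.7 * p)$values
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("line profiles are flat on constants and peak on bumps", {
  flat <- lineProfile(matrix(5, 64, 64), rbind(c(10, 5), c(10, 55)),
                      width = 3, pixelSize = 0.1)
  expect_lt(diff(range(flat$mean)), 1e-12)
  expect_equal(diff(flat$positions)[1], 0.1)

  p <- bumpPlane(c(64L, 64L), 32, 32, r = 5, edge = 0.5)
  pr <- lineProfile(p, rbind(c(32, 5), c(32, 59)), width = 1, pixelSize = 1)
  peakPos <- pr$positions[which.max(pr$mean)]
  expect_equal(peakPos, 32 - 5, tolerance = 1)  # path starts at x = 5
  # FWHM ~ planted diameter
  half <- (max(pr$mean) + min(pr$mean)) / 2
  above <- range(which(pr$mean >= half))
  expect_equal(diff(pr$positions[above]), 10, tolerance = 1.5)

  # perpendicular averaging widths agree along a symmetric structure
  p1 <- lineProfile(p, rbind(c(32, 10), c(32, 54)), width = 1, pixelSize = 1)
  p5 <- lineProfile(p, rbind(c(32, 10), c(32, 54)), width = 5, pixelSize = 1)
  expect_equal(which.max(p1$mean), which.max(p5$mean))

  expect_error(lineProfile(p, rbind(c(-5, 0), c(100, 0))), "outside")
})

test_that("dome profile averaging honors replicate identity and rim peaks", {
  un <- generateDomeImage(domeSpec(profile = "uniform", nDomes = 20L))
  pu <- domeProfileAverage(un$image, un$centers, un$radiusPx)
  expect_lt(max(pu$reference$sd), 1e-12)   # identical domes -> SD 0
  expect_equal(pu$ratio$n, 20L)
  expect_lt(diff(range(pu$ratio$mean)), 1e-12)

  rim <- generateDomeImage(domeSpec(profile = "rim", nDomes = 12L))
  pr <- domeProfileAverage(rim$image, rim$centers, rim$radiusPx)
  expect_equal(pr$ratio$positions[which.max(pr$ratio$mean)], 150,
               tolerance = 0.1)

  # clipped domes are excluded with a warning
  centersEdge <- rbind(un$centers, data.frame(y = 2, x = 2))
  expect_warning(pe <- domeProfileAverage(un$image, centersEdge,
                                          un$radiusPx), "clipped")
  expect_equal(pe$ratio$n, 20L)
})

test_that("plane presence classifies uniform, excluded and rim fixtures", {
  un <- generateDomeImage(domeSpec(profile = "uniform"))
  pp <- planePresence(un$image, un$image, un$centers, un$radiusPx)
  expect_true(all(pp$class == "present"))
  expect_equal(pp$topOn, rep(1, nrow(pp)), tolerance = 1e-10)

  ex <- generateDomeImage(domeSpec(profile = "excluded"))
  ppe <- planePresence(ex$image, un$image, ex$centers, ex$radiusPx)
  expect_true(all(ppe$class == "excluded"))

  rim <- generateDomeImage(domeSpec(profile = "rim"))
  ppr <- planePresence(un$image, rim$image, rim$centers, rim$radiusPx)
  expect_true(all(ppr$class == "rim-enriched"))
  expect_true(all(ppr$rimEnhancement > 1))

  small <- generateDomeImage(domeSpec(profile = "uniform",
                                      shape = c(128L, 128L), nDomes = 4L))
  expect_error(planePresence(un$image, small$image, un$centers,
                             un$radiusPx), "registration error")
})
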