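# Planted-truth recovery studies: run an analysis stage end to end on
# synthetic data and score the result against the generator's ground truth.
# These are the package's own operating-characteristic benchmarks.

#' Detector recovery study on planted puncta
#'
#' Generates `nImages` synthetic puncta images and scores the scale-space
#' detector against the planted truth: recall within `matchRadiusPx`, false
#' positives, and the mean-area error.
#'
#' @param nImages number of images
#' @param seed RNG seed for the whole study
#' @param nSpotsRange inclusive range of planted spot counts per image
#' @param radiusRangeUm truncation bounds of the planted radius
#'   distribution (um)
#' @param radiusMeanUm,radiusSdUm planted radius distribution (um)
#' @param params [detectionParams()] used for detection; the default uses a
#'   quarter-octave scale grid for finer radius (hence area) resolution
#' @param matchRadiusPx maximum truth-to-detection distance for a hit (px)
#' @param spec base [punctaSpec()] supplying image shape, calibration,
#'   intensity and noise settings
#' @return list with `recallPct`, `falsePositivePct`, `areaErrorPct`,
#'   `meanAreaTruthUm2`, `meanAreaDetectedUm2`, `nPlanted`, `nDetected`
#' @export
detectorRecoveryStudy <- function(nImages = 50L, seed = 1L,
                                  nSpotsRange = c(5L, 20L),
                                  radiusRangeUm = NULL,
                                  radiusMeanUm = NULL, radiusSdUm = NULL,
                                  params = detectionParams(
                                    scales = geomScales(2, 12, 2^0.25)),
                                  matchRadiusPx = 1,
                                  spec = punctaSpec()) {
  withSeed(seed, {
    nPlanted <- nDetected <- nHit <- nFP <- 0L
    areaT <- areaD <- numeric(0)
    for (i in seq_len(nImages)) {
      s <- spec
      s$nSpots <- sample(nSpotsRange[1L]:nSpotsRange[2L], 1L)
      if (!is.null(radiusMeanUm)) s$radiusMeanUm <- radiusMeanUm
      if (!is.null(radiusSdUm)) s$radiusSdUm <- radiusSdUm
      if (!is.null(radiusRangeUm)) {
        s$radiusMinUm <- radiusRangeUm[1L]
        s$radiusMaxUm <- radiusRangeUm[2L]
      }
      s$seed <- sample.int(.Machine$integer.max, 1L)
      g <- generatePunctaImage(s)
      tr <- spots(g$truth)
      d <- spots(detectSpots(g$image, params, channel = "protein"))
      nPlanted <- nPlanted + nrow(tr)
      nDetected <- nDetected + nrow(d)
      if (nrow(tr) && nrow(d)) {
        dd <- outer(tr$y, d$y, "-")^2 + outer(tr$x, d$x, "-")^2
        nearest <- apply(dd, 1L, which.min)
        hit <- sqrt(dd[cbind(seq_len(nrow(tr)), nearest)]) <= matchRadiusPx
        nHit <- nHit + sum(hit)
        areaT <- c(areaT, tr$areaUm2)
        areaD <- c(areaD, d$areaUm2[nearest[hit]])
        # detections not within the match radius of any planted center
        minToTruth <- sqrt(apply(dd, 2L, min))
        nFP <- nFP + sum(minToTruth > matchRadiusPx)
      } else {
        nFP <- nFP + nrow(d)
      }
    }
    list(recallPct = 100 * nHit / nPlanted,
         falsePositivePct = 100 * nFP / nPlanted,
         areaErrorPct = 100 * (mean(areaD) / mean(areaT) - 1),
         meanAreaTruthUm2 = mean(areaT),
         meanAreaDetectedUm2 = mean(areaD),
         nPlanted = nPlanted, nDetected = nDetected)
  })
}

#' AFM recovery study on planted patches
#'
#' Generates tilted, rough height maps bearing flat-topped patches at two
#' setpoint-force conditions (default 47 nm / low and 15 nm / high), levels
#' and segments them, and scores recovered heights and areas against truth.
#'
#' @param nMaps maps per condition
#' @param seed RNG seed
#' @param heightsNm planted heights, `c(low, high)`
#' @param patchAreaUm2 planted patch area (um^2)
#' @param nPatches patches per map
#' @param roughnessSd roughness sd in nm
#' @return list with recovered mean heights, their percent errors, the
#'   median cluster area, the area percent error, and per-condition
#'   cluster tables
#' @export
afmRecoveryStudy <- function(nMaps = 3L, seed = 1L, heightsNm = c(47, 15),
                             patchAreaUm2 = 0.005, nPatches = 3L,
                             roughnessSd = 1) {
  withSeed(seed, {
    run <- function(h, label) {
      out <- list()
      truthArea <- numeric(0)
      for (i in seq_len(nMaps)) {
        g <- generateHeightMap(afmSpec(
          nPatches = nPatches, patchHeightNm = h,
          patchAreaUm2 = patchAreaUm2, roughnessSd = roughnessSd,
          setpointLabel = label,
          seed = sample.int(.Machine$integer.max, 1L)))
        out[[i]] <- segmentClusters(levelPlane(g$map))
        truthArea <- c(truthArea, g$truth$areaUm2)
      }
      list(clusters = do.call(rbind, out), truthArea = truthArea)
    }
    lo <- run(heightsNm[1L], "low")
    hi <- run(heightsNm[2L], "high")
    areas <- c(lo$clusters$areaUm2, hi$clusters$areaUm2)
    truthAreas <- c(lo$truthArea, hi$truthArea)
    list(heightLowNm = mean(lo$clusters$heightNm),
         heightHighNm = mean(hi$clusters$heightNm),
         heightErrorLowPct =
           100 * abs(mean(lo$clusters$heightNm) / heightsNm[1L] - 1),
         heightErrorHighPct =
           100 * abs(mean(hi$clusters$heightNm) / heightsNm[2L] - 1),
         medianAreaUm2 = stats::median(areas),
         areaErrorPct = 100 * abs(mean(areas) / mean(truthAreas) - 1),
         low = lo$clusters, high = hi$clusters)
  })
}

#' Docking-interval recovery study
#'
#' Generates a docking movie (renewal-process arrivals, persisting
#' particles), tracks it, and compares the tracking-based mean inter-event
#' interval both to the generator's drawn sample and to the specified mean;
#' also verifies that bypassing tracking reproduces the drawn sample
#' exactly.
#'
#' @param seed RNG seed
#' @param spec a [dockingSpec()]; the default movie length targets on the
#'   order of 200 events
#' @param detectionThreshold,maxLinkDistance tracking parameters
#' @return list with `meanRecoveredS`, `meanTruthS`, `n`, `seS`,
#'   `withinTwoSE`, `bypassExact`
#' @export
dockingRecoveryStudy <- function(seed = 1L,
                                 spec = dockingSpec(nFrames = 1200L,
                                                    shape = c(192L, 192L)),
                                 detectionThreshold = 1.5,
                                 maxLinkDistance = 3) {
  spec$seed <- seed
  g <- generateDockingMovie(spec)
  tr <- trackParticles(g$movie, detectionThreshold, maxLinkDistance)
  di <- dockingIntervals(tr)
  truthIv <- attr(g$truth, "intervals")
  se <- stats::sd(truthIv) / sqrt(length(truthIv))
  bypass <- dockingIntervals(g$truth$time)
  list(meanRecoveredS = di$meanInterval,
       sdRecoveredS = di$sdInterval,
       meanTruthS = mean(truthIv),
       n = di$n, seS = se,
       withinTwoSE = abs(di$meanInterval - spec$meanInterval) <= 2 * se,
       bypassExact = isTRUE(all.equal(bypass$intervals, truthIv,
                                      tolerance = 1e-12)))
}

#' Recruitment-kinetics recovery study
#'
#' Fits the saturating-binding model on a noise-free stack (exactness
#' check) and on `nNoisy` noisy stacks at the requested pixel signal-to-
#' noise ratio (bias check).
#'
#' @param seed RNG seed
#' @param tau planted time constant (s)
#' @param snr peak-amplitude-to-noise-sd ratio for the noisy stacks
#' @param nNoisy number of noisy replicate stacks
#' @return list with `tauErrorNoiseFreePct`, `tauBiasNoisyPct`, `tauS`
#' @export
kineticsRecoveryStudy <- function(seed = 1L, tau = 60, snr = 10,
                                  nNoisy = 6L) {
  withSeed(seed, {
    clean <- punctaSpec(nSpots = 10L, poissonGain = 0, readNoiseSd = 0,
                        seed = sample.int(.Machine$integer.max, 1L))
    k0 <- generateRecruitmentStack(kineticsSpec(tau = tau,
                                                seed = sample.int(1e8, 1L)),
                                   clean)
    tau0 <- recruitmentCurve(k0$image, channel = "protein")$tau
    noisy <- punctaSpec(nSpots = 10L, poissonGain = 0,
                        readNoiseSd = 150 / snr)
    taus <- vapply(seq_len(nNoisy), function(i) {
      k <- generateRecruitmentStack(
        kineticsSpec(tau = tau, seed = sample.int(1e8, 1L)), noisy)
      recruitmentCurve(k$image, channel = "protein")$tau
    }, numeric(1))
    list(tauErrorNoiseFreePct = 100 * abs(tau0 / tau - 1),
         tauBiasNoisyPct = 100 * (mean(taus) / tau - 1),
         tauS = tau)
  })
}

#' Type-I error study for the implemented tests
#'
#' Simulated null: both groups drawn from the same normal distribution;
#' the rejection rate at alpha = 0.05 is reported with its binomial
#' confidence band.
#'
#' @param nReps simulation replicates
#' @param seed RNG seed
#' @param nPerGroup group size
#' @return list with `welchTypeI`, `anovaTypeI`, `ciLow`, `ciHigh`, `nReps`
#' @export
typeIErrorStudy <- function(nReps = 10000L, seed = 1L, nPerGroup = 12L) {
  withSeed(seed, {
    welchRej <- vapply(seq_len(nReps), function(i) {
      welchTTest(stats::rnorm(nPerGroup), stats::rnorm(nPerGroup))$p < 0.05
    }, logical(1))
    g <- rep(c("a", "b", "c"), each = nPerGroup)
    anovaRej <- vapply(seq_len(nReps), function(i) {
      anovaDunnett(stats::rnorm(3 * nPerGroup), g, "a")$anova$p < 0.05
    }, logical(1))
    half <- 1.96 * sqrt(0.05 * 0.95 / nReps)
    list(welchTypeI = mean(welchRej), anovaTypeI = mean(anovaRej),
         ciLow = 0.05 - half, ciHigh = 0.05 + half, nReps = nReps)
  })
}
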