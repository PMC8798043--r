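# Synthetic-data generators. Every generator returns machine-readable
# ground truth alongside the data, so each analysis stage can be tested
# against planted truth, and is bit-reproducible for a fixed spec + seed.

withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic puncta image
#'
#' Punctate bright spots on a membrane background. Spots are radially
#' symmetric smooth bumps (a disc edge smoothed by `edgeSigmaPx`); their
#' planted "radius" is the radius of the disc at half maximum, matching the
#' detector's equivalent-disc convention. Defaults plant a population whose
#' mean half-max disc area `E[pi r^2] = pi (mu^2 + sigma^2)` is 0.067 um^2
#' at 0.05 um/px, the magnitude typical of sub-micrometric membrane protein
#' assemblies.
#'
#' @param shape image shape `(ny, nx)` in px
#' @param pixelSize um/px
#' @param nSpots number of planted spots
#' @param radiusMeanUm,radiusSdUm truncated-normal radius distribution (um)
#' @param radiusMinUm,radiusMaxUm truncation bounds for the radii; the lower
#'   bound defaults to 1 px
#' @param peakMean,peakSd truncated-normal peak-amplitude distribution
#'   (above background)
#' @param peakMin lower truncation for the peaks (defaults to
#'   `peakMean / 10`)
#' @param background protein-channel background level
#' @param membraneLevel uniform membrane-channel level
#' @param poissonGain photons per intensity unit for shot noise (0 disables)
#' @param readNoiseSd additive zero-mean Gaussian read noise sd (0 disables)
#' @param edgeSigmaPx edge smoothing of the bump profile in px
#' @param minSeparationPx extra center-to-center clearance beyond the sum of
#'   radii when placing without overlap
#' @param allowOverlap place centers uniformly without the clearance check
#' @param seed RNG seed (NULL leaves the RNG state alone)
#' @return list of class `PunctaSpec`
#' @export
punctaSpec <- function(shape = c(256L, 256L), pixelSize = 0.05, nSpots = 20L,
                       radiusMeanUm = sqrt(0.067 / pi - 0.03^2),
                       radiusSdUm = 0.03,
                       radiusMinUm = NULL, radiusMaxUm = Inf,
                       peakMean = 150, peakSd = 30, peakMin = NULL,
                       background = 20, membraneLevel = 100, poissonGain = 1,
                       readNoiseSd = 15, edgeSigmaPx = 0.5,
                       minSeparationPx = 3, allowOverlap = FALSE,
                       seed = NULL) {
  if (is.null(radiusMinUm)) radiusMinUm <- pixelSize
  if (is.null(peakMin)) peakMin <- peakMean / 10
  stopifnot(pixelSize > 0, nSpots >= 0, radiusMeanUm > 0, readNoiseSd >= 0,
            poissonGain >= 0, radiusMinUm > 0, radiusMaxUm > radiusMinUm)
  structure(as.list(environment()), class = "PunctaSpec")
}

# half-maximum-disc bump: 1 inside, 0 outside, smooth edge; half max at rho=R
bumpProfile <- function(rho, R, edgeSigma) stats::pnorm((R - rho) / edgeSigma)

addBump <- function(plane, cy, cx, R, amp, edgeSigma) {
  ext <- ceiling(R + 4 * edgeSigma)
  y0 <- max(0, round(cy) - ext); y1 <- min(nrow(plane) - 1, round(cy) + ext)
  x0 <- max(0, round(cx) - ext); x1 <- min(ncol(plane) - 1, round(cx) + ext)
  yy <- y0:y1; xx <- x0:x1
  rho <- sqrt(outer((yy - cy)^2, (xx - cx)^2, "+"))
  plane[yy + 1, xx + 1] <- plane[yy + 1, xx + 1] +
    amp * bumpProfile(rho, R, edgeSigma)
  plane
}

applyNoise <- function(plane, poissonGain, readNoiseSd) {
  if (poissonGain > 0)
    plane <- matrix(stats::rpois(length(plane), poissonGain * plane) /
                      poissonGain, nrow(plane), ncol(plane))
  if (readNoiseSd > 0)
    plane <- plane + matrix(stats::rnorm(length(plane), 0, readNoiseSd),
                            nrow(plane), ncol(plane))
  pmax(plane, 0)
}

# rejection-sampled non-overlapping centers; bounded retries
placeCenters <- function(shape, radiiPx, minSep, allowOverlap,
                         maxTries = 2000L) {
  n <- length(radiiPx)
  ys <- xs <- numeric(n)
  for (i in seq_len(n)) {
    margin <- ceiling(radiiPx[i]) + 4
    if (2 * margin >= min(shape))
      stop("placement error: spot of radius ", radiiPx[i],
           " px does not fit inside the image")
    ok <- FALSE
    for (try in seq_len(maxTries)) {
      cy <- stats::runif(1, margin, shape[1L] - 1 - margin)
      cx <- stats::runif(1, margin, shape[2L] - 1 - margin)
      if (allowOverlap || i == 1L ||
          all(sqrt((ys[seq_len(i - 1)] - cy)^2 +
                   (xs[seq_len(i - 1)] - cx)^2) >=
              radiiPx[seq_len(i - 1)] + radiiPx[i] + minSep)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("placement error: could not place ", n,
                  " non-overlapping spots after ", maxTries, " retries")
    ys[i] <- cy; xs[i] <- cx
  }
  cbind(y = ys, x = xs)
}

#' Generate a synthetic puncta image with ground truth
#'
#' @param spec a [punctaSpec()]
#' @return list with `image` (two-channel [ImageStack-class]: `membrane`,
#'   `protein`) and `truth` (a [SpotSet-class] of planted centers, radii,
#'   areas and peaks)
#' @export
generatePunctaImage <- function(spec) {
  stopifnot(inherits(spec, "PunctaSpec"))
  withSeed(spec$seed, {
    n <- spec$nSpots
    rUm <- numeric(0)
    if (n > 0) {
      rUm <- stats::rnorm(n, spec$radiusMeanUm, spec$radiusSdUm)
      bad <- rUm < spec$radiusMinUm | rUm > spec$radiusMaxUm
      while (any(bad)) {
        rUm[bad] <- stats::rnorm(sum(bad), spec$radiusMeanUm, spec$radiusSdUm)
        bad <- rUm < spec$radiusMinUm | rUm > spec$radiusMaxUm
      }
    }
    rPx <- rUm / spec$pixelSize
    peaks <- numeric(0)
    if (n > 0) {
      peaks <- stats::rnorm(n, spec$peakMean, spec$peakSd)
      while (any(peaks < spec$peakMin))
        peaks[peaks < spec$peakMin] <-
          stats::rnorm(sum(peaks < spec$peakMin), spec$peakMean, spec$peakSd)
    }
    centers <- if (n > 0)
      placeCenters(spec$shape, rPx, spec$minSeparationPx, spec$allowOverlap)
      else cbind(y = numeric(0), x = numeric(0))
    protein <- matrix(spec$background, spec$shape[1L], spec$shape[2L])
    for (i in seq_len(n))
      protein <- addBump(protein, centers[i, 1L], centers[i, 2L], rPx[i],
                         peaks[i], spec$edgeSigmaPx)
    membrane <- matrix(spec$membraneLevel, spec$shape[1L], spec$shape[2L])
    protein <- applyNoise(protein, spec$poissonGain, spec$readNoiseSd)
    membrane <- applyNoise(membrane, spec$poissonGain, spec$readNoiseSd)
    px <- array(0, c(1L, 2L, spec$shape))
    px[1L, 1L, , ] <- membrane
    px[1L, 2L, , ] <- protein
    img <- ImageStack(px, spec$pixelSize,
                      channelLabels = c("membrane", "protein"))
    truth <- if (n > 0) {
      data.frame(y = centers[, 1L], x = centers[, 2L],
                 radiusPx = rPx, scaleIdx = NA_integer_,
                 response = NA_real_,
                 areaUm2 = pi * rUm^2, nMerged = 1L, peak = peaks)
    } else {
      cbind(emptySpotFrame(), data.frame(peak = numeric(0)))
    }
    list(image = img, truth = SpotSet(truth, spec$pixelSize,
                                      provenance = list(generator = "puncta")))
  })
}

#' Specification of recruitment (binding) kinetics
#'
#' Saturating first-order binding: mean protein signal follows
#' `plateau * (1 - exp(-t / tau))`, reaching steady state (95% of plateau)
#' within `tSteadyState`. Defaults reach steady state well under 4 minutes.
#'
#' @param plateau steady-state mean gray value of the protein channel
#' @param tau rise time constant in s (0 = instant)
#' @param tSteadyState nominal steady-state time in s (must be >=
#'   `3 * tau`)
#' @param frameInterval s/frame
#' @param nFrames number of frames
#' @param seed RNG seed
#' @return list of class `KineticsSpec`
#' @export
kineticsSpec <- function(plateau = 100, tau = 60, tSteadyState = 240,
                         frameInterval = 5, nFrames = 96L, seed = NULL) {
  stopifnot(tau >= 0, plateau >= 0, frameInterval > 0, nFrames >= 2,
            tSteadyState >= 3 * tau)
  structure(as.list(environment()), class = "KineticsSpec")
}

#' Generate a recruitment time-lapse stack
#'
#' Renders the puncta pattern of `puncta` scaled in time so the protein
#' channel's mean gray value follows `plateau * (1 - exp(-t / tau))`, plus
#' the puncta spec's noise model; membrane channel constant.
#'
#' @param spec a [kineticsSpec()]
#' @param puncta a [punctaSpec()] providing the spatial pattern and noise
#' @return list with `image` ([ImageStack-class]) and `truth` (list with the
#'   planted `plateau`, `tau`, times, and the puncta truth)
#' @export
generateRecruitmentStack <- function(spec, puncta = punctaSpec()) {
  stopifnot(inherits(spec, "KineticsSpec"))
  if (spec$nFrames * spec$frameInterval <= spec$tSteadyState)
    stop("stack duration must exceed the steady-state time")
  withSeed(spec$seed, {
    base <- puncta
    base$poissonGain <- 0
    base$readNoiseSd <- 0
    base$seed <- NULL
    clean <- generatePunctaImage(base)
    pattern <- getPlane(clean$image, 1L, "protein")
    pattern <- pattern / mean(pattern)  # unit mean gray value
    times <- (seq_len(spec$nFrames) - 1L) * spec$frameInterval
    ramp <- if (spec$tau == 0) rep(1, spec$nFrames) else
      1 - exp(-times / spec$tau)
    px <- array(0, c(spec$nFrames, 2L, puncta$shape))
    for (f in seq_len(spec$nFrames)) {
      px[f, 1L, , ] <- applyNoise(
        matrix(puncta$membraneLevel, puncta$shape[1L], puncta$shape[2L]),
        puncta$poissonGain, puncta$readNoiseSd)
      px[f, 2L, , ] <- applyNoise(spec$plateau * ramp[f] * pattern,
                                  puncta$poissonGain, puncta$readNoiseSd)
    }
    img <- ImageStack(px, puncta$pixelSize, spec$frameInterval,
                      c("membrane", "protein"))
    list(image = img,
         truth = list(plateau = spec$plateau, tau = spec$tau, times = times,
                      puncta = clean$truth))
  })
}

#' Specification of a synthetic AFM height map
#'
#' A tilted plane bearing flat-topped disc patches of known height and
#' area, plus Gaussian roughness. Defaults plant patches of 0.005 um^2 and
#' 47 nm, the magnitudes of membrane-bound protein clusters.
#'
#' @param shape map shape in px
#' @param pixelSize nm/px
#' @param tilt plane tilt `(nm/px in y, nm/px in x)`
#' @param nPatches number of patches
#' @param patchHeightNm patch heights in nm (recycled across patches)
#' @param patchAreaUm2 patch areas in um^2 (recycled)
#' @param roughnessSd Gaussian surface roughness sd in nm (must be smaller
#'   than the patch height)
#' @param setpointLabel setpoint-force label carried by the map
#' @param seed RNG seed
#' @return list of class `AfmSpec`
#' @export
afmSpec <- function(shape = c(256L, 256L), pixelSize = 4, tilt = c(0.05, 0.08),
                    nPatches = 3L, patchHeightNm = 47, patchAreaUm2 = 0.005,
                    roughnessSd = 1, setpointLabel = "low", seed = NULL) {
  stopifnot(pixelSize > 0, all(patchHeightNm > roughnessSd), nPatches >= 0,
            all(patchAreaUm2 > 0), roughnessSd >= 0)
  structure(as.list(environment()), class = "AfmSpec")
}

#' Generate a synthetic AFM height map with ground truth
#'
#' @param spec an [afmSpec()]
#' @return list with `map` ([HeightMap-class]) and `truth` (data.frame of
#'   patch centers, planted heights in nm, and rendered areas in um^2)
#' @export
generateHeightMap <- function(spec) {
  stopifnot(inherits(spec, "AfmSpec"))
  withSeed(spec$seed, {
    n <- spec$nPatches
    hts <- rep_len(spec$patchHeightNm, max(n, 1L))[seq_len(n)]
    areas <- rep_len(spec$patchAreaUm2, max(n, 1L))[seq_len(n)]
    rPx <- sqrt(areas * 1e6 / spec$pixelSize^2 / pi)
    if (any(2 * rPx >= min(spec$shape)))
      stop("placement error: patch larger than the map")
    z <- outer((seq_len(spec$shape[1L]) - 1) * spec$tilt[1L],
               (seq_len(spec$shape[2L]) - 1) * spec$tilt[2L], "+")
    centers <- if (n > 0) placeCenters(spec$shape, rPx, 6, FALSE)
               else cbind(y = numeric(0), x = numeric(0))
    renderedPx <- integer(n)
    for (i in seq_len(n)) {
      m <- discPixelMask(spec$shape, centers[i, 1L], centers[i, 2L], rPx[i])
      renderedPx[i] <- sum(m)
      z[m] <- z[m] + hts[i]
    }
    if (spec$roughnessSd > 0)
      z <- z + matrix(stats::rnorm(length(z), 0, spec$roughnessSd),
                      spec$shape[1L], spec$shape[2L])
    truth <- data.frame(y = centers[, 1L], x = centers[, 2L],
                        heightNm = hts,
                        areaUm2 = renderedPx * (spec$pixelSize * 1e-3)^2,
                        radiusPx = rPx)
    list(map = HeightMap(z, spec$pixelSize, spec$setpointLabel),
         truth = truth)
  })
}

#' Specification of a docking-event movie
#'
#' Particles (single proteins) dock at renewal-process times and persist;
#' the default inter-event distribution is exponential, with gamma available
#' to emulate overdispersed intervals. Defaults use a mean interval of
#' 115 s and 32 nm particles.
#'
#' @param meanInterval mean inter-event interval in s
#' @param distribution `"exponential"` or `"gamma"`
#' @param gammaShape shape parameter when `distribution = "gamma"`
#' @param particleDiameterNm docked-particle footprint diameter in nm
#' @param particleHeightNm docked-particle height in nm
#' @param shape movie frame shape in px
#' @param pixelSize nm/px
#' @param nFrames,frameInterval movie length and s/frame
#' @param roughnessSd per-frame Gaussian noise sd in nm
#' @param seed RNG seed
#' @return list of class `DockingSpec`
#' @export
dockingSpec <- function(meanInterval = 115, distribution = "exponential",
                        gammaShape = (115 / 94)^2, particleDiameterNm = 32,
                        particleHeightNm = 3, shape = c(160L, 160L),
                        pixelSize = 8, nFrames = 600L, frameInterval = 20,
                        roughnessSd = 0.2, seed = NULL) {
  stopifnot(meanInterval > 0, particleDiameterNm > 0, frameInterval > 0,
            distribution %in% c("exponential", "gamma"))
  structure(as.list(environment()), class = "DockingSpec")
}

#' Generate a docking movie with ground-truth events
#'
#' @param spec a [dockingSpec()]
#' @return list with `movie` ([HeightMovie-class]) and `truth` (data.frame
#'   of event times (s) and positions; `attr(truth, "intervals")` holds the
#'   drawn inter-event intervals)
#' @export
generateDockingMovie <- function(spec) {
  stopifnot(inherits(spec, "DockingSpec"))
  withSeed(spec$seed, {
    duration <- spec$nFrames * spec$frameInterval
    nDraw <- max(10L, ceiling(2.5 * duration / spec$meanInterval))
    iv <- if (spec$distribution == "exponential")
      stats::rexp(nDraw, 1 / spec$meanInterval)
    else stats::rgamma(nDraw, shape = spec$gammaShape,
                       scale = spec$meanInterval / spec$gammaShape)
    times <- cumsum(iv)
    while (times[length(times)] <= duration) {
      iv2 <- if (spec$distribution == "exponential")
        stats::rexp(nDraw, 1 / spec$meanInterval)
      else stats::rgamma(nDraw, shape = spec$gammaShape,
                         scale = spec$meanInterval / spec$gammaShape)
      iv <- c(iv, iv2); times <- cumsum(iv)
    }
    keep <- times <= duration
    times <- times[keep]
    n <- length(times)
    rPx <- spec$particleDiameterNm / 2 / spec$pixelSize
    centers <- if (n > 0) placeCenters(spec$shape, rep(rPx, n), 2, FALSE)
               else cbind(y = numeric(0), x = numeric(0))
    frames <- array(0, c(spec$nFrames, spec$shape))
    frameTimes <- (seq_len(spec$nFrames) - 1L) * spec$frameInterval
    masks <- lapply(seq_len(n), function(i)
      discPixelMask(spec$shape, centers[i, 1L], centers[i, 2L], rPx))
    for (f in seq_len(spec$nFrames)) {
      z <- matrix(0, spec$shape[1L], spec$shape[2L])
      vis <- which(times <= frameTimes[f])
      for (i in vis) z[masks[[i]]] <- z[masks[[i]]] + spec$particleHeightNm
      if (spec$roughnessSd > 0)
        z <- z + matrix(stats::rnorm(length(z), 0, spec$roughnessSd),
                        spec$shape[1L], spec$shape[2L])
      frames[f, , ] <- z
    }
    truth <- data.frame(time = times, y = centers[, 1L], x = centers[, 2L])
    # the drawn sample of inter-event intervals (successive differences)
    attr(truth, "intervals") <- diff(times)
    list(movie = HeightMovie(frames, spec$pixelSize, spec$frameInterval),
         truth = truth)
  })
}

#' Specification of a nano-dome profile image
#'
#' Radially symmetric nano-domes of radius `radiusNm` carrying a reference
#' (lipid) channel and a protein channel whose lateral profile is uniform,
#' rim-enriched (Gaussian ring of width `rimWidthNm` at the dome radius), or
#' excluded from the dome footprint. Default dome radius 150 nm.
#'
#' @param radiusNm dome radius R in nm
#' @param profile `"uniform"`, `"rim"` or `"excluded"`
#' @param enrichment peak protein enrichment factor at the rim (rim profile)
#' @param exclusionLevel residual protein fraction on the footprint
#'   (excluded profile)
#' @param rimWidthNm Gaussian rim width in nm
#' @param shape image shape in px
#' @param pixelSize nm/px
#' @param nDomes number of domes laid out on a grid
#' @param referenceLevel,proteinLevel baseline channel intensities
#' @param noiseSd additive Gaussian noise sd (0 disables)
#' @param seed RNG seed
#' @return list of class `DomeSpec`
#' @export
domeSpec <- function(radiusNm = 150, profile = "uniform", enrichment = 2,
                     exclusionLevel = 0.2, rimWidthNm = 50,
                     shape = c(256L, 256L), pixelSize = 20, nDomes = 20L,
                     referenceLevel = 100, proteinLevel = 100, noiseSd = 0,
                     seed = NULL) {
  stopifnot(radiusNm > 0, profile %in% c("uniform", "rim", "excluded"),
            nDomes >= 1)
  structure(as.list(environment()), class = "DomeSpec")
}

#' Generate a nano-dome two-channel image
#'
#' @param spec a [domeSpec()]
#' @return list with `image` (two-channel [ImageStack-class]: `reference`,
#'   `protein`), `centers` (data.frame, 0-based px) and `radiusPx`
#' @export
generateDomeImage <- function(spec) {
  stopifnot(inherits(spec, "DomeSpec"))
  withSeed(spec$seed, {
    Rpx <- spec$radiusNm / spec$pixelSize
    wPx <- spec$rimWidthNm / spec$pixelSize
    pitch <- ceiling(2 * (Rpx + 3 * wPx) + 4)
    perRow <- floor((spec$shape[2L] - pitch) / pitch) + 1L
    if (perRow < 1) stop("dome does not fit in the field")
    idx <- seq_len(spec$nDomes) - 1L
    cy <- pitch / 2 + (idx %/% perRow) * pitch
    cx <- pitch / 2 + (idx %% perRow) * pitch
    if (any(cy + Rpx + 3 * wPx > spec$shape[1L] - 1))
      stop("too many domes for the field")
    ref <- matrix(spec$referenceLevel, spec$shape[1L], spec$shape[2L])
    prot <- matrix(spec$proteinLevel, spec$shape[1L], spec$shape[2L])
    for (i in seq_along(cy)) {
      ext <- ceiling(Rpx + 3 * wPx) + 2
      yy <- max(0, round(cy[i]) - ext):min(spec$shape[1L] - 1, round(cy[i]) + ext)
      xx <- max(0, round(cx[i]) - ext):min(spec$shape[2L] - 1, round(cx[i]) + ext)
      rho <- sqrt(outer((yy - cy[i])^2, (xx - cx[i])^2, "+"))
      mod <- switch(spec$profile,
        uniform = matrix(1, length(yy), length(xx)),
        rim = 1 + (spec$enrichment - 1) * exp(-(rho - Rpx)^2 / (2 * wPx^2)),
        excluded = spec$exclusionLevel + (1 - spec$exclusionLevel) *
          stats::pnorm((rho - Rpx) / max(wPx / 2, 0.5)))
      prot[yy + 1, xx + 1] <- spec$proteinLevel * mod
    }
    if (spec$noiseSd > 0) {
      ref <- pmax(ref + stats::rnorm(length(ref), 0, spec$noiseSd), 0)
      prot <- pmax(prot + stats::rnorm(length(prot), 0, spec$noiseSd), 0)
    }
    px <- array(0, c(1L, 2L, spec$shape))
    px[1L, 1L, , ] <- ref
    px[1L, 2L, , ] <- prot
    list(image = ImageStack(px, spec$pixelSize * 1e-3,
                            channelLabels = c("reference", "protein")),
         centers = data.frame(y = cy, x = cx), radiusPx = Rpx)
  })
}
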