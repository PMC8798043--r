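# Scale-space spot detector: LoG filter bank over a list of blob radii,
# starting points from minima of the across-scale minimum projection (and of
# the smallest scale), a cross-scale linking walk per starting point, and
# area-overlap merging of the resulting spots.

#' Detection parameters
#'
#' @param scales blob radii in px, strictly ascending. Default: geometric
#'   series covering 2-20 px at ratio sqrt(2).
#' @param noiseTolerance minimum `|response|` (scale-normalized LoG units)
#'   for a starting point, or `"auto"` for `autoK` times a robust
#'   (median-absolute-deviation) noise estimate of the smallest-scale
#'   response plane. The manual value mirrors per-series hand tuning.
#' @param autoK multiplier for the automatic tolerance (default 5).
#' @param overlapMergeFraction two spots are merged when at least this
#'   fraction of the surface of one is covered by the other (default 0.20).
#' @param minArea,maxArea optional area filter in um^2 applied post-merge.
#' @return a list of class `DetectionParams`
#' @export
detectionParams <- function(scales = geomScales(), noiseTolerance = "auto",
                            autoK = 5, overlapMergeFraction = 0.20,
                            minArea = NULL, maxArea = NULL) {
  if (any(scales <= 0) || is.unsorted(scales, strictly = TRUE))
    stop("scales must be strictly ascending and > 0")
  if (!(identical(noiseTolerance, "auto") ||
        (is.numeric(noiseTolerance) && noiseTolerance >= 0)))
    stop("noiseTolerance must be 'auto' or a number >= 0")
  if (overlapMergeFraction <= 0 || overlapMergeFraction > 1)
    stop("overlapMergeFraction must be in (0, 1]")
  structure(list(scales = scales, noiseTolerance = noiseTolerance,
                 autoK = autoK, overlapMergeFraction = overlapMergeFraction,
                 minArea = minArea, maxArea = maxArea),
            class = "DetectionParams")
}

#' Geometric scale series
#'
#' @param from,to smallest and largest radius in px
#' @param ratio ratio between consecutive radii
#' @return ascending radii covering `[from, to]` (the endpoint is appended
#'   when the series does not land on it)
#' @export
geomScales <- function(from = 2, to = 20, ratio = sqrt(2)) {
  k <- floor(log(to / from) / log(ratio) + 1e-9)
  s <- from * ratio^(0:k)
  if (s[length(s)] < to * (1 - 1e-9)) s <- c(s, to)
  s
}

# Scale-normalized LoG kernel for blob radius r = sqrt(2) * sigma.
# sigma^2 * Laplacian-of-Gaussian; the kernel is recentred to sum exactly to
# zero so constant images give exactly zero response (and detection is
# invariant under additive offsets). Bright blobs yield negative responses.
logKernel <- function(sigma) {
  h <- max(3L, ceiling(4 * sigma))
  g <- seq(-h, h)
  rho2 <- outer(g^2, g^2, "+")
  k <- (rho2 - 2 * sigma^2) / (2 * pi * sigma^4) * exp(-rho2 / (2 * sigma^2))
  k - mean(k)
}

#' Build a LoG scale space
#'
#' Filters one 2-d plane with a scale-normalized Laplacian-of-Gaussian at
#' each requested blob radius (`sigma = r / sqrt(2)`). Responses are
#' comparable across scales; bright blobs appear as negative minima at the
#' scale matching their radius.
#'
#' @param plane numeric matrix `(y, x)`
#' @param scales blob radii in px, ascending
#' @return a [ScaleSpace-class]
#' @export
buildScaleSpace <- function(plane, scales) {
  plane <- as.matrix(plane)
  if (any(scales <= 0) || is.unsorted(scales, strictly = TRUE))
    stop("scales must be strictly ascending and > 0")
  resp <- array(0, c(length(scales), nrow(plane), ncol(plane)))
  for (i in seq_along(scales)) {
    k <- logKernel(scales[i] / sqrt(2))
    if (nrow(k) > nrow(plane) || ncol(k) > ncol(plane))
      stop(sprintf(
        "image (%d x %d) smaller than the LoG kernel support (%d px) at radius %.3g",
        nrow(plane), ncol(plane), nrow(k), scales[i]))
    resp[i, , ] <- EBImage::filter2(plane, k, boundary = "replicate")
  }
  new("ScaleSpace", responses = resp, scales = as.numeric(scales))
}

# Strict local minima in the 8-neighborhood; the one-pixel border is
# excluded (no full neighborhood there). Returns a logical matrix.
localMinima2d <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  p <- matrix(Inf, ny + 2L, nx + 2L)
  p[2:(ny + 1L), 2:(nx + 1L)] <- m
  res <- matrix(TRUE, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    res <- res & (m < p[2:(ny + 1L) + dy, 2:(nx + 1L) + dx])
  }
  res[c(1L, ny), ] <- FALSE
  res[, c(1L, nx)] <- FALSE
  res
}

#' Find starting points in a scale space
#'
#' Starting points are strict 8-neighborhood local minima of the pixel-wise
#' minimum projection across scales, united with local minima of the
#' smallest-scale plane. Candidates whose `|response|` (taken on the minimum
#' projection) falls below the noise tolerance are discarded; duplicates are
#' collapsed.
#'
#' @param scaleSpace a [ScaleSpace-class]
#' @param noiseTolerance numeric threshold or `"auto"` (see
#'   [detectionParams()])
#' @param autoK multiplier for the automatic tolerance
#' @return data.frame with columns `y`, `x` (0-based px) and `response`
#' @export
findStartingPoints <- function(scaleSpace, noiseTolerance = "auto",
                               autoK = 5) {
  resp <- scaleSpace@responses
  minProj <- resp[1L, , ]
  if (dim(resp)[1L] > 1L) {
    for (i in 2:dim(resp)[1L]) minProj <- pmin(minProj, resp[i, , ])
  }
  smallest <- resp[1L, , ]
  if (identical(noiseTolerance, "auto")) {
    # floor keeps numerical dust out of noise-free images, where the MAD
    # estimate collapses to zero
    noiseTolerance <- max(autoK * robustSd(as.vector(smallest)),
                          1e-8 * max(abs(minProj)))
  }
  cand <- localMinima2d(minProj) | localMinima2d(smallest)
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(y = numeric(0), x = numeric(0), response = numeric(0)))
  val <- minProj[idx]
  keep <- val < 0 & (-val) >= noiseTolerance
  idx <- idx[keep, , drop = FALSE]
  data.frame(y = idx[, 1L] - 1, x = idx[, 2L] - 1, response = minProj[idx])
}

#' Link a starting point across scales
#'
#' Walks the scales in ascending order; at each scale, searches for the
#' response minimum within the current spot radius of the current position
#' and moves there. The spot is assigned the scale with the most negative
#' visited response; its radius is that scale's radius.
#'
#' @param candidate numeric `(y, x)` starting position (0-based px)
#' @param scaleSpace a [ScaleSpace-class]
#' @return one-row data.frame: `y`, `x`, `radiusPx`, `scaleIdx`, `response`
#' @export
linkScales <- function(candidate, scaleSpace) {
  resp <- scaleSpace@responses
  scales <- scaleSpace@scales
  ny <- dim(resp)[2L]; nx <- dim(resp)[3L]
  py <- candidate[[1L]]; px <- candidate[[2L]]
  best <- Inf; bestScale <- 1L; bestY <- py; bestX <- px
  for (s in seq_along(scales)) {
    r <- scales[s]
    y0 <- max(0, floor(py - r)); y1 <- min(ny - 1, ceiling(py + r))
    x0 <- max(0, floor(px - r)); x1 <- min(nx - 1, ceiling(px + r))
    win <- resp[s, (y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]
    win <- matrix(win, y1 - y0 + 1L, x1 - x0 + 1L)
    yy <- y0:y1; xx <- x0:x1
    inDisc <- outer((yy - py)^2, (xx - px)^2, "+") <= r^2
    win[!inDisc] <- Inf
    m <- which.min(win)
    my <- yy[(m - 1L) %% nrow(win) + 1L]
    mx <- xx[(m - 1L) %/% nrow(win) + 1L]
    v <- resp[s, my + 1L, mx + 1L]
    py <- my; px <- mx
    if (v < best) {
      best <- v; bestScale <- s; bestY <- my; bestX <- mx
    }
  }
  if (!is.finite(best)) { # flat scale space: stay at the start, smallest scale
    best <- resp[1L, candidate[[1L]] + 1L, candidate[[2L]] + 1L]
    bestScale <- 1L; bestY <- candidate[[1L]]; bestX <- candidate[[2L]]
  }
  data.frame(y = bestY, x = bestX, radiusPx = scales[bestScale],
             scaleIdx = bestScale, response = best)
}

#' Merge overlapping spots
#'
#' Two spots are merged when the disc of one covers at least
#' `overlapMergeFraction` of the surface of the other (lens area over the
#' smaller disc's area, computed analytically). Merging is transitively
#' closed via a disjoint-set structure and iterated until no pair satisfies
#' the criterion, so the output respects the post-merge invariant. A merged
#' group becomes one spot at the response-weighted center; its area is the
#' union of the member discs and its radius the equivalent-disc radius.
#'
#' @param spotFrame data.frame with `y`, `x`, `radiusPx`, `response`
#'   (a [SpotSet-class] is also accepted)
#' @param overlapMergeFraction merge threshold in `(0, 1]` (default 0.20)
#' @param pixelSize um/px, used to express merged areas in um^2
#' @return data.frame of merged spots (or a [SpotSet-class] when one was
#'   supplied)
#' @export
mergeOverlapping <- function(spotFrame, overlapMergeFraction = 0.20,
                             pixelSize = 1) {
  if (overlapMergeFraction <= 0 || overlapMergeFraction > 1)
    stop("overlapMergeFraction must be in (0, 1]")
  asSet <- is(spotFrame, "SpotSet")
  if (asSet) {
    setObj <- spotFrame
    pixelSize <- setObj@pixelSize
    spotFrame <- setObj@spots
  }
  df <- as.data.frame(spotFrame)
  if (!"response" %in% names(df)) df$response <- rep(-1, nrow(df))
  if (!"nMerged" %in% names(df)) df$nMerged <- rep(1L, nrow(df))
  if (!"areaPx" %in% names(df)) df$areaPx <- pi * df$radiusPx^2
  if (!"scaleIdx" %in% names(df)) df$scaleIdx <- rep(NA_integer_, nrow(df))
  repeat {
    n <- nrow(df)
    if (n < 2L) break
    parent <- seq_len(n)
    any_merge <- FALSE
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      f <- discOverlapFraction(df$y[i], df$x[i], df$radiusPx[i],
                               df$y[j], df$x[j], df$radiusPx[j])
      if (f >= overlapMergeFraction - 1e-9) {
        ri <- dsuFind(parent, i); rj <- dsuFind(parent, j)
        if (ri != rj) { parent[max(ri, rj)] <- min(ri, rj); any_merge <- TRUE }
      }
    }
    if (!any_merge) break
    root <- vapply(seq_len(n), function(i) dsuFind(parent, i), integer(1))
    out <- lapply(unique(root), function(g) {
      mem <- df[root == g, , drop = FALSE]
      if (nrow(mem) == 1L) return(mem)
      w <- abs(mem$response)
      if (sum(w) == 0) w <- rep(1, nrow(mem))
      aPx <- discUnionArea(mem$y, mem$x, mem$radiusPx)
      k <- which.min(mem$response)
      data.frame(y = sum(w * mem$y) / sum(w), x = sum(w * mem$x) / sum(w),
                 radiusPx = sqrt(aPx / pi), scaleIdx = mem$scaleIdx[k],
                 response = mem$response[k], areaPx = aPx,
                 nMerged = sum(mem$nMerged))
    })
    df <- do.call(rbind, out)
    rownames(df) <- NULL
  }
  df$areaUm2 <- df$areaPx * pixelSize^2
  df <- df[order(df$y, df$x), , drop = FALSE]
  rownames(df) <- NULL
  df <- df[, c("y", "x", "radiusPx", "scaleIdx", "response", "areaPx",
               "areaUm2", "nMerged")]
  if (asSet) SpotSet(df, pixelSize, setObj@provenance) else df
}

#' @describeIn detectSpots detect on a single calibrated plane. Composition
#'   of [buildScaleSpace()], [findStartingPoints()], [linkScales()] and
#'   [mergeOverlapping()], followed by the optional area filter;
#'   deterministic for fixed inputs.
#' @param pixelSize um/px of the plane
#' @param channelPlanes optional named list of co-registered planes on which
#'   per-spot mean intensities are measured (the detection plane itself is
#'   always measured as `mean_detection`)
#' @export
setMethod("detectSpots", "matrix",
  function(object, params = detectionParams(), pixelSize = 1,
           channelPlanes = NULL, ...) {
    ss <- buildScaleSpace(object, params$scales)
    cand <- findStartingPoints(ss, params$noiseTolerance, params$autoK)
    if (nrow(cand) == 0L) {
      return(SpotSet(emptySpotFrame(), pixelSize,
                     provenance = list(params = params)))
    }
    linked <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i)
      linkScales(c(cand$y[i], cand$x[i]), ss)))
    linked <- unique(linked)
    merged <- mergeOverlapping(linked, params$overlapMergeFraction, pixelSize)
    if (!is.null(params$minArea))
      merged <- merged[merged$areaUm2 >= params$minArea, , drop = FALSE]
    if (!is.null(params$maxArea))
      merged <- merged[merged$areaUm2 <= params$maxArea, , drop = FALSE]
    merged$mean_detection <- spotMeanIntensity(merged, object)
    if (!is.null(channelPlanes)) {
      for (nm in names(channelPlanes)) {
        merged[[paste0("mean_", nm)]] <-
          spotMeanIntensity(merged, channelPlanes[[nm]])
      }
    }
    SpotSet(merged, pixelSize, provenance = list(params = params))
  })

#' @describeIn detectSpots detect on one frame/channel of an [ImageStack-class];
#'   per-spot mean intensities are measured on every channel of that frame.
#' @param frame,channel frame index and detection channel (index or label)
#' @export
setMethod("detectSpots", "ImageStack",
  function(object, params = detectionParams(), frame = 1L, channel = 1L, ...) {
    plane <- getPlane(object, frame, channel)
    others <- stats::setNames(
      lapply(seq_len(nChannels(object)), function(c) getPlane(object, frame, c)),
      channelLabels(object))
    res <- detectSpots(plane, params, pixelSize = pixelSize(object),
                       channelPlanes = others)
    res@provenance <- list(frame = frame, channel = channel, params = params)
    res
  })

# mean intensity of a plane over each spot's rasterized disc footprint
spotMeanIntensity <- function(spotFrame, plane) {
  if (nrow(spotFrame) == 0L) return(numeric(0))
  vapply(seq_len(nrow(spotFrame)), function(i) {
    m <- discPixelMask(dim(plane), spotFrame$y[i], spotFrame$x[i],
                       spotFrame$radiusPx[i])
    if (!any(m)) return(plane[round(spotFrame$y[i]) + 1L,
                              round(spotFrame$x[i]) + 1L])
    mean(plane[m])
  }, numeric(1))
}
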