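# AFM / HS-AFM analysis: first-order plane leveling, cluster segmentation
# with size/height statistics, cross-sections, nearest-neighbor particle
# tracking with an occupancy heat map, particle sizing, and docking-event
# interval statistics.

# least-squares first-order plane z = a + b*y + c*x over unmasked pixels
fitPlaneCoef <- function(z, use) {
  idx <- which(use, arr.ind = TRUE)
  X <- cbind(1, idx[, 1L] - 1, idx[, 2L] - 1)
  stats::lm.fit(X, z[use])$coefficients
}

evalPlane <- function(coef, dim) {
  outer(coef[2L] * (seq_len(dim[1L]) - 1),
        coef[3L] * (seq_len(dim[2L]) - 1), "+") + coef[1L]
}

#' First-order plane leveling of a height map
#'
#' Fits a least-squares plane to the pixels outside the exclusion mask and
#' subtracts it; the fit is iterated a second time with the mask grown by
#' positive outliers (above 3 robust sd), so protruding features do not
#' bias the background plane. The background median is subtracted last, so
#' leveled heights are referenced to the background surface.
#'
#' @param map a [HeightMap-class] (or bare matrix, nm)
#' @param exclusionMask optional logical matrix of pixels to exclude from
#'   the plane fit (e.g. known features)
#' @return leveled [HeightMap-class] (or matrix, matching the input)
#' @export
levelPlane <- function(map, exclusionMask = NULL) {
  isMap <- is(map, "HeightMap")
  z <- if (isMap) heights(map) else as.matrix(map)
  use <- if (is.null(exclusionMask)) matrix(TRUE, nrow(z), ncol(z))
         else !exclusionMask
  if (mean(use) < 0.1)
    stop("insufficient background: exclusion mask covers more than 90% of pixels")
  cf <- fitPlaneCoef(z, use)
  r <- z - evalPlane(cf, dim(z))
  s <- robustSd(r[use])
  use2 <- use & (r <= stats::median(r[use]) + 3 * max(s, 1e-12))
  if (mean(use2) >= 0.1) {
    cf2 <- fitPlaneCoef(z, use2)
    r <- z - evalPlane(cf2, dim(z))
    use <- use2
  }
  r <- r - stats::median(r[use])
  if (isMap) HeightMap(r, pixelSize(map), setpointLabel(map)) else r
}

#' Level every frame of a height movie
#'
#' @param movie a [HeightMovie-class]
#' @return leveled [HeightMovie-class]
#' @export
levelMovie <- function(movie) {
  fr <- movie@frames
  for (f in seq_len(dim(fr)[1L])) fr[f, , ] <- levelPlane(fr[f, , ])
  HeightMovie(fr, pixelSize(movie), frameInterval(movie),
              setpointLabel(movie))
}

#' Segment clusters in a leveled height map
#'
#' Connected components (8-connectivity) of pixels above the height
#' threshold; default threshold is the leveled background (0) plus 5 robust
#' background sd. Heights are measured relative to the leveled background.
#'
#' @param map leveled [HeightMap-class]
#' @param heightThreshold nm; `NULL` for the automatic threshold
#' @param minPixels drop components smaller than this many pixels
#' @param heightStat per-cluster height statistic: `"median"` (default;
#'   unbiased for flat-topped clusters under symmetric roughness) or
#'   `"topDecile"` (mean of the top decile of pixel heights)
#' @return `ClusterTable` data.frame: `label`, `areaUm2`, `heightNm`,
#'   `meanHeightNm`, `maxHeightNm`, `y`, `x` (centroid), `setpoint`
#' @export
segmentClusters <- function(map, heightThreshold = NULL, minPixels = 4L,
                            heightStat = c("median", "topDecile")) {
  heightStat <- match.arg(heightStat)
  z <- heights(map)
  bgSd <- robustSd(as.vector(z))
  if (is.null(heightThreshold)) heightThreshold <- 5 * bgSd
  if (heightThreshold <= 2 * bgSd)
    warning("height threshold is within the background noise floor; ",
            "over-segmentation likely")
  lab <- EBImage::bwlabel(z > heightThreshold)
  n <- max(lab)
  rows <- lapply(seq_len(n), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < minPixels) return(NULL)
    h <- z[idx]
    hs <- switch(heightStat,
                 median = stats::median(h),
                 topDecile = mean(sort(h, decreasing = TRUE)[
                   seq_len(max(1L, ceiling(length(h) / 10)))]))
    data.frame(label = k,
               areaUm2 = nrow(idx) * (pixelSize(map) * 1e-3)^2,
               heightNm = hs, meanHeightNm = mean(h), maxHeightNm = max(h),
               y = mean(idx[, 1L] - 1), x = mean(idx[, 2L] - 1),
               setpoint = setpointLabel(map))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(label = integer(0), areaUm2 = numeric(0),
                      heightNm = numeric(0), meanHeightNm = numeric(0),
                      maxHeightNm = numeric(0), y = numeric(0),
                      x = numeric(0), setpoint = character(0)))
  out <- do.call(rbind, rows)
  out$label <- seq_len(nrow(out))
  out
}

#' Height cross-section along a polyline
#'
#' @param map a [HeightMap-class]
#' @param polyline n x 2 `(y, x)` px vertices
#' @return a [profileCurve()] with positions in nm (a zero-length path
#'   yields a single sample)
#' @export
crossSection <- function(map, polyline) {
  p <- profileAlongPath(heights(map), polyline, width = 1L)
  if (length(p$s) == 1L)
    return(structure(list(positions = p$s * pixelSize(map), mean = p$value,
                          sd = NA_real_, n = 1L, units = "nm"),
                     class = "ProfileCurve"))
  profileCurve(p$s * pixelSize(map), p$value, n = 1L, units = "nm")
}

# per-frame particle centroids above threshold
detectFrameParticles <- function(z, threshold, minPixels = 2L) {
  lab <- EBImage::bwlabel(z > threshold)
  n <- max(lab)
  if (n == 0L) return(data.frame(y = numeric(0), x = numeric(0)))
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[idx]
  cnt <- tabulate(l, n)
  ys <- tapply(idx[, 1L] - 1, l, mean)
  xs <- tapply(idx[, 2L] - 1, l, mean)
  keep <- cnt >= minPixels
  data.frame(y = as.numeric(ys)[keep], x = as.numeric(xs)[keep])
}

#' Track particles through a height movie
#'
#' Per-frame detections (connected components above `detectionThreshold`)
#' are linked frame to frame by greedy nearest-neighbor assignment within
#' `maxLinkDistance`; unmatched detections open new tracks and unmatched
#' tracks close. The occupancy heat map is the time-summed count of track
#' positions per pixel. A detection whose footprint would swallow two or
#' more previous track positions marks a coalescence event.
#'
#' @param movie leveled [HeightMovie-class]
#' @param detectionThreshold nm
#' @param maxLinkDistance px
#' @param minPixels minimum component size in px
#' @return list with `tracks` (data.frame `trackId`, `frame`, `time`, `y`,
#'   `x`), `births` (per track: `trackId`, `birthFrame`, `birthTime`,
#'   `deathFrame`, `kind`), and `heatmap` (matrix)
#' @export
trackParticles <- function(movie, detectionThreshold, maxLinkDistance = 3,
                           minPixels = 2L) {
  nt <- nFrames(movie)
  dt <- frameInterval(movie)
  dimz <- dim(movie@frames)[2:3]
  heat <- matrix(0, dimz[1L], dimz[2L])
  rows <- vector("list", nt)
  lastY <- numeric(0); lastX <- numeric(0); lastId <- integer(0)
  lastSeen <- integer(0)
  nextId <- 1L
  birth <- list()
  linkR <- maxLinkDistance
  for (f in seq_len(nt)) {
    det <- detectFrameParticles(movie@frames[f, , ], detectionThreshold,
                                minPixels)
    nd <- nrow(det)
    assigned <- rep(NA_integer_, nd)
    if (nd && length(lastId)) {
      dmat <- outer(det$y, lastY, "-")^2 + outer(det$x, lastX, "-")^2
      ord <- order(dmat)
      usedD <- rep(FALSE, nd); usedT <- rep(FALSE, length(lastId))
      for (o in ord) {
        if (dmat[o] > linkR^2) break
        i <- (o - 1L) %% nd + 1L
        j <- (o - 1L) %/% nd + 1L
        if (!usedD[i] && !usedT[j]) {
          assigned[i] <- j; usedD[i] <- TRUE; usedT[j] <- TRUE
        }
      }
    }
    newY <- lastY; newX <- lastX
    for (i in seq_len(nd)) {
      j <- assigned[i]
      if (!is.na(j)) {
        id <- lastId[j]
        newY[j] <- det$y[i]; newX[j] <- det$x[i]
        lastSeen[j] <- f
      } else {
        # new track; flag coalescence when >= 2 previous positions sit
        # inside the new detection's neighborhood
        near <- if (length(lastY))
          sum((lastY - det$y[i])^2 + (lastX - det$x[i])^2 <= linkR^2) else 0L
        id <- nextId
        birth[[id]] <- data.frame(
          trackId = id, birthFrame = f, birthTime = (f - 1L) * dt,
          deathFrame = NA_integer_,
          kind = if (near >= 2L) "ring coalescence" else "single")
        nextId <- nextId + 1L
        newY <- c(newY, det$y[i]); newX <- c(newX, det$x[i])
        lastId <- c(lastId, id); lastSeen <- c(lastSeen, f)
      }
      rows[[f]] <- rbind(rows[[f]],
                         data.frame(trackId = id, frame = f,
                                    time = (f - 1L) * dt,
                                    y = det$y[i], x = det$x[i]))
      heat[round(det$y[i]) + 1L, round(det$x[i]) + 1L] <-
        heat[round(det$y[i]) + 1L, round(det$x[i]) + 1L] + 1
    }
    # tracks unmatched in this frame close and cannot be linked to later
    active <- lastSeen == f
    lastY <- newY[active]; lastX <- newX[active]
    lastId <- lastId[active]; lastSeen <- lastSeen[active]
  }
  tracks <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tracks))
    tracks <- data.frame(trackId = integer(0), frame = integer(0),
                         time = numeric(0), y = numeric(0), x = numeric(0))
  births <- if (length(birth)) do.call(rbind, birth) else
    data.frame(trackId = integer(0), birthFrame = integer(0),
               birthTime = numeric(0), deathFrame = integer(0),
               kind = character(0))
  if (nrow(births)) {
    death <- tapply(tracks$frame, tracks$trackId, max)
    births$deathFrame <- as.integer(death[as.character(births$trackId)])
  }
  list(tracks = tracks, births = births, heatmap = heat)
}

#' Particle diameter from the half-maximum footprint
#'
#' Equivalent-disc diameter of the connected region around the centroid
#' whose height exceeds half the particle's maximum height.
#'
#' @param map leveled [HeightMap-class]
#' @param centroid `(y, x)` px of the particle
#' @param searchRadiusPx window radius used to find the particle maximum
#' @param otherCentroids optional `(y, x)` rows of neighboring particles;
#'   the value is flagged ambiguous when the footprint contains one
#' @return list: `diameterNm`, `areaPx`, `flag` (`"ok"`, `"unresolvable"`
#'   when below 2 px, `"ambiguous"` when touching another particle)
#' @export
particleSize <- function(map, centroid, searchRadiusPx = 5,
                         otherCentroids = NULL) {
  z <- heights(map)
  win <- discPixelMask(dim(z), centroid[[1L]], centroid[[2L]], searchRadiusPx)
  hmax <- max(z[win])
  lab <- EBImage::bwlabel(z > hmax / 2)
  k <- lab[round(centroid[[1L]]) + 1L, round(centroid[[2L]]) + 1L]
  if (k == 0L) {
    # centroid between pixels: take the nearest labeled pixel in the window
    idx <- which(lab > 0 & win, arr.ind = TRUE)
    if (nrow(idx) == 0L)
      return(list(diameterNm = NA_real_, areaPx = 0L, flag = "unresolvable"))
    d2 <- (idx[, 1L] - 1 - centroid[[1L]])^2 + (idx[, 2L] - 1 - centroid[[2L]])^2
    k <- lab[idx[which.min(d2), , drop = FALSE]]
  }
  areaPx <- sum(lab == k)
  diamPx <- 2 * sqrt(areaPx / pi)
  flag <- "ok"
  if (diamPx < 2) flag <- "unresolvable"
  if (!is.null(otherCentroids)) {
    oc <- as.matrix(otherCentroids)
    for (i in seq_len(nrow(oc))) {
      if (lab[round(oc[i, 1L]) + 1L, round(oc[i, 2L]) + 1L] == k)
        flag <- "ambiguous"
    }
  }
  list(diameterNm = diamPx * pixelSize(map), areaPx = areaPx, flag = flag)
}

#' Docking-event intervals
#'
#' Event times are track birth times (or a supplied vector of event times /
#' generator truth); intervals are their successive differences.
#'
#' @param x a [trackParticles()] result, its `births` data.frame, or a
#'   numeric vector of event times in s
#' @return `EventTable` list: `times`, `kinds`, `intervals`, `meanInterval`,
#'   `sdInterval`, `n`
#' @export
dockingIntervals <- function(x) {
  if (is.list(x) && !is.null(x$births)) x <- x$births
  if (is.data.frame(x)) {
    ord <- order(x$birthTime %||% x$time)
    times <- (x$birthTime %||% x$time)[ord]
    kinds <- if (!is.null(x$kind)) x$kind[ord] else rep("single", length(times))
  } else {
    times <- sort(as.numeric(x))
    kinds <- rep("single", length(times))
  }
  if (length(times) < 2L)
    stop("insufficient events: need at least 2 docking events")
  iv <- diff(times)
  list(times = times, kinds = kinds, intervals = iv,
       meanInterval = mean(iv), sdInterval = stats::sd(iv),
       n = length(times))
}

#' Cluster height versus setpoint force
#'
#' Mean +/- sd cluster height per setpoint condition and their difference,
#' with a Welch two-sample comparison.
#'
#' @param clustersLow,clustersHigh `ClusterTable` data.frames from
#'   [segmentClusters()] at low and high setpoint force
#' @return list with per-condition summaries, `difference` (low - high, nm)
#'   and `test` (a [welchTTest()] result)
#' @export
heightVsForce <- function(clustersLow, clustersHigh) {
  if (nrow(clustersLow) == 0L || nrow(clustersHigh) == 0L)
    stop("insufficient data: empty cluster table")
  lo <- conditionSummary(clustersLow$heightNm, "low")
  hi <- conditionSummary(clustersHigh$heightNm, "high")
  tst <- if (lo$n >= 2 && hi$n >= 2)
    welchTTest(lo$values, hi$values) else NULL
  list(low = lo, high = hi, difference = lo$mean - hi$mean, test = tst)
}
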