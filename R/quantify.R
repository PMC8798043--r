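# Intensity quantification on detected structures: binding normalization,
# per-spot intensity distributions, cross-condition fold changes, line
# profiles, and nano-dome profile analysis. All normalized quantities are
# invariant under multiplying the image by a constant.

#' Condition summary of per-unit values
#'
#' @param values numeric per-unit measurements
#' @param label condition label
#' @return list of class `ConditionSummary` with `values`, `mean`, `sd`,
#'   `median`, `n`
#' @export
conditionSummary <- function(values, label = "condition") {
  values <- as.numeric(values)
  structure(list(label = label, values = values,
                 mean = if (length(values)) mean(values) else NA_real_,
                 sd = if (length(values) > 1) stats::sd(values) else NA_real_,
                 median = if (length(values)) stats::median(values) else NA_real_,
                 n = length(values)),
            class = "ConditionSummary")
}

#' @export
print.ConditionSummary <- function(x, ...) {
  cat(sprintf("ConditionSummary '%s': n = %d, mean = %.4g, sd = %.4g, median = %.4g\n",
              x$label, x$n, x$mean, x$sd, x$median))
  invisible(x)
}

#' Mean-gray binding normalization
#'
#' Protein binding level as mean gray value of the protein channel divided
#' by the mean gray value of the membrane channel in the same frame,
#' averaged over the frames at or after the steady-state time.
#'
#' @param stack an [ImageStack-class] with both channels
#' @param proteinChannel,membraneChannel channel indices or labels
#' @param steadyStateTime s; default 240 (steady state is reached in under
#'   4 min for the kinetics considered here)
#' @return normalized binding value (dimensionless)
#' @export
normalizedBinding <- function(stack, proteinChannel = "protein",
                              membraneChannel = "membrane",
                              steadyStateTime = 240) {
  nt <- nFrames(stack)
  times <- (seq_len(nt) - 1L) * frameInterval(stack)
  use <- if (nt == 1L) 1L else which(times >= steadyStateTime)
  if (!length(use))
    stop("stack duration (", max(times), " s) is shorter than the ",
         "steady-state time (", steadyStateTime, " s)")
  vals <- vapply(use, function(f) {
    p <- mean(getPlane(stack, f, proteinChannel))
    m <- mean(getPlane(stack, f, membraneChannel))
    if (m == 0) stop("undefined normalization: membrane mean gray value is 0")
    p / m
  }, numeric(1))
  mean(vals)
}

# union footprint mask of all spots in a SpotSet for a given image shape
spotFootprintUnion <- function(spotSet, dim) {
  s <- spots(spotSet)
  m <- matrix(FALSE, dim[1L], dim[2L])
  for (i in seq_len(nrow(s)))
    m <- m | discPixelMask(dim, s$y[i], s$x[i], s$radiusPx[i])
  m
}

#' Per-spot intensity distribution
#'
#' Mean intensity of the plane inside each spot's disc footprint (merged
#' spots use their equivalent disc), with summary statistics.
#'
#' @param spotSet a [SpotSet-class]
#' @param plane numeric matrix co-registered with the spots
#' @param label condition label for the summary
#' @return a [conditionSummary()]
#' @export
spotIntensityDistribution <- function(spotSet, plane, label = "condition") {
  s <- spots(spotSet)
  if (nrow(s) == 0L) return(conditionSummary(numeric(0), label))
  clipped <- s$y - s$radiusPx < 0 | s$y + s$radiusPx > nrow(plane) - 1 |
    s$x - s$radiusPx < 0 | s$x + s$radiusPx > ncol(plane) - 1
  if (any(clipped))
    warning(sum(clipped), " spot footprint(s) clipped by the image edge")
  conditionSummary(spotMeanIntensity(s, plane), label)
}

#' Normalized intensity on reference structures
#'
#' Per reference spot (e.g. clathrin-positive structure), the mean target
#' intensity inside the footprint divided by the plane-wide background mean
#' of the normalization plane, background being every pixel outside all
#' reference footprints.
#'
#' @param referenceSpots a [SpotSet-class] detected on the reference channel
#' @param targetPlane plane whose intensity is measured
#' @param normalizationPlane plane providing the background mean (often the
#'   same as `targetPlane`)
#' @param label condition label
#' @return a [conditionSummary()]
#' @export
normalizedIntensityOnReference <- function(referenceSpots, targetPlane,
                                           normalizationPlane = targetPlane,
                                           label = "condition") {
  s <- spots(referenceSpots)
  if (nrow(s) == 0L) return(conditionSummary(numeric(0), label))
  inside <- spotFootprintUnion(referenceSpots, dim(normalizationPlane))
  bg <- mean(normalizationPlane[!inside])
  if (!is.finite(bg) || bg == 0)
    stop("undefined normalization: background mean is 0")
  conditionSummary(spotMeanIntensity(s, targetPlane) / bg, label)
}

#' Fold change between two condition summaries
#'
#' @param summaryA,summaryB [conditionSummary()] objects (or numeric
#'   vectors) for the numerator and denominator conditions
#' @return list with `ratio` (`mean(a)/mean(b)`) and `medianRatio`
#' @export
foldChange <- function(summaryA, summaryB) {
  a <- if (inherits(summaryA, "ConditionSummary")) summaryA else
    conditionSummary(summaryA)
  b <- if (inherits(summaryB, "ConditionSummary")) summaryB else
    conditionSummary(summaryB)
  if (a$n == 0L || b$n == 0L) stop("both summaries must be non-empty")
  if (b$mean == 0) stop("undefined ratio: denominator mean is 0")
  list(ratio = a$mean / b$mean,
       medianRatio = if (b$median != 0) a$median / b$median else NA_real_)
}

#' Profile curve container
#'
#' @param positions physical positions, strictly increasing
#' @param mean mean (normalized) intensity per position
#' @param sd sd per position (NA when a single curve)
#' @param n number of curves averaged
#' @param units unit string for the positions
#' @return list of class `ProfileCurve`
#' @export
profileCurve <- function(positions, mean, sd = rep(NA_real_, length(mean)),
                         n = 1L, units = "um") {
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  structure(list(positions = positions, mean = mean, sd = sd, n = n,
                 units = units), class = "ProfileCurve")
}

#' @export
print.ProfileCurve <- function(x, ...) {
  cat(sprintf("ProfileCurve: %d positions (%g to %g %s), n = %d curve(s)\n",
              length(x$positions), min(x$positions), max(x$positions),
              x$units, x$n))
  invisible(x)
}

#' Intensity line profile along a polyline
#'
#' Samples the plane at 1-px steps along the path with bilinear
#' interpolation, averaging over `width` perpendicular pixels; positions
#' are converted to physical units with `pixelSize`.
#'
#' @param plane numeric matrix
#' @param polyline n x 2 matrix of `(y, x)` vertices in px (0-based)
#' @param width odd perpendicular averaging width in px
#' @param pixelSize physical size of one px
#' @param units unit label for positions
#' @return a [profileCurve()]
#' @export
lineProfile <- function(plane, polyline, width = 1L, pixelSize = 1,
                        units = "um") {
  p <- profileAlongPath(plane, polyline, width)
  profileCurve(p$s * pixelSize, p$value, n = 1L, units = units)
}

# per-dome radial intensity curve: mean over 360 1-degree rays, bilinear
# samples every 0.5 px out to rMax
radialProfile <- function(plane, cy, cx, rMax, rStep = 0.5) {
  radii <- seq(0, rMax, by = rStep)
  ang <- (0:359) * pi / 180
  sy <- outer(radii, sin(ang)); sx <- outer(radii, cos(ang))
  vals <- bilinearAt(plane, cy + as.vector(sy), cx + as.vector(sx))
  rowMeans(matrix(vals, length(radii), length(ang)))
}

#' Averaged radial nano-dome profiles
#'
#' Radial cross-sections through each dome center, per channel; each dome's
#' curve is normalized to its own maximum, then curves are averaged to a
#' mean +/- SD profile. Domes whose profile circle is clipped by the image
#' edge are excluded with a warning. The unnormalized protein/reference
#' ratio profile is also returned.
#'
#' @param image two-channel [ImageStack-class] (reference, protein) or a
#'   named list of matrices
#' @param centers data.frame/matrix of dome centers `(y, x)` in px
#' @param radiusPx dome radius R in px
#' @param maxRadiusFactor profiles extend to `maxRadiusFactor * radiusPx`
#' @param referenceChannel,proteinChannel channel labels
#' @return list of [profileCurve()] per channel plus `ratio`; positions in
#'   nm when the image pixel size is given in um
#' @export
domeProfileAverage <- function(image, centers, radiusPx,
                               maxRadiusFactor = 2,
                               referenceChannel = "reference",
                               proteinChannel = "protein") {
  if (is(image, "ImageStack")) {
    planes <- list(reference = getPlane(image, 1L, referenceChannel),
                   protein = getPlane(image, 1L, proteinChannel))
    posScale <- pixelSize(image) * 1e3  # um/px -> nm positions
    units <- "nm"
  } else {
    planes <- image
    posScale <- 1
    units <- "px"
  }
  centers <- as.data.frame(centers)
  rMax <- maxRadiusFactor * radiusPx
  d <- dim(planes[[1L]])
  ok <- centers$y - rMax >= 0 & centers$y + rMax <= d[1L] - 1 &
    centers$x - rMax >= 0 & centers$x + rMax <= d[2L] - 1
  if (any(!ok))
    warning(sum(!ok), " dome(s) clipped by the image edge were excluded")
  centers <- centers[ok, , drop = FALSE]
  if (nrow(centers) == 0L) stop("no unclipped dome remains")
  radii <- seq(0, rMax, by = 0.5)
  raw <- lapply(planes, function(pl)
    t(vapply(seq_len(nrow(centers)),
             function(i) radialProfile(pl, centers$y[i], centers$x[i], rMax),
             numeric(length(radii)))))
  out <- lapply(raw, function(m) {
    normd <- m / apply(m, 1L, max)
    profileCurve(radii * posScale, colMeans(normd),
                 if (nrow(m) > 1) apply(normd, 2L, stats::sd) else
                   rep(NA_real_, ncol(m)),
                 n = nrow(m), units = units)
  })
  ratio <- raw[[proteinChannel]] / raw[[referenceChannel]]
  out$ratio <- profileCurve(radii * posScale, colMeans(ratio),
                            if (nrow(ratio) > 1) apply(ratio, 2L, stats::sd)
                            else rep(NA_real_, ncol(ratio)),
                            n = nrow(ratio), units = units)
  out
}

#' Top/bottom plane presence classification of nano-domes
#'
#' For each dome, the reference-normalized protein signal is measured on
#' the dome footprint in the top plane (dome apex) and in the bottom plane,
#' and on a rim annulus in the bottom plane. Domes are classified as
#' `present`, `excluded` (footprint signal below `exclusionThreshold` times
#' the off-dome level) or `rim-enriched` (annulus over footprint ratio at
#' or above `rimThreshold`).
#'
#' @param topImage,bottomImage registered two-channel [ImageStack-class]
#'   objects (or named lists of `reference`/`protein` matrices)
#' @param centers dome centers `(y, x)` px
#' @param radiusPx dome radius in px
#' @param referenceChannel,proteinChannel channel labels
#' @param exclusionThreshold,rimThreshold declared classification thresholds
#' @return data.frame with per-dome normalized means and the class
#' @export
planePresence <- function(topImage, bottomImage, centers, radiusPx,
                          referenceChannel = "reference",
                          proteinChannel = "protein",
                          exclusionThreshold = 0.5, rimThreshold = 1.3) {
  getPlanes <- function(img) {
    if (is(img, "ImageStack"))
      list(reference = getPlane(img, 1L, referenceChannel),
           protein = getPlane(img, 1L, proteinChannel))
    else img
  }
  top <- getPlanes(topImage); bottom <- getPlanes(bottomImage)
  if (!identical(dim(top$protein), dim(bottom$protein)))
    stop("registration error: top and bottom planes differ in shape")
  d <- dim(top$protein)
  centers <- as.data.frame(centers)
  outside <- matrix(TRUE, d[1L], d[2L])
  for (i in seq_len(nrow(centers)))
    outside <- outside & !discPixelMask(d, centers$y[i], centers$x[i],
                                        2 * radiusPx)
  normMean <- function(pl, mask) mean(pl$protein[mask]) / mean(pl$reference[mask])
  res <- lapply(seq_len(nrow(centers)), function(i) {
    foot <- discPixelMask(d, centers$y[i], centers$x[i], radiusPx)
    core <- discPixelMask(d, centers$y[i], centers$x[i], 0.6 * radiusPx)
    ann <- discPixelMask(d, centers$y[i], centers$x[i], 1.4 * radiusPx) &
      !discPixelMask(d, centers$y[i], centers$x[i], 0.9 * radiusPx)
    topOn <- normMean(top, foot) / normMean(top, outside)
    bottomOn <- normMean(bottom, foot) / normMean(bottom, outside)
    # rim contrast against the dome center: the ring straddles the
    # footprint edge, so the full-footprint mean would dilute it
    rimEnh <- normMean(bottom, ann) / normMean(bottom, core)
    cls <- if (topOn < exclusionThreshold) "excluded"
      else if (rimEnh >= rimThreshold) "rim-enriched"
      else "present"
    data.frame(dome = i, topOn = topOn, bottomOn = bottomOn,
               rimEnhancement = rimEnh, class = cls)
  })
  do.call(rbind, res)
}
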