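# Disc geometry and interpolation helpers shared by the detector,
# quantification and AFM modules. All coordinates are 0-based (y, x) with
# pixel centers at integers.

#' Area of intersection (lens) of two discs
#'
#' Closed-form circle-circle intersection area.
#'
#' @param d center-to-center distance
#' @param r1,r2 disc radii
#' @return lens area (same squared units as the radii)
#' @export
discLensArea <- function(d, r1, r2) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  # circular segment angles at each center
  a1 <- acos(pmin(1, pmax(-1, (d^2 + r1^2 - r2^2) / (2 * d * r1))))
  a2 <- acos(pmin(1, pmax(-1, (d^2 + r2^2 - r1^2) / (2 * d * r2))))
  r1^2 * (a1 - sin(2 * a1) / 2) + r2^2 * (a2 - sin(2 * a2) / 2)
}

#' Fraction of the smaller disc covered by the other
#'
#' The merge criterion quantity: lens area divided by the area of the
#' smaller of the two discs, i.e. the larger of the two mutual coverage
#' fractions.
#'
#' @inheritParams discLensArea
#' @param y1,x1,y2,x2 disc centers
#' @return coverage fraction in `[0, 1]`
#' @export
discOverlapFraction <- function(y1, x1, r1, y2, x2, r2) {
  d <- sqrt((y1 - y2)^2 + (x1 - x2)^2)
  discLensArea(d, r1, r2) / (pi * min(r1, r2)^2)
}

#' Area of the union of discs
#'
#' Numerical union area by sub-pixel rasterization of the bounding box (no
#' closed form exists for three or more mutually overlapping discs).
#'
#' @param y,x,r numeric vectors of centers and radii
#' @param subdiv sub-pixel grid subdivisions per pixel (default 8)
#' @return union area in squared pixels
#' @export
discUnionArea <- function(y, x, r, subdiv = 8L) {
  n <- length(r)
  if (n == 0L) return(0)
  if (n == 1L) return(pi * r^2)
  step <- 1 / subdiv
  ylo <- min(y - r); yhi <- max(y + r)
  xlo <- min(x - r); xhi <- max(x + r)
  gy <- seq(ylo + step / 2, yhi, by = step)
  gx <- seq(xlo + step / 2, xhi, by = step)
  covered <- matrix(FALSE, length(gy), length(gx))
  for (i in seq_len(n)) {
    dy2 <- (gy - y[i])^2
    dx2 <- (gx - x[i])^2
    covered <- covered | outer(dy2, dx2, "+") <= r[i]^2
  }
  sum(covered) * step^2
}

# Logical mask of pixels whose centers lie inside the disc. dim = c(ny, nx),
# 0-based center coordinates.
discPixelMask <- function(dim, cy, cx, r) {
  yy <- (seq_len(dim[1L]) - 1) - cy
  xx <- (seq_len(dim[2L]) - 1) - cx
  outer(yy^2, xx^2, "+") <= r^2
}

# Indices (matrix rows/cols) of pixels inside the disc, clipped to the image.
discPixelIndex <- function(dim, cy, cx, r) {
  which(discPixelMask(dim, cy, cx, r), arr.ind = TRUE)
}

#' Bilinear interpolation of a matrix at fractional 0-based coordinates
#'
#' Points outside the matrix are clamped to the border.
#'
#' @param m numeric matrix `(y, x)`
#' @param y,x numeric vectors of 0-based coordinates
#' @return interpolated values
#' @export
bilinearAt <- function(m, y, x) {
  ny <- nrow(m); nx <- ncol(m)
  y <- pmin(pmax(y, 0), ny - 1)
  x <- pmin(pmax(x, 0), nx - 1)
  y0 <- pmin(floor(y), ny - 2); x0 <- pmin(floor(x), nx - 2)
  y0 <- pmax(y0, 0); x0 <- pmax(x0, 0)
  fy <- y - y0; fx <- x - x0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  m[i00] * (1 - fy) * (1 - fx) + m[i01] * (1 - fy) * fx +
    m[i10] * fy * (1 - fx) + m[i11] * fy * fx
}

# Resample a polyline (n x 2 matrix of 0-based (y, x) vertices) at `step`-px
# arc-length intervals. Returns list(y, x, s) with s the arc length in px.
# A zero-length path yields its single vertex.
samplePolyline <- function(path, step = 1) {
  path <- as.matrix(path)
  if (nrow(path) < 1L) stop("path must have at least one vertex")
  seg <- diff(path)
  len <- sqrt(rowSums(seg^2))
  total <- sum(len)
  if (total == 0) {
    return(list(y = path[1L, 1L], x = path[1L, 2L], s = 0))
  }
  s <- seq(0, total, by = step)
  if (s[length(s)] < total) s <- c(s, total)
  cum <- c(0, cumsum(len))
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(path) - 1L)
  f <- (s - cum[idx]) / pmax(len[idx], .Machine$double.eps)
  list(y = path[idx, 1L] + f * seg[idx, 1L],
       x = path[idx, 2L] + f * seg[idx, 2L],
       s = s)
}

# Sample intensity along a polyline with perpendicular averaging over
# `width` pixels (odd). Returns list(s, value). Used by line profiles,
# kymographs and AFM cross-sections.
profileAlongPath <- function(m, path, width = 1L, step = 1) {
  sp <- samplePolyline(path, step)
  n <- length(sp$s)
  width <- as.integer(width)
  if (width %% 2L == 0L) stop("width must be odd")
  if (any(sp$y < 0 | sp$y > nrow(m) - 1 | sp$x < 0 | sp$x > ncol(m) - 1))
    stop("path runs outside the image")
  if (n == 1L) {
    return(list(s = sp$s, value = bilinearAt(m, sp$y, sp$x)))
  }
  # unit tangents by central differences, normals perpendicular to them
  ty <- c(diff(sp$y)[1L], (sp$y[-(1:2)] - sp$y[1:(n - 2)]) / 2,
          diff(sp$y)[n - 1L])
  tx <- c(diff(sp$x)[1L], (sp$x[-(1:2)] - sp$x[1:(n - 2)]) / 2,
          diff(sp$x)[n - 1L])
  nrm <- sqrt(ty^2 + tx^2)
  nrm[nrm == 0] <- 1
  nyv <- -tx / nrm; nxv <- ty / nrm
  offs <- seq(-(width - 1L) / 2L, (width - 1L) / 2L)
  acc <- matrix(0, n, length(offs))
  for (j in seq_along(offs)) {
    acc[, j] <- bilinearAt(m, sp$y + offs[j] * nyv, sp$x + offs[j] * nxv)
  }
  list(s = sp$s, value = rowMeans(acc))
}

# Simple disjoint-set (union-find) used for transitive-closure merging.
dsuFind <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

# robust sd via median absolute deviation
robustSd <- function(x) stats::mad(x, constant = 1.4826)
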