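# Fixture helpers shared across tests. All fixtures are generated in code.

# single smooth bump of half-max radius r on a constant background
bumpPlane <- function(shape = c(96L, 96L), cy = 48, cx = 48, r = 4,
                      peak = 100, background = 10, edge = 0.5) {
  p <- matrix(background, shape[1L], shape[2L])
  punctakit:::addBump(p, cy, cx, r, peak, edge)
}

# brute-force strict 8-neighborhood local minima (independent of the
# detector's vectorized implementation)
bruteLocalMinima <- function(m) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in 2:(nrow(m) - 1)) for (j in 2:(ncol(m) - 1)) {
    v <- m[i, j]
    nb <- m[(i - 1):(i + 1), (j - 1):(j + 1)]
    out[i, j] <- sum(nb < v) == 0 && sum(nb == v) == 1
  }
  out
}

# lens area from the closed form, written out independently of the package
bruteLensArea <- function(d, r1, r2) {
  if (d >= r1 + r2) return(0)
  if (d + min(r1, r2) <= max(r1, r2)) return(pi * min(r1, r2)^2)
  seg <- function(r, h) r^2 * acos(h / r) - h * sqrt(r^2 - h^2)
  h1 <- (d^2 + r1^2 - r2^2) / (2 * d)
  seg(r1, h1) + seg(r2, d - h1)
}

# union area of discs on a fine independent grid (1/10 px)
bruteUnionArea <- function(y, x, r, step = 0.1) {
  gy <- seq(min(y - r), max(y + r), by = step)
  gx <- seq(min(x - r), max(x + r), by = step)
  tot <- 0
  for (iy in gy) {
    inside <- rep(FALSE, length(gx))
    for (k in seq_along(r))
      inside <- inside | ((iy - y[k])^2 + (gx - x[k])^2 <= r[k]^2)
    tot <- tot + sum(inside)
  }
  tot * step^2
}

# brute-force pairwise-closure merging oracle: builds the merge graph from
# the coverage criterion, collapses each connected component (breadth-first
# search) to the equivalent disc of its union at the member centroid, and
# repeats until no pair meets the criterion.
bruteMergeDiscs <- function(y, x, r, frac) {
  repeat {
    n <- length(r)
    if (n < 2L) break
    adj <- matrix(FALSE, n, n)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      d <- sqrt((y[i] - y[j])^2 + (x[i] - x[j])^2)
      if (bruteLensArea(d, r[i], r[j]) / (pi * min(r[i], r[j])^2) >=
          frac - 1e-9)
        adj[i, j] <- adj[j, i] <- TRUE
    }
    if (!any(adj)) break
    comp <- rep(0L, n); cid <- 0L
    for (s in seq_len(n)) {
      if (comp[s] > 0L) next
      cid <- cid + 1L
      queue <- s
      while (length(queue)) {
        v <- queue[1L]; queue <- queue[-1L]
        if (comp[v] > 0L) next
        comp[v] <- cid
        queue <- c(queue, which(adj[v, ] & comp == 0L))
      }
    }
    ny <- nx <- nr <- numeric(cid)
    for (c in seq_len(cid)) {
      m <- comp == c
      ny[c] <- mean(y[m]); nx[c] <- mean(x[m])
      nr[c] <- if (sum(m) == 1L) r[m] else
        sqrt(bruteUnionArea(y[m], x[m], r[m]) / pi)
    }
    y <- ny; x <- nx; r <- nr
  }
  list(y = y, x = x, r = r, n = length(r))
}

# center distance at which two equal discs of radius r overlap by exactly
# `frac` of one disc's surface (closed-form lens inverted numerically)
equalDiscDistanceForOverlap <- function(r, frac) {
  stats::uniroot(function(d) discLensArea(d, r, r) / (pi * r^2) - frac,
                 c(1e-6, 2 * r), tol = 1e-12)$root
}

# tilted plane + one sharp disc patch, no noise
patchMap <- function(shape = c(128L, 128L), tilt = c(0.05, 0.08),
                     cy = 64, cx = 64, rPx = 12, height = 47,
                     pixelSize = 4) {
  z <- outer((seq_len(shape[1L]) - 1) * tilt[1L],
             (seq_len(shape[2L]) - 1) * tilt[2L], "+")
  if (rPx > 0) {
    m <- punctakit:::discPixelMask(shape, cy, cx, rPx)
    z[m] <- z[m] + height
  }
  HeightMap(z, pixelSize)
}
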