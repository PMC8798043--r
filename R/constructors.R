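#' Construct an ImageStack
#'
#' @param pixels numeric array. Accepted layouts: `(y, x)` single plane,
#'   `(channel, y, x)` single frame, or the canonical `(time, channel, y, x)`.
#' @param pixelSize pixel size in um/px.
#' @param frameInterval frame interval in s; 0 for single-frame data.
#' @param channelLabels channel names; defaults to `"ch1"`, `"ch2"`, ...
#' @return an [ImageStack-class]
#' @examples
#' img <- ImageStack(matrix(1, 32, 32), pixelSize = 0.05)
#' dim(pixels(img))
#' @export
ImageStack <- function(pixels, pixelSize, frameInterval = 0,
                       channelLabels = NULL) {
  d <- dim(pixels)
  if (is.null(d) || length(d) == 2L) {
    pixels <- array(pixels, c(1L, 1L, dim(as.matrix(pixels))))
  } else if (length(d) == 3L) {
    pixels <- array(pixels, c(1L, d))
  } else if (length(d) != 4L) {
    stop("pixels must have 2, 3 or 4 dimensions")
  }
  if (is.null(channelLabels))
    channelLabels <- paste0("ch", seq_len(dim(pixels)[2L]))
  new("ImageStack", pixels = pixels, pixelSize = as.numeric(pixelSize),
      frameInterval = as.numeric(frameInterval),
      channelLabels = as.character(channelLabels))
}

#' Construct a HeightMap
#'
#' @param heights numeric matrix of heights in nm, `(y, x)`.
#' @param pixelSize pixel size in nm/px.
#' @param setpointLabel `"low"`, `"high"` or `"unspecified"`.
#' @return a [HeightMap-class]
#' @export
HeightMap <- function(heights, pixelSize, setpointLabel = "unspecified") {
  new("HeightMap", heights = as.matrix(heights),
      pixelSize = as.numeric(pixelSize),
      setpointLabel = as.character(setpointLabel))
}

#' Construct a HeightMovie
#'
#' @param frames 3-d array `(time, y, x)` in nm, or a list of matrices /
#'   [HeightMap-class] objects sharing shape and calibration.
#' @param pixelSize nm/px (taken from the first HeightMap if omitted).
#' @param frameInterval s/frame.
#' @param setpointLabel setpoint-force label.
#' @return a [HeightMovie-class]
#' @export
HeightMovie <- function(frames, pixelSize = NULL, frameInterval,
                        setpointLabel = "unspecified") {
  if (is.list(frames)) {
    mats <- lapply(frames, function(f) {
      if (is(f, "HeightMap")) heights(f) else as.matrix(f)
    })
    if (is.null(pixelSize) && is(frames[[1L]], "HeightMap"))
      pixelSize <- pixelSize(frames[[1L]])
    shp <- dim(mats[[1L]])
    if (!all(vapply(mats, function(m) identical(dim(m), shp), logical(1))))
      stop("all frames must share the same shape")
    frames <- aperm(array(unlist(mats), c(shp, length(mats))), c(3L, 1L, 2L))
  }
  if (is.null(pixelSize)) stop("pixelSize is required")
  new("HeightMovie", frames = frames, pixelSize = as.numeric(pixelSize),
      frameInterval = as.numeric(frameInterval),
      setpointLabel = as.character(setpointLabel))
}

#' Construct a SpotSet
#'
#' @param spots data.frame with at least `y`, `x`, `radiusPx`, `areaUm2`.
#' @param pixelSize um/px used for the areas.
#' @param provenance free-form list (image id, frame, channel, params).
#' @return a [SpotSet-class]
#' @export
SpotSet <- function(spots, pixelSize, provenance = NULL) {
  if (!"nMerged" %in% names(spots)) spots$nMerged <- rep(1L, nrow(spots))
  new("SpotSet", spots = as.data.frame(spots),
      pixelSize = as.numeric(pixelSize), provenance = provenance)
}

emptySpotFrame <- function() {
  data.frame(y = numeric(0), x = numeric(0), radiusPx = numeric(0),
             scaleIdx = integer(0), response = numeric(0),
             areaUm2 = numeric(0), nMerged = integer(0))
}
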