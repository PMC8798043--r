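#' @import methods
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' ImageStack: calibrated multi-channel, multi-frame 2D image data
#'
#' Container for fluorescence acquisitions. Pixel data are stored as a
#' 4-dimensional numeric array indexed `(time, channel, y, x)`; coordinates
#' are 0-based with pixel centers at integers, and physical areas are
#' reported in um^2 as pixel count times `pixelSize^2`.
#'
#' @slot pixels numeric 4-d array `(time, channel, y, x)`; finite, >= 0.
#' @slot pixelSize pixel size in um/px (> 0).
#' @slot frameInterval frame interval in seconds (0 for a single frame).
#' @slot channelLabels character vector naming the channels.
#'
#' @seealso [ImageStack()] for construction, [pixels()], [pixelSize()],
#'   [frameInterval()], [channelLabels()] for access.
#' @exportClass ImageStack
setClass("ImageStack",
  representation(
    pixels = "array",
    pixelSize = "numeric",
    frameInterval = "numeric",
    channelLabels = "character"
  )
)

setValidity("ImageStack", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 4L)
    return("pixels must be a 4-d array (time, channel, y, x)")
  if (!all(is.finite(p)))
    return("pixel intensities must be finite")
  if (any(p < 0))
    return("pixel intensities must be >= 0")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number (um/px)")
  if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
      object@frameInterval < 0)
    return("frameInterval must be a single number >= 0 (s)")
  if (length(object@channelLabels) != dim(p)[2L])
    return("channelLabels length must equal the number of channels")
  TRUE
})

#' HeightMap: calibrated AFM topography
#'
#' @slot heights numeric matrix of heights in nm, indexed `(y, x)`.
#' @slot pixelSize pixel size in nm/px (> 0).
#' @slot setpointLabel one of `"low"`, `"high"`, `"unspecified"`; records
#'   the AFM imaging (setpoint) force regime the map was acquired at.
#'
#' @exportClass HeightMap
setClass("HeightMap",
  representation(
    heights = "matrix",
    pixelSize = "numeric",
    setpointLabel = "character"
  )
)

setValidity("HeightMap", function(object) {
  if (!is.numeric(object@heights) || !all(is.finite(object@heights)))
    return("heights must be a finite numeric matrix (nm)")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number (nm/px)")
  if (length(object@setpointLabel) != 1L ||
      !object@setpointLabel %in% c("low", "high", "unspecified"))
    return("setpointLabel must be one of 'low', 'high', 'unspecified'")
  TRUE
})

#' HeightMovie: a time series of calibrated AFM height maps
#'
#' @slot frames numeric 3-d array `(time, y, x)` of heights in nm.
#' @slot pixelSize pixel size in nm/px, shared by all frames.
#' @slot frameInterval frame interval in seconds (> 0).
#' @slot setpointLabel setpoint-force label shared by all frames.
#'
#' @exportClass HeightMovie
setClass("HeightMovie",
  representation(
    frames = "array",
    pixelSize = "numeric",
    frameInterval = "numeric",
    setpointLabel = "character"
  )
)

setValidity("HeightMovie", function(object) {
  if (length(dim(object@frames)) != 3L)
    return("frames must be a 3-d array (time, y, x)")
  if (!all(is.finite(object@frames)))
    return("heights must be finite")
  if (object@pixelSize <= 0) return("pixelSize must be > 0 (nm/px)")
  if (object@frameInterval <= 0) return("frameInterval must be > 0 (s)")
  if (!object@setpointLabel %in% c("low", "high", "unspecified"))
    return("setpointLabel must be one of 'low', 'high', 'unspecified'")
  TRUE
})

#' ScaleSpace: stack of scale-normalized LoG responses
#'
#' One response plane per scale; `scales` are blob radii in pixels
#' (radius = sqrt(2) * sigma of the underlying Gaussian). Bright blobs on a
#' dark background produce negative responses, so blob centers are response
#' minima.
#'
#' @slot responses numeric 3-d array `(scale, y, x)`.
#' @slot scales numeric vector of blob radii in px, strictly ascending.
#'
#' @exportClass ScaleSpace
setClass("ScaleSpace",
  representation(responses = "array", scales = "numeric")
)

setValidity("ScaleSpace", function(object) {
  if (length(dim(object@responses)) != 3L)
    return("responses must be a 3-d array (scale, y, x)")
  if (dim(object@responses)[1L] != length(object@scales))
    return("one response plane per scale required")
  if (!all(is.finite(object@responses)))
    return("responses must be finite")
  if (any(object@scales <= 0) || is.unsorted(object@scales, strictly = TRUE))
    return("scales must be strictly ascending and > 0")
  TRUE
})

#' SpotSet: detected spots/clusters with geometry and intensities
#'
#' The `spots` data frame has one row per spot with columns `y`, `x`
#' (center, px, 0-based), `radiusPx`, `scaleIdx`, `response`, `areaUm2`,
#' `nMerged`, plus one `mean_<channel>` column per measured channel.
#'
#' @slot spots data.frame of per-spot records.
#' @slot pixelSize pixel size in um/px used for the areas.
#' @slot provenance list describing image id, frame, channel and parameters.
#'
#' @exportClass SpotSet
setClass("SpotSet",
  representation(
    spots = "data.frame",
    pixelSize = "numeric",
    provenance = "listOrNULL"
  )
)

setValidity("SpotSet", function(object) {
  s <- object@spots
  need <- c("y", "x", "radiusPx", "areaUm2")
  if (!all(need %in% names(s)))
    return(paste("spots must have columns", paste(need, collapse = ", ")))
  if (nrow(s) && any(s$radiusPx <= 0)) return("radiusPx must be > 0")
  if (nrow(s) && any(s$areaUm2 <= 0)) return("areaUm2 must be > 0")
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  TRUE
})

#' Kymograph: space-time intensity matrix sampled along a path
#'
#' @slot values matrix indexed (position along path, time/frame).
#' @slot path numeric matrix of polyline vertices `(y, x)` in px.
#' @slot width perpendicular averaging width in px (odd integer).
#' @slot pixelSize um/px of the source stack.
#' @slot frameInterval s/frame of the source stack.
#'
#' @exportClass Kymograph
setClass("Kymograph",
  representation(
    values = "matrix",
    path = "matrix",
    width = "numeric",
    pixelSize = "numeric",
    frameInterval = "numeric"
  )
)

setValidity("Kymograph", function(object) {
  if (!all(is.finite(object@values))) return("values must be finite")
  if (ncol(object@path) != 2L) return("path must be an n x 2 (y, x) matrix")
  if (object@width < 1) return("width must be >= 1")
  TRUE
})
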