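#' @rdname ImageStack-class
#' @aliases pixels,ImageStack-method
setMethod("pixels", "ImageStack", function(object) object@pixels)

#' @rdname ImageStack-class
setMethod("pixelSize", "ImageStack", function(object) object@pixelSize)

#' @rdname ImageStack-class
setMethod("frameInterval", "ImageStack", function(object) object@frameInterval)

#' @rdname ImageStack-class
setMethod("channelLabels", "ImageStack", function(object) object@channelLabels)

#' @rdname ImageStack-class
setMethod("nFrames", "ImageStack", function(object) dim(object@pixels)[1L])

#' @rdname ImageStack-class
setMethod("nChannels", "ImageStack", function(object) dim(object@pixels)[2L])

#' @rdname getPlane
setMethod("getPlane", "ImageStack", function(object, frame = 1L, channel = 1L) {
  if (is.character(channel)) {
    channel <- match(channel, object@channelLabels)
    if (is.na(channel)) stop("unknown channel label")
  }
  object@pixels[frame, channel, , ]
})

#' @rdname HeightMap-class
setMethod("heights", "HeightMap", function(object) object@heights)

#' @rdname HeightMap-class
setMethod("pixelSize", "HeightMap", function(object) object@pixelSize)

#' @rdname HeightMap-class
setMethod("setpointLabel", "HeightMap", function(object) object@setpointLabel)

#' @rdname HeightMovie-class
setMethod("pixelSize", "HeightMovie", function(object) object@pixelSize)

#' @rdname HeightMovie-class
setMethod("frameInterval", "HeightMovie", function(object) object@frameInterval)

#' @rdname HeightMovie-class
setMethod("setpointLabel", "HeightMovie", function(object) object@setpointLabel)

#' @rdname HeightMovie-class
setMethod("nFrames", "HeightMovie", function(object) dim(object@frames)[1L])

#' @rdname getPlane
setMethod("getPlane", "HeightMovie", function(object, frame = 1L, channel = 1L) {
  object@frames[frame, , ]
})

#' Frame as a HeightMap
#'
#' @param movie a [HeightMovie-class]
#' @param frame 1-based frame index
#' @return a [HeightMap-class]
#' @export
movieFrame <- function(movie, frame) {
  HeightMap(movie@frames[frame, , ], movie@pixelSize, movie@setpointLabel)
}

#' @rdname SpotSet-class
setMethod("spots", "SpotSet", function(object) object@spots)

#' @rdname SpotSet-class
setMethod("pixelSize", "SpotSet", function(object) object@pixelSize)

#' @rdname SpotSet-class
setMethod("provenance", "SpotSet", function(object) object@provenance)

#' @rdname SpotSet-class
#' @param x a SpotSet
setMethod("length", "SpotSet", function(x) nrow(x@spots))

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "ImageStack: %d frame(s) x %d channel(s), %d x %d px @ %.4g um/px\n",
    d[1L], d[2L], d[3L], d[4L], object@pixelSize))
  if (d[1L] > 1L)
    cat(sprintf("  frame interval %.3g s (duration %.3g s)\n",
                object@frameInterval, (d[1L] - 1L) * object@frameInterval))
  cat("  channels:", paste(object@channelLabels, collapse = ", "), "\n")
})

setMethod("show", "HeightMap", function(object) {
  d <- dim(object@heights)
  cat(sprintf(
    "HeightMap: %d x %d px @ %.4g nm/px, setpoint %s, height range [%.3g, %.3g] nm\n",
    d[1L], d[2L], object@pixelSize, object@setpointLabel,
    min(object@heights), max(object@heights)))
})

setMethod("show", "HeightMovie", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "HeightMovie: %d frames, %d x %d px @ %.4g nm/px, dt %.3g s, setpoint %s\n",
    d[1L], d[2L], d[3L], object@pixelSize, object@frameInterval,
    object@setpointLabel))
})

setMethod("show", "SpotSet", function(object) {
  cat(sprintf("SpotSet: %d spot(s) @ %.4g um/px\n",
              nrow(object@spots), object@pixelSize))
  if (nrow(object@spots)) {
    cat(sprintf("  area (um^2): mean %.4g, median %.4g\n",
                mean(object@spots$areaUm2), stats::median(object@spots$areaUm2)))
  }
})

setMethod("show", "ScaleSpace", function(object) {
  cat(sprintf("ScaleSpace: %d scales (radii %s px), %d x %d px\n",
              length(object@scales),
              paste(signif(object@scales, 3), collapse = ", "),
              dim(object@responses)[2L], dim(object@responses)[3L]))
})

setMethod("show", "Kymograph", function(object) {
  cat(sprintf("Kymograph: %d positions x %d frames (width %d px)\n",
              nrow(object@values), ncol(object@values), object@width))
})

#' @rdname Kymograph-class
#' @param object a Kymograph
#' @export
kymoValues <- function(object) object@values
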