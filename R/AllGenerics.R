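#' @rdname ImageStack-class
#' @param object an object
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname ImageStack-class
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname ImageStack-class
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))

#' @rdname ImageStack-class
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))

#' @rdname ImageStack-class
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname ImageStack-class
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' Extract one 2-d plane from a stack
#'
#' @param object an [ImageStack-class] or [HeightMovie-class]
#' @param frame 1-based frame index
#' @param channel 1-based channel index or channel label (images only)
#' @return numeric matrix `(y, x)`
#' @export
setGeneric("getPlane", function(object, frame = 1L, channel = 1L)
  standardGeneric("getPlane"))

#' @rdname HeightMap-class
#' @param object an object
#' @export
setGeneric("heights", function(object) standardGeneric("heights"))

#' @rdname HeightMap-class
#' @export
setGeneric("setpointLabel", function(object) standardGeneric("setpointLabel"))

#' @rdname SpotSet-class
#' @param object an object
#' @export
setGeneric("spots", function(object) standardGeneric("spots"))

#' @rdname SpotSet-class
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' Detect spots with the scale-space detector
#'
#' @param object image input (matrix plane or [ImageStack-class])
#' @param params a [detectionParams()] list
#' @param ... further arguments passed to methods
#' @export
setGeneric("detectSpots", function(object, params = detectionParams(), ...)
  standardGeneric("detectSpots"))
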