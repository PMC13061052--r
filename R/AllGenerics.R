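#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("channelSignal", function(x, channel) standardGeneric("channelSignal"))

#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname accessors
#' @export
setGeneric("recordDuration", function(x) standardGeneric("recordDuration"))

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname accessors
#' @export
setGeneric("beatTimes", function(x) standardGeneric("beatTimes"))

#' @rdname accessors
#' @export
setGeneric("peakIndices", function(x) standardGeneric("peakIndices"))

#' @rdname accessors
#' @export
setGeneric("channelLabel", function(x) standardGeneric("channelLabel"))

#' @rdname accessors
#' @export
setGeneric("rrIntervals", function(x) standardGeneric("rrIntervals"))

#' @rdname accessors
#' @export
setGeneric("rrValid", function(x) standardGeneric("rrValid"))

#' @rdname accessors
#' @export
setGeneric("isUsable", function(x) standardGeneric("isUsable"))

#' @rdname accessors
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))

#' @rdname accessors
#' @export
setGeneric("epochLabels", function(x) standardGeneric("epochLabels"))

#' @rdname accessors
#' @export
setGeneric("metrics", function(x) standardGeneric("metrics"))

#' @rdname accessors
#' @export
setGeneric("qualityWindows", function(x) standardGeneric("qualityWindows"))
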