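#' @title Generics for podoquant data objects
#' @name podoquant-generics
#' @description Accessor generics shared by the imaging containers.
#' @param x a podoquant object
#' @param ... further arguments for methods
#' @keywords internal
NULL

#' @describeIn podoquant-generics physical pixel size in micrometres per pixel
#' @export
setGeneric("pixelSize", function(x, ...) standardGeneric("pixelSize"))

#' @describeIn podoquant-generics channel names of a scene
#' @export
setGeneric("channelNames", function(x, ...) standardGeneric("channelNames"))

#' @describeIn podoquant-generics one channel (optionally one frame) as a matrix
#' @export
setGeneric("getChannel", function(x, ...) standardGeneric("getChannel"))

#' @describeIn podoquant-generics number of frames of a time-lapse scene
#' @export
setGeneric("nFrames", function(x, ...) standardGeneric("nFrames"))

#' @describeIn podoquant-generics frame interval in minutes
#' @export
setGeneric("frameInterval", function(x, ...) standardGeneric("frameInterval"))

#' @describeIn podoquant-generics total skeleton length in micrometres
#' @export
setGeneric("skeletonLength", function(x, ...) standardGeneric("skeletonLength"))

#' @describeIn podoquant-generics capillary area in square micrometres
#' @export
setGeneric("capillaryArea", function(x, ...) standardGeneric("capillaryArea"))

#' @describeIn podoquant-generics filtration slit density in 1/micrometre
#' @export
setGeneric("fsd", function(x, ...) standardGeneric("fsd"))

#' @describeIn podoquant-generics planted-object table of a ground-truth record
#' @export
setGeneric("truthObjects", function(x, ...) standardGeneric("truthObjects"))

#' @describeIn podoquant-generics scene-level scalar ground truth
#' @export
setGeneric("truthScalars", function(x, ...) standardGeneric("truthScalars"))

#' @describeIn podoquant-generics planted-object label map
#' @export
setGeneric("truthLabels", function(x, ...) standardGeneric("truthLabels"))
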