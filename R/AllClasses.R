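#' ImageScene: a calibrated multichannel fluorescence scene
#'
#' The carrier object consumed by all imaging pipelines. Each channel is a
#' numeric array, either \code{y × x} for a single frame or \code{y × x × t}
#' for a time lapse; all channels share dimensions. The physical pixel size
#' (isotropic, in micrometres per pixel) converts pixel measurements into the
#' µm-based units every downstream quantity is reported in.
#'
#' @slot pixels named list of numeric arrays, one per channel
#' @slot channels character vector of channel names (same order as pixels)
#' @slot pixelSize micrometres per pixel, a single positive number
#' @slot frameInterval minutes between frames for time-lapse scenes;
#'   \code{NA} for single frames
#'
#' @seealso [ImageScene()] for the user constructor, [readImageScene()]
#' @exportClass ImageScene
setClass("ImageScene",
    representation(
        pixels = "list",
        channels = "character",
        pixelSize = "numeric",
        frameInterval = "numeric"
    )
)

setValidity("ImageScene", function(object) {
    msg <- character()
    if (length(object@pixels) == 0L)
        msg <- c(msg, "scene must carry at least one channel")
    if (length(object@pixels) != length(object@channels))
        msg <- c(msg, "channel names and pixel arrays differ in length")
    if (anyDuplicated(object@channels))
        msg <- c(msg, "channel names must be unique")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
        msg <- c(msg, "pixelSize must be a single positive finite number")
    dims <- lapply(object@pixels, dim)
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) > 1L)
        msg <- c(msg, "all channels must share dimensions")
    for (ch in object@pixels) {
        if (!all(is.finite(ch)) || any(ch < 0)) {
            msg <- c(msg, "intensities must be finite and non-negative")
            break
        }
    }
    if (length(msg)) msg else TRUE
})

#' GroundTruth: planted objects and parameters of a synthetic scene
#'
#' Every synthetic generator returns one of these next to its scene. It is
#' sufficient to score any pipeline output without re-deriving anything from
#' pixels: per-object records (masks via the label map, physical areas,
#' lengths, speeds in µm-based units) plus scene-level scalars such as the
#' true total slit length, true capillary area or planted table counts.
#'
#' @slot objects data.frame with one row per planted object
#' @slot labels integer label map tying objects to pixels (or \code{NULL})
#' @slot scalars named list of scene-level ground-truth values
#'
#' @exportClass GroundTruth
setClass("GroundTruth",
    representation(
        objects = "data.frame",
        labels = "ANY",
        scalars = "list"
    )
)

setValidity("GroundTruth", function(object) {
    if (!is.null(object@labels) && !is.matrix(object@labels) &&
        !is.array(object@labels))
        return("labels must be NULL, a matrix or an array")
    TRUE
})

#' SlitNetwork: the filtration-slit-density measurement of one scene
#'
#' Holds the segmented slit mask, its one-pixel skeleton, the physical
#' skeleton length, the capillary mask and area, and the filtration slit
#' density FSD = skeleton length / capillary area in µm^-1.
#'
#' @slot slitMask logical/binary matrix of slit signal
#' @slot skeleton logical/binary matrix, subset of the slit mask
#' @slot skeletonLength total slit length in micrometres
#' @slot capillaryMask logical/binary matrix of the capillary region
#' @slot capillaryArea capillary area in square micrometres
#' @slot fsd filtration slit density in 1/micrometre
#' @slot pixelSize micrometres per pixel used for the measurement
#'
#' @seealso [measureSlitDensity()]
#' @exportClass SlitNetwork
setClass("SlitNetwork",
    representation(
        slitMask = "matrix",
        skeleton = "matrix",
        skeletonLength = "numeric",
        capillaryMask = "matrix",
        capillaryArea = "numeric",
        fsd = "numeric",
        pixelSize = "numeric"
    )
)

setValidity("SlitNetwork", function(object) {
    msg <- character()
    if (any(object@skeleton > 0 & !(object@slitMask > 0)))
        msg <- c(msg, "skeleton must be a subset of the slit mask")
    if (!is.finite(object@capillaryArea) || object@capillaryArea <= 0)
        msg <- c(msg, "capillary area must be positive")
    if (is.finite(object@fsd) && is.finite(object@skeletonLength) &&
        abs(object@fsd - object@skeletonLength / object@capillaryArea) >
            1e-8 * max(1, object@fsd))
        msg <- c(msg, "fsd must equal skeleton length / capillary area")
    if (length(msg)) msg else TRUE
})

#' MembraneGeometry: spherical-cap strain state of a stretched membrane
#'
#' Geometry of a circular elastic membrane of radius \code{a} deflected at
#' its centre by height \code{h}. Under the spherical-cap model the relative
#' area increase is (h/a)^2 and the mean linear strain is
#' sqrt(1 + dA/A) - 1.
#'
#' @slot capHeight centre deflection h in millimetres
#' @slot radius membrane radius a in millimetres
#' @slot areaIncrease relative area increase dA/A (dimensionless)
#' @slot linearStrain mean linear strain (dimensionless)
#'
#' @seealso [membraneStrain()]
#' @exportClass MembraneGeometry
setClass("MembraneGeometry",
    representation(
        capHeight = "numeric",
        radius = "numeric",
        areaIncrease = "numeric",
        linearStrain = "numeric"
    )
)

setValidity("MembraneGeometry", function(object) {
    msg <- character()
    if (object@radius <= 0) msg <- c(msg, "radius must be positive")
    if (object@capHeight < 0) msg <- c(msg, "cap height must be >= 0")
    if (object@areaIncrease < 0 || object@linearStrain < 0)
        msg <- c(msg, "area increase and strain must be >= 0")
    if (length(msg)) msg else TRUE
})
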