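#' Construct an ImageScene
#'
#' @param pixels a numeric matrix (single channel), a \code{y × x × t} array
#'   (single-channel time lapse), or a named list of such arrays
#' @param channels channel names; defaults to names of \code{pixels} or
#'   \code{"ch1"}, \code{"ch2"}, ...
#' @param pixelSize micrometres per pixel (isotropic), required and positive
#' @param frameInterval minutes between frames (time lapse only)
#' @return an [ImageScene-class] object
#' @examples
#' img <- matrix(runif(64), 8, 8)
#' sc <- ImageScene(img, pixelSize = 0.1)
#' pixelSize(sc)
#' @export
ImageScene <- function(pixels, channels = NULL, pixelSize,
                       frameInterval = NA_real_) {
    if (!is.list(pixels)) pixels <- list(pixels)
    pixels <- lapply(pixels, function(p) {
        if (is.matrix(p) || (is.array(p) && length(dim(p)) == 3L)) {
            storage.mode(p) <- "double"
            p
        } else stop("each channel must be a 2D matrix or 3D (y,x,t) array")
    })
    if (is.null(channels))
        channels <- if (!is.null(names(pixels)) && all(nzchar(names(pixels))))
            names(pixels) else paste0("ch", seq_along(pixels))
    names(pixels) <- channels
    new("ImageScene", pixels = pixels, channels = as.character(channels),
        pixelSize = as.numeric(pixelSize),
        frameInterval = as.numeric(frameInterval))
}

#' @rdname ImageScene
#' @param x an ImageScene
#' @export
setMethod("pixelSize", "ImageScene", function(x) x@pixelSize)

#' @rdname ImageScene
#' @export
setMethod("channelNames", "ImageScene", function(x) x@channels)

#' @rdname ImageScene
#' @export
setMethod("frameInterval", "ImageScene", function(x) x@frameInterval)

#' @rdname ImageScene
#' @param channel channel name or index
#' @param frame frame index for time-lapse channels; \code{NULL} returns the
#'   full array
#' @export
setMethod("getChannel", "ImageScene", function(x, channel = 1L,
                                               frame = NULL) {
    p <- x@pixels[[channel]]
    if (is.null(p)) stop("no such channel: ", channel)
    if (is.null(frame)) return(p)
    if (length(dim(p)) == 2L) {
        if (frame != 1L) stop("single-frame channel has no frame ", frame)
        return(p)
    }
    p[, , frame]
})

#' @rdname ImageScene
#' @export
setMethod("nFrames", "ImageScene", function(x) {
    d <- dim(x@pixels[[1L]])
    if (length(d) == 3L) d[3L] else 1L
})

#' @rdname ImageScene
#' @export
setMethod("dim", "ImageScene", function(x) dim(x@pixels[[1L]]))

setMethod("show", "ImageScene", function(object) {
    d <- dim(object@pixels[[1L]])
    cat("ImageScene:", d[1L], "x", d[2L], "px")
    if (length(d) == 3L) cat(" x", d[3L], "frames")
    cat("\n  channels:", paste(object@channels, collapse = ", "), "\n")
    cat("  pixel size:", object@pixelSize, "µm/px")
    if (is.finite(object@frameInterval))
        cat("; frame interval:", object@frameInterval, "min")
    cat("\n")
})

#' Construct a GroundTruth record
#'
#' @param objects data.frame of planted objects (one row each)
#' @param labels optional integer label map linking objects to pixels
#' @param scalars named list of scene-level ground-truth values
#' @return a [GroundTruth-class] object
#' @export
GroundTruth <- function(objects = data.frame(), labels = NULL,
                        scalars = list()) {
    new("GroundTruth", objects = objects, labels = labels, scalars = scalars)
}

#' @rdname GroundTruth
#' @param x a GroundTruth
#' @export
setMethod("truthObjects", "GroundTruth", function(x) x@objects)

#' @rdname GroundTruth
#' @export
setMethod("truthScalars", "GroundTruth", function(x) x@scalars)

#' @rdname GroundTruth
#' @export
setMethod("truthLabels", "GroundTruth", function(x) x@labels)

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", nrow(object@objects), "planted objects;",
        length(object@scalars), "scene-level scalars\n")
    if (length(object@scalars)) {
        sc <- object@scalars
        flat <- vapply(sc, function(v)
            paste(format(unlist(v), digits = 4), collapse = ","), "")
        cat(paste0("  ", names(sc), " = ", flat, collapse = "\n"), "\n")
    }
})

#' @rdname SlitNetwork-class
#' @param x a SlitNetwork
#' @export
setMethod("skeletonLength", "SlitNetwork", function(x) x@skeletonLength)

#' @rdname SlitNetwork-class
#' @export
setMethod("capillaryArea", "SlitNetwork", function(x) x@capillaryArea)

#' @rdname SlitNetwork-class
#' @export
setMethod("fsd", "SlitNetwork", function(x) x@fsd)

#' @rdname SlitNetwork-class
#' @export
setMethod("pixelSize", "SlitNetwork", function(x) x@pixelSize)

setMethod("show", "SlitNetwork", function(object) {
    cat("SlitNetwork\n")
    cat("  slit length   :", format(object@skeletonLength, digits = 5),
        "µm\n")
    cat("  capillary area:", format(object@capillaryArea, digits = 5),
        "µm²\n")
    cat("  FSD           :", format(object@fsd, digits = 4),
        "µm⁻¹\n")
})

setMethod("show", "MembraneGeometry", function(object) {
    cat("MembraneGeometry (spherical cap)\n")
    cat("  deflection h  :", object@capHeight, "mm\n")
    cat("  radius a      :", object@radius, "mm\n")
    cat(sprintf("  area increase : %.2f%%\n", 100 * object@areaIncrease))
    cat(sprintf("  linear strain : %.2f%%\n", 100 * object@linearStrain))
})
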