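# Filtration-slit-density (FSD) measurement: slit length per glomerular
# capillary area in µm^-1, from a projected slit-diaphragm channel.

#' Segment the slit-diaphragm signal
#'
#' @param img 2D slit channel (maximum-intensity projection)
#' @param method \code{"otsu"} (default) or \code{"fixed"}
#' @param threshold fixed threshold (required for \code{method = "fixed"})
#' @return logical slit mask; a constant image yields an empty mask with a
#'   warning
#' @export
segmentSlits <- function(img, method = c("otsu", "fixed"),
                         threshold = NULL) {
    method <- match.arg(method)
    if (method == "fixed") {
        if (is.null(threshold)) stop("fixed method needs a threshold")
        return(img > threshold)
    }
    rng <- range(img)
    if (diff(rng) == 0) {
        warning("constant image: empty slit mask")
        return(matrix(FALSE, nrow(img), ncol(img)))
    }
    norm <- (img - rng[1L]) / diff(rng)
    thr <- EBImage::otsu(EBImage::as.Image(norm), range = c(0, 1))
    norm > thr
}

#' Skeletonize a mask and measure its curvilinear length
#'
#' Thins the mask to a one-pixel skeleton and sums the orthogonal/diagonal
#' step metric (1 or sqrt(2) pixel steps) times the pixel size.
#'
#' @param mask binary slit mask
#' @param pixelSize µm per pixel
#' @return list with \code{skeleton} (logical matrix) and \code{length}
#'   (µm; 0 for an empty mask)
#' @export
measureCurvilinearLength <- function(mask, pixelSize) {
    stopifnot(pixelSize > 0)
    skel <- thinMask(mask)
    list(skeleton = skel,
         length = skeletonPathLength(skel, pixelSize))
}

#' Delineate the capillary area
#'
#' With an explicit ROI polygon the capillary mask is its rasterization.
#' Otherwise the mask is the filled envelope of the slit signal:
#' morphological closing at \code{closingRadius} bridges foot-process-scale
#' gaps between slits, and hole filling produces the capillary region.
#'
#' @param slitMask binary slit mask (ignored when \code{roi} given)
#' @param roi optional ROI polygon, a matrix/data.frame of (row, col)
#'   vertices in px
#' @param closingRadius closing radius in µm
#' @param pixelSize µm per pixel
#' @return logical capillary mask
#' @export
delineateCapillary <- function(slitMask, roi = NULL, closingRadius = 1,
                               pixelSize) {
    stopifnot(pixelSize > 0)
    if (!is.null(roi)) {
        roi <- as.matrix(roi)
        return(rasterizePolygon(roi, dim(slitMask)))
    }
    if (is.null(slitMask) || !any(slitMask > 0))
        stop("empty slit mask and no ROI: cannot delineate the capillary")
    rPx <- max(1L, round(closingRadius / pixelSize))
    env <- EBImage::closing(slitMask > 0, discBrush(rPx)) > 0
    as.matrix(EBImage::fillHull(env)) > 0
}

#' Filtration slit density
#'
#' @param length total slit length in µm
#' @param area capillary area in µm² (> 0)
#' @return FSD in µm^-1
#' @examples filtrationSlitDensity(45.7, 10) # 4.57
#' @export
filtrationSlitDensity <- function(length, area) {
    if (!is.finite(area) || area <= 0) stop("capillary area must be positive")
    stopifnot(length >= 0)
    length / area
}

#' End-to-end FSD measurement of one scene
#'
#' Chains [segmentSlits()], [measureCurvilinearLength()],
#' [delineateCapillary()] and [filtrationSlitDensity()], restricting the
#' skeleton to the capillary region.
#'
#' @param scene an [ImageScene-class] with a slit channel
#' @param channel channel name or index
#' @param roi optional ROI polygon (row, col vertices)
#' @param method,threshold forwarded to [segmentSlits()]
#' @param closingRadius forwarded to [delineateCapillary()]
#' @return a [SlitNetwork-class]
#' @export
measureSlitDensity <- function(scene, channel = 1L, roi = NULL,
                               method = "otsu", threshold = NULL,
                               closingRadius = 1) {
    img <- getChannel(scene, channel)
    ps <- pixelSize(scene)
    slit <- segmentSlits(img, method = method, threshold = threshold)
    cap <- delineateCapillary(slit, roi = roi,
                              closingRadius = closingRadius, pixelSize = ps)
    slitIn <- slit & cap
    m <- measureCurvilinearLength(slitIn, ps)
    area <- sum(cap) * ps^2
    new("SlitNetwork",
        slitMask = slitIn * 1, skeleton = m$skeleton * 1,
        skeletonLength = m$length,
        capillaryMask = cap * 1, capillaryArea = area,
        fsd = filtrationSlitDensity(m$length, area),
        pixelSize = ps)
}
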