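# Synthetic focal-contact scenes with exact ground truth.

# Fluorescence noise model: signal-dependent Poisson (shot) noise followed
# by additive Gaussian read noise. SNR is defined as peak amplitude over
# the Gaussian sd.
applyNoise <- function(img, poissonGain, gaussianSd) {
    out <- img
    if (!is.null(poissonGain) && is.finite(poissonGain) && poissonGain > 0)
        out <- stats::rpois(length(out), lambda = out * poissonGain) /
            poissonGain
    if (gaussianSd > 0)
        out <- out + stats::rnorm(length(out), sd = gaussianSd)
    out <- pmax(out, 0)
    matrix(out, nrow(img), ncol(img))
}

#' Parameters of a synthetic focal-contact scene
#'
#' Elliptical contacts with a centre-bright generalized-Gaussian intensity
#' profile sit on a diffuse cell-shaped background; Poisson then Gaussian
#' noise is applied last. The default mean contact area of 1.32 µm² is the
#' size regime of vinculin-positive adhesions in cultured podocytes.
#'
#' @param imageSize image size in px, \code{c(rows, cols)}
#' @param pixelSize µm per pixel
#' @param nFa number of planted contacts
#' @param faAreaMean mean contact area in µm²
#' @param faAreaCV coefficient of variation of contact area
#' @param axisRatioRange range of ellipse major/minor axis ratios
#' @param amplitudeRatio centre/edge intensity ratio of the profile (> 1)
#' @param peakAmplitude peak intensity of a contact above background
#' @param background diffuse cell background level
#' @param touchingFraction fraction of contacts planted as touching pairs
#' @param poissonGain gain of the Poisson noise stage (0 disables)
#' @param gaussianSd sd of the additive Gaussian stage; SNR =
#'   \code{peakAmplitude / gaussianSd}
#' @param seed RNG seed
#' @return validated spec (list of class \code{FaSceneSpec})
#' @export
faSceneSpec <- function(imageSize = c(640L, 640L), pixelSize = 0.1,
                        nFa = 200L, faAreaMean = 1.32, faAreaCV = 0.35,
                        axisRatioRange = c(1.5, 3), amplitudeRatio = 2,
                        peakAmplitude = 200, background = 100,
                        touchingFraction = 0, poissonGain = 1,
                        gaussianSd = 20, seed = 1L) {
    stopifnot(nFa >= 0, faAreaMean > 0, faAreaCV >= 0, pixelSize > 0,
              length(imageSize) == 2L, all(imageSize >= 64L),
              axisRatioRange[1L] >= 1, diff(axisRatioRange) >= 0,
              amplitudeRatio > 1, peakAmplitude > 0, background >= 0,
              touchingFraction >= 0, touchingFraction <= 1, gaussianSd >= 0)
    structure(list(imageSize = as.integer(imageSize), pixelSize = pixelSize,
                   nFa = as.integer(nFa), faAreaMean = faAreaMean,
                   faAreaCV = faAreaCV, axisRatioRange = axisRatioRange,
                   amplitudeRatio = amplitudeRatio,
                   peakAmplitude = peakAmplitude, background = background,
                   touchingFraction = touchingFraction,
                   poissonGain = poissonGain, gaussianSd = gaussianSd,
                   seed = seed),
              class = "FaSceneSpec")
}

# Normalized elliptical radius of (dr, dc) offsets for semi-axes (a, b) px
# at orientation phi.
ellipseRadius <- function(dr, dc, a, b, phi) {
    u <- dc * cos(phi) + dr * sin(phi)
    v <- -dc * sin(phi) + dr * cos(phi)
    sqrt((u / a)^2 + (v / b)^2)
}

#' Generate a synthetic focal-contact scene
#'
#' @param spec a [faSceneSpec()]
#' @return list with \code{scene} ([ImageScene-class], channel \code{"fa"})
#'   and \code{truth} ([GroundTruth-class]; label map of planted contacts,
#'   per-contact areas in µm²)
#' @export
synthFaScene <- function(spec = faSceneSpec()) {
    stopifnot(inherits(spec, "FaSceneSpec"))
    withSeed(spec$seed, {
        nr <- spec$imageSize[1L]; nc <- spec$imageSize[2L]
        ps <- spec$pixelSize
        # diffuse cell-shaped background: big blurred ellipse
        ctr <- c(nr, nc) / 2
        rows <- matrix(seq_len(nr), nr, nc)
        cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
        cellR <- ellipseRadius(rows - ctr[1L], cols - ctr[2L],
                               a = 0.46 * nc, b = 0.44 * nr, phi = 0.3)
        bgField <- spec$background * (cellR <= 1) + 0.2 * spec$background
        bgField <- as.matrix(EBImage::gblur(bgField, sigma = 6))
        cellMask <- cellR <= 0.92 # placement region, away from the rim

        n <- spec$nFa
        img <- bgField
        truthLab <- matrix(0L, nr, nc)
        objects <- data.frame()
        if (n > 0L) {
            areas <- if (spec$faAreaCV > 0)
                stats::rgamma(n, shape = 1 / spec$faAreaCV^2,
                              scale = spec$faAreaMean * spec$faAreaCV^2)
            else rep(spec$faAreaMean, n)
            areas <- pmax(areas, 0.05)
            q <- stats::runif(n, spec$axisRatioRange[1L],
                              spec$axisRatioRange[2L])
            aPx <- sqrt(areas / ps^2 * q / pi)
            bPx <- aPx / q
            phi <- stats::runif(n, 0, pi)
            nTouchPairs <- floor(spec$touchingFraction * n / 2)
            pairOf <- integer(n) # 0 = isolated; else partner index
            centers <- matrix(NA_real_, n, 2L)
            placed <- 0L
            tries <- 0L
            maxTries <- 400L * max(n, 1L)
            while (placed < n) {
                tries <- tries + 1L
                if (tries > maxTries)
                    stop("cannot place ", n, " contacts without exceeding ",
                         "the overlap budget; reduce nFa or faAreaMean")
                i <- placed + 1L
                makePair <- nTouchPairs > 0L && i %% 2L == 0L &&
                    pairOf[i - 1L] == 0L && nTouchPairs * 2L >= i
                if (makePair) {
                    # plant touching: just-overlapping with the previous one
                    ang <- stats::runif(1, 0, 2 * pi)
                    d <- 0.85 * (aPx[i - 1L] + aPx[i])
                    cand <- centers[i - 1L, ] + d * c(sin(ang), cos(ang))
                } else {
                    cand <- c(stats::runif(1, 1, nr), stats::runif(1, 1, nc))
                }
                rr <- round(cand[1L]); cc <- round(cand[2L])
                if (rr < 1 || rr > nr || cc < 1 || cc > nc ||
                    !cellMask[rr, cc]) next
                others <- seq_len(placed)
                if (makePair) others <- others[others != i - 1L]
                if (length(others)) {
                    d2 <- (centers[others, 1L] - cand[1L])^2 +
                          (centers[others, 2L] - cand[2L])^2
                    if (any(d2 < (aPx[others] + aPx[i] + 2)^2)) next
                }
                centers[i, ] <- cand
                if (makePair) {
                    pairOf[i] <- i - 1L
                    pairOf[i - 1L] <- i
                    nTouchPairs <- nTouchPairs - 1L
                }
                placed <- i
            }
            # centre-bright generalized-Gaussian profile, truncated at the
            # ellipse edge so the planted mask is the object support;
            # high exponent = plateau-like plaque with a steep rim
            pexp <- 8
            sigmaN <- (1 / log(spec$amplitudeRatio))^(1 / pexp)
            relR <- matrix(Inf, nr, nc) # best (smallest) relative radius
            for (i in seq_len(n)) {
                ext <- ceiling(aPx[i]) + 2L
                r0 <- max(1L, round(centers[i, 1L]) - ext)
                r1 <- min(nr, round(centers[i, 1L]) + ext)
                c0 <- max(1L, round(centers[i, 2L]) - ext)
                c1 <- min(nc, round(centers[i, 2L]) + ext)
                rg <- r0:r1; cg <- c0:c1
                dr <- matrix(rg - centers[i, 1L], length(rg), length(cg))
                dc <- matrix(cg - centers[i, 2L], length(rg), length(cg),
                             byrow = TRUE)
                rrel <- ellipseRadius(dr, dc, aPx[i], bPx[i], phi[i])
                inside <- rrel <= 1
                prof <- spec$peakAmplitude * exp(-(rrel / sigmaN)^pexp)
                img[rg, cg][inside] <- img[rg, cg][inside] + prof[inside]
                sub <- truthLab[rg, cg]
                better <- inside & rrel < relR[rg, cg]
                sub[better] <- i
                truthLab[rg, cg] <- sub
                tmp <- relR[rg, cg]
                tmp[better] <- rrel[better]
                relR[rg, cg] <- tmp
            }
            objects <- data.frame(
                id = seq_len(n),
                row = centers[, 1L], col = centers[, 2L],
                area_um2 = areas,
                major_um = 2 * aPx * ps, minor_um = 2 * bPx * ps,
                orientation_rad = phi,
                touching_partner = pairOf)
        }
        img <- applyNoise(img, spec$poissonGain, spec$gaussianSd)
        scene <- ImageScene(list(fa = img), pixelSize = ps)
        truth <- GroundTruth(objects = objects, labels = truthLab,
                             scalars = list(n_fa = n,
                                            mean_area_um2 = if (n) mean(objects$area_um2) else NA_real_,
                                            pixel_size_um = ps))
        list(scene = scene, truth = truth)
    })
}
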