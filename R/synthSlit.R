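# Synthetic slit-diaphragm scenes: meandering in-phase sinusoid families
# planted at an exact target filtration slit density (length per area).

#' Parameters of a synthetic slit-diaphragm scene
#'
#' A family of parallel, in-phase sinusoidal curves (random global
#' orientation, phase and register) is drawn across a circular region. The
#' scene's true capillary mask is the filled morphological envelope of the
#' drawn curves — the same definition [delineateCapillary()] applies to a
#' measured slit mask — and the family is trimmed at the curve ends,
#' distributed over all curves, until the total polyline length L satisfies
#' L = FSD × A within a fraction of a percent. In-phase curves keep a
#' constant perpendicular spacing, which must stay above twice the line
#' width so skeletonization cannot merge neighbouring slits at the default
#' blur; the generator errors when the requested density violates this.
#'
#' @param capillaryRadiusUm radius of the drawing region in µm
#' @param targetFsd target filtration slit density in µm^-1 (0 = blank)
#' @param pixelSize µm per pixel (super-resolution regime)
#' @param lineWidthPx rasterized slit line width in px
#' @param blurSdPx Gaussian blur sd in px applied to the rendered lines
#' @param waveAmplitudeUm amplitude of the sinusoidal meander in µm
#' @param wavelengthUm wavelength of the meander in µm
#' @param envelopeRadiusUm closing radius defining the true capillary
#'   envelope (matches the default of [delineateCapillary()])
#' @param amplitude line peak intensity above background (pre-blur)
#' @param background intensity floor inside the capillary
#' @param poissonGain,gaussianSd noise model, as in [faSceneSpec()]
#' @param seed RNG seed
#' @return validated spec (list of class \code{SlitSceneSpec})
#' @export
slitSceneSpec <- function(capillaryRadiusUm = 4, targetFsd = 4.57,
                          pixelSize = 0.02, lineWidthPx = 1L,
                          blurSdPx = 1, waveAmplitudeUm = 0.5,
                          wavelengthUm = 3, envelopeRadiusUm = 1,
                          amplitude = 500, background = 20,
                          poissonGain = 1, gaussianSd = 20, seed = 1L) {
    stopifnot(capillaryRadiusUm > 0, targetFsd >= 0, pixelSize > 0,
              lineWidthPx >= 1, blurSdPx >= 0, waveAmplitudeUm >= 0,
              wavelengthUm > 0, amplitude > 0, envelopeRadiusUm > 0)
    structure(list(capillaryRadiusUm = capillaryRadiusUm,
                   targetFsd = targetFsd, pixelSize = pixelSize,
                   lineWidthPx = as.integer(lineWidthPx),
                   blurSdPx = blurSdPx, waveAmplitudeUm = waveAmplitudeUm,
                   wavelengthUm = wavelengthUm,
                   envelopeRadiusUm = envelopeRadiusUm,
                   amplitude = amplitude, background = background,
                   poissonGain = poissonGain, gaussianSd = gaussianSd,
                   seed = seed),
              class = "SlitSceneSpec")
}

# Rasterize a list of sampled curves (matrices of r/c px coords) into a
# logical mask of marked points, then widen to lineWidthPx.
rasterCurves <- function(curves, dimIm, widthPx) {
    mask <- matrix(FALSE, dimIm[1L], dimIm[2L])
    for (cv in curves) {
        if (nrow(cv) == 0L) next
        rr <- round(cv[, 1L]); cc <- round(cv[, 2L])
        ok <- rr >= 1 & rr <= dimIm[1L] & cc >= 1 & cc <= dimIm[2L]
        mask[cbind(rr[ok], cc[ok])] <- TRUE
    }
    if (widthPx > 1L) mask <- EBImage::dilate(mask, discBrush((widthPx - 1) / 2)) > 0
    mask
}

# Total polyline length (µm) of sampled curves.
curvesLength <- function(curves, ps) {
    sum(vapply(curves, function(cv) {
        if (nrow(cv) < 2L) return(0)
        sum(sqrt(diff(cv[, 1L])^2 + diff(cv[, 2L])^2)) * ps
    }, 0))
}

# Trim `delta` µm of length off a curve family, half from each end of
# every curve, proportionally to curve length.
trimCurves <- function(curves, delta, ps) {
    lens <- vapply(curves, function(cv)
        if (nrow(cv) < 2L) 0 else
            sum(sqrt(diff(cv[, 1L])^2 + diff(cv[, 2L])^2)) * ps, 0)
    tot <- sum(lens)
    if (tot <= 0) return(curves)
    lapply(seq_along(curves), function(i) {
        cv <- curves[[i]]
        cut <- delta * lens[i] / tot / 2
        if (cut <= 0 || nrow(cv) < 3L) return(cv)
        seg <- sqrt(diff(cv[, 1L])^2 + diff(cv[, 2L])^2) * ps
        cumF <- cumsum(seg)
        cumB <- rev(cumsum(rev(seg)))
        iFirst <- which(cumF > cut)[1L]
        iLast <- which(cumB > cut)
        iLast <- iLast[length(iLast)] + 1L
        if (is.na(iFirst) || iFirst + 1L >= iLast) return(cv[0L, , drop = FALSE])
        cv[iFirst:iLast, , drop = FALSE]
    })
}

#' Generate a synthetic slit-diaphragm scene
#'
#' @param spec a [slitSceneSpec()]
#' @return list with \code{scene} (channel \code{"slit"}) and \code{truth}:
#'   scalars \code{true_length_um}, \code{capillary_area_um2},
#'   \code{true_fsd}, \code{target_fsd}; labels = capillary mask (1) plus
#'   slit rasterization (2)
#' @export
synthSlitScene <- function(spec = slitSceneSpec()) {
    stopifnot(inherits(spec, "SlitSceneSpec"))
    withSeed(spec$seed, {
        ps <- spec$pixelSize
        Rpx <- spec$capillaryRadiusUm / ps
        margin <- ceiling(1.2 / ps)
        half <- ceiling(Rpx) + margin
        nr <- nc <- 2L * half + 1L
        ctr <- half + 1
        rows <- matrix(seq_len(nr), nr, nc)
        cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
        disc <- (rows - ctr)^2 + (cols - ctr)^2 <= Rpx^2
        envBrush <- discBrush(max(1L, round(spec$envelopeRadiusUm / ps)))
        envelopeOf <- function(curves) {
            m <- rasterCurves(curves, c(nr, nc), spec$lineWidthPx)
            if (!any(m)) return(matrix(FALSE, nr, nc))
            as.matrix(EBImage::fillHull(
                EBImage::closing(m, envBrush) > 0)) > 0
        }

        slitMask <- matrix(FALSE, nr, nc)
        capMask <- disc
        totalLen <- 0
        curves <- list()
        if (spec$targetFsd > 0) {
            Aw <- spec$waveAmplitudeUm; lam <- spec$wavelengthUm
            phase <- stats::runif(1, 0, 2 * pi)
            theta <- stats::runif(1, 0, pi)
            register <- stats::runif(1) # curve-family register in [0,1)
            xsF <- seq(0, lam, length.out = 512L)
            f <- mean(sqrt(1 + (Aw * 2 * pi / lam)^2 *
                           cos(2 * pi * xsF / lam + phase)^2))
            R <- spec$capillaryRadiusUm
            xSamp <- seq(-R - Aw - 0.5, R + Aw + 0.5, by = ps / 2)
            ct <- cos(theta); st <- sin(theta)
            drawFamily <- function(spacing) {
                offsets <- seq(-R, R, by = spacing) +
                    (register - 0.5) * spacing
                out <- list()
                for (y0 in offsets) {
                    yy <- y0 + Aw * sin(2 * pi * xSamp / lam + phase)
                    rr <- ctr + (xSamp * st + yy * ct) / ps
                    cc <- ctr + (xSamp * ct - yy * st) / ps
                    riS <- pmin(pmax(round(rr), 1L), nr)
                    ciS <- pmin(pmax(round(cc), 1L), nc)
                    inside <- disc[cbind(riS, ciS)] &
                        round(rr) >= 1 & round(rr) <= nr &
                        round(cc) >= 1 & round(cc) <= nc
                    if (!any(inside)) next
                    runs <- rle(inside)
                    endIdx <- cumsum(runs$lengths)
                    for (ri in which(runs$values)) {
                        i1 <- endIdx[ri] - runs$lengths[ri] + 1L
                        i2 <- endIdx[ri]
                        if (i2 - i1 < 4L) next
                        out[[length(out) + 1L]] <- cbind(rr[i1:i2], cc[i1:i2])
                    }
                }
                out
            }
            # spacing sets the density; calibrate it against the realised
            # length-per-envelope-area ratio (edge chords and the envelope
            # rim shift it a few percent off f/spacing)
            spacing <- f / spec$targetFsd
            for (pass in 1:3) {
                if (spacing / f < 2 * spec$lineWidthPx * ps + 2 * ps)
                    stop("target FSD geometrically unreachable: required ",
                         "curve spacing falls below twice the line width")
                curves <- drawFamily(spacing)
                if (length(curves) == 0L)
                    stop("target FSD geometrically unreachable")
                capMask <- envelopeOf(curves)
                A <- sum(capMask) * ps^2
                L <- curvesLength(curves, ps)
                ratio <- L / A
                if (abs(ratio / spec$targetFsd - 1) < 0.01) break
                spacing <- spacing * ratio / spec$targetFsd
            }
            totalLen <- curvesLength(curves, ps)
            areaChk <- sum(capMask) * ps^2
            if (abs(totalLen / areaChk / spec$targetFsd - 1) > 0.02)
                stop("target FSD geometrically unreachable at the given ",
                     "curve spacing")
            slitMask <- rasterCurves(curves, c(nr, nc), spec$lineWidthPx)
        }
        areaUm2 <- sum(capMask) * ps^2
        img <- matrix(0.2 * spec$background, nr, nc)
        img[capMask] <- spec$background
        img <- img + spec$amplitude * slitMask
        if (spec$blurSdPx > 0)
            img <- as.matrix(EBImage::gblur(img, sigma = spec$blurSdPx))
        img <- applyNoise(img, spec$poissonGain, spec$gaussianSd)
        labels <- matrix(0L, nr, nc)
        labels[capMask] <- 1L
        labels[slitMask] <- 2L
        scene <- ImageScene(list(slit = img), pixelSize = ps)
        truth <- GroundTruth(
            objects = data.frame(n_curves = length(curves)),
            labels = labels,
            scalars = list(true_length_um = totalLen,
                           capillary_area_um2 = areaUm2,
                           true_fsd = if (areaUm2 > 0) totalLen / areaUm2 else NA_real_,
                           target_fsd = spec$targetFsd,
                           pixel_size_um = ps))
        list(scene = scene, truth = truth)
    })
}
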