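# Synthetic cell scenes: a convex cell body with thin protrusions of known
# geodesic length, and nuclei time lapses with known motion.

#' Generate a synthetic filopodia scene
#'
#' A convex (disc) cell body with thin straight protrusions of planted
#' geodesic length radiating from its boundary. Protrusion directions are
#' spread around the perimeter so neighbouring filopodia never merge.
#'
#' @param nFilopodia number of protrusions
#' @param lengthMeanUm mean protrusion length in µm (gamma-sampled,
#'   CV \code{lengthCV}) — ignored when \code{lengths} is given
#' @param lengths explicit protrusion lengths in µm (planting exact values)
#' @param lengthCV coefficient of variation of sampled lengths
#' @param bodyRadiusUm radius of the cell body in µm
#' @param widthPx protrusion thickness in px (thin, <= 3)
#' @param pixelSize µm per pixel
#' @param amplitude,background,poissonGain,gaussianSd rendering and noise
#' @param seed RNG seed
#' @return list with \code{scene} (channel \code{"actin"}) and \code{truth}
#'   (per-filopodium base/tip/length; labels = the planted cell mask)
#' @export
synthFilopodiaScene <- function(nFilopodia = 8L, lengthMeanUm = 7,
                                lengths = NULL, lengthCV = 0.3,
                                bodyRadiusUm = 12, widthPx = 3L,
                                pixelSize = 0.2, amplitude = 180,
                                background = 20, poissonGain = 1,
                                gaussianSd = 18, seed = 1L) {
    if (!is.null(lengths)) nFilopodia <- length(lengths)
    nFilopodia <- as.integer(nFilopodia)
    stopifnot(nFilopodia >= 0, bodyRadiusUm > 0, pixelSize > 0,
              widthPx >= 1, is.null(lengths) || all(lengths > 0),
              lengthMeanUm > 0)
    withSeed(seed, {
        ps <- pixelSize
        if (is.null(lengths) && nFilopodia > 0L) {
            lengths <- if (lengthCV > 0)
                stats::rgamma(nFilopodia, shape = 1 / lengthCV^2,
                              scale = lengthMeanUm * lengthCV^2)
            else rep(lengthMeanUm, nFilopodia)
            lengths <- pmax(lengths, 0.5)
        }
        maxLen <- if (nFilopodia > 0L) max(lengths) else 0
        Rpx <- bodyRadiusUm / ps
        half <- ceiling(Rpx + maxLen / ps) + 10L
        nr <- nc <- 2L * half + 1L
        if (nr > 4096L) stop("protrusion longer than a representable image")
        ctr <- half + 1
        rows <- matrix(seq_len(nr), nr, nc)
        cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
        body <- (rows - ctr)^2 + (cols - ctr)^2 <= Rpx^2
        mask <- body
        objects <- data.frame()
        if (nFilopodia > 0L) {
            ang <- 2 * pi * (seq_len(nFilopodia) - 1) / nFilopodia +
                stats::runif(1, 0, 2 * pi) +
                stats::rnorm(nFilopodia, sd = 0.25 / nFilopodia * 2 * pi)
            baseR <- ctr + (Rpx - 1) * sin(ang)
            baseC <- ctr + (Rpx - 1) * cos(ang)
            tipR <- ctr + (Rpx + lengths / ps) * sin(ang)
            tipC <- ctr + (Rpx + lengths / ps) * cos(ang)
            capPx <- (widthPx - 1) / 2 # dilation cap radius
            for (i in seq_len(nFilopodia)) {
                if (tipR[i] < 1 || tipR[i] > nr || tipC[i] < 1 ||
                    tipC[i] > nc)
                    stop("protrusion longer than image")
                # pull the drawn tip in by the cap radius so the rasterized
                # bar ends at the planted tip
                mask <- mask | rasterizePolyline(
                    cbind(c(baseR[i], tipR[i] - capPx * sin(ang[i])),
                          c(baseC[i], tipC[i] - capPx * cos(ang[i]))),
                    c(nr, nc), width = widthPx)
            }
            objects <- data.frame(
                id = seq_len(nFilopodia),
                base_row = ctr + Rpx * sin(ang),
                base_col = ctr + Rpx * cos(ang),
                tip_row = tipR, tip_col = tipC,
                length_um = lengths)
        }
        img <- background * 0.2 + amplitude * mask
        img <- as.matrix(EBImage::gblur(img, sigma = 0.8))
        img <- applyNoise(img, poissonGain, gaussianSd)
        labels <- matrix(0L, nr, nc)
        labels[mask] <- 1L
        scene <- ImageScene(list(actin = img), pixelSize = ps)
        truth <- GroundTruth(objects = objects, labels = labels,
                             scalars = list(
                                 n_filopodia = nFilopodia,
                                 mean_length_um = if (nFilopodia) mean(lengths) else NA_real_,
                                 body_radius_um = bodyRadiusUm,
                                 pixel_size_um = ps))
        list(scene = scene, truth = truth)
    })
}

#' Generate a synthetic nuclei time lapse
#'
#' Gaussian-spot nuclei move with constant drift plus an isotropic Gaussian
#' random walk. The truth records every track's positions and its mean
#' speed (total path length / total duration) in µm/min.
#'
#' @param nCells number of nuclei
#' @param driftUmPerFrame drift vector \code{c(drow, dcol)} in µm per frame
#' @param stepSdUm per-axis sd of the random-walk step in µm
#' @param nFrames number of frames (>= 2)
#' @param frameIntervalMin minutes between frames
#' @param imageSize image size in px
#' @param pixelSize µm per pixel
#' @param nucleusRadiusPx spot radius in px (Gaussian sigma is half this)
#' @param minSeparationPx minimum initial centre separation
#' @param amplitude,background,poissonGain,gaussianSd rendering and noise
#' @param seed RNG seed
#' @return list with \code{scene} (single-channel time lapse \code{"nuclei"})
#'   and \code{truth} (objects: track_id, frame, row, col in px and µm;
#'   scalars: per-track mean speeds)
#' @export
synthNucleiTimelapse <- function(nCells = 30L,
                                 driftUmPerFrame = c(0, 0),
                                 stepSdUm = 0, nFrames = 10L,
                                 frameIntervalMin = 20,
                                 imageSize = c(400L, 400L),
                                 pixelSize = 0.65, nucleusRadiusPx = 6,
                                 minSeparationPx = 15,
                                 amplitude = 200, background = 20,
                                 poissonGain = 1, gaussianSd = 20,
                                 seed = 1L) {
    stopifnot(nFrames >= 2L, nCells >= 0, frameIntervalMin > 0,
              pixelSize > 0, stepSdUm >= 0)
    withSeed(seed, {
        nr <- imageSize[1L]; nc <- imageSize[2L]; ps <- pixelSize
        # keep every nucleus inside the frame for the whole movie
        reachPx <- (sqrt(sum(driftUmPerFrame^2)) * (nFrames - 1) +
                    4 * stepSdUm * sqrt(nFrames)) / ps
        margin <- ceiling(nucleusRadiusPx + reachPx) + 2L
        if (2L * margin + 10L > min(nr, nc))
            stop("motion model exceeds the image; enlarge imageSize")
        pos0 <- matrix(NA_real_, nCells, 2L)
        placed <- 0L; tries <- 0L
        while (placed < nCells) {
            tries <- tries + 1L
            if (tries > 10000L * max(nCells, 1L))
                stop("cannot place nuclei at the requested separation")
            cand <- c(stats::runif(1, margin, nr - margin),
                      stats::runif(1, margin, nc - margin))
            if (placed > 0L) {
                d2 <- (pos0[seq_len(placed), 1L] - cand[1L])^2 +
                      (pos0[seq_len(placed), 2L] - cand[2L])^2
                if (any(d2 < minSeparationPx^2)) next
            }
            placed <- placed + 1L
            pos0[placed, ] <- cand
        }
        # trajectories in px
        traj <- array(NA_real_, c(nCells, 2L, nFrames))
        if (nCells > 0L) {
            traj[, , 1L] <- pos0
            for (t in 2L:nFrames) {
                step <- matrix(stats::rnorm(2L * nCells, sd = stepSdUm / ps),
                               nCells, 2L)
                driftPx <- driftUmPerFrame / ps
                traj[, , t] <- traj[, , t - 1L] +
                    matrix(driftPx, nCells, 2L, byrow = TRUE) + step
            }
        }
        sigma <- nucleusRadiusPx / 2
        rows <- matrix(seq_len(nr), nr, nc)
        cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
        stack <- array(0, c(nr, nc, nFrames))
        for (t in seq_len(nFrames)) {
            fr <- matrix(background, nr, nc)
            for (i in seq_len(nCells)) {
                d2 <- (rows - traj[i, 1L, t])^2 + (cols - traj[i, 2L, t])^2
                near <- d2 <= (4 * sigma)^2
                fr[near] <- fr[near] + amplitude * exp(-d2[near] / (2 * sigma^2))
            }
            stack[, , t] <- applyNoise(fr, poissonGain, gaussianSd)
        }
        objects <- data.frame()
        speeds <- numeric(0)
        if (nCells > 0L) {
            objects <- do.call(rbind, lapply(seq_len(nCells), function(i)
                data.frame(track_id = i, frame = seq_len(nFrames),
                           row = traj[i, 1L, ], col = traj[i, 2L, ])))
            speeds <- vapply(seq_len(nCells), function(i) {
                d <- sqrt(diff(traj[i, 1L, ])^2 + diff(traj[i, 2L, ])^2) * ps
                sum(d) / ((nFrames - 1) * frameIntervalMin)
            }, 0)
        }
        scene <- ImageScene(list(nuclei = stack), pixelSize = ps,
                            frameInterval = frameIntervalMin)
        truth <- GroundTruth(objects = objects, labels = NULL,
                             scalars = list(
                                 n_cells = nCells,
                                 mean_speed_um_min = speeds,
                                 frame_interval_min = frameIntervalMin,
                                 pixel_size_um = ps))
        list(scene = scene, truth = truth)
    })
}
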