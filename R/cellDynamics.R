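# Cell-level quantifications: seeded segmentation, spreading, nuclei
# detection, adhesion change, migration tracking, filopodia.

#' Segment cells from seed points (semi-automatic segmentation)
#'
#' Marker-controlled region growing: the intensity channel is smoothed, a
#' global (Otsu) threshold defines the foreground, and each seed grows into
#' its own label over that foreground, partitioning it between seeds.
#'
#' @param img 2D intensity matrix
#' @param seeds data.frame with columns \code{cell_id, row, col} (1-based
#'   pixel coordinates); every seed must lie on foreground
#' @param smoothSigma Gaussian smoothing sd in px
#' @param threshold foreground threshold on the smoothed image;
#'   \code{NULL} = Otsu
#' @return integer cell label map
#' @export
segmentCellFromSeeds <- function(img, seeds, smoothSigma = 2,
                                 threshold = NULL) {
    if (is.null(seeds) || nrow(seeds) == 0L) stop("at least one seed required")
    stopifnot(all(c("cell_id", "row", "col") %in% names(seeds)))
    sm <- if (smoothSigma > 0) as.matrix(EBImage::gblur(img, smoothSigma))
          else img
    if (is.null(threshold)) {
        rng <- range(sm)
        if (diff(rng) == 0) stop("constant image: no foreground")
        norm <- (sm - rng[1L]) / diff(rng)
        threshold <- rng[1L] + diff(rng) *
            EBImage::otsu(EBImage::as.Image(norm), range = c(0, 1))
    }
    fg <- sm > threshold
    seedMat <- matrix(0L, nrow(img), ncol(img))
    for (i in seq_len(nrow(seeds))) {
        rr <- as.integer(round(seeds$row[i])); cc <- as.integer(round(seeds$col[i]))
        if (rr < 1 || rr > nrow(img) || cc < 1 || cc > ncol(img) ||
            !fg[rr, cc])
            stop("seed for cell ", seeds$cell_id[i],
                 " at (", seeds$row[i], ", ", seeds$col[i],
                 ") lies on background")
        seedMat[rr, cc] <- as.integer(seeds$cell_id[i])
    }
    lab <- EBImage::propagate(EBImage::as.Image(sm),
                              EBImage::as.Image(seedMat),
                              mask = EBImage::as.Image(fg))
    out <- as.matrix(lab)
    storage.mode(out) <- "integer"
    out
}

#' Cell spreading areas over time
#'
#' @param labelMaps list of cell label maps, one per timepoint
#' @param pixelSize µm per pixel
#' @param timepoints optional timepoint annotations (defaults to index)
#' @return data.frame with per-timepoint n, mean and sd of cell area (µm²);
#'   timepoints without cells are recorded as missing
#' @export
measureSpreading <- function(labelMaps, pixelSize, timepoints = NULL) {
    stopifnot(length(labelMaps) >= 1L, pixelSize > 0)
    if (is.null(timepoints)) timepoints <- seq_along(labelMaps)
    rows <- lapply(seq_along(labelMaps), function(i) {
        lab <- labelMaps[[i]]
        sizes <- tabulate(lab[lab > 0L])
        sizes <- sizes[sizes > 0L]
        if (length(sizes) == 0L)
            return(data.frame(timepoint = timepoints[i], n_cells = 0L,
                              mean_area_um2 = NA_real_,
                              sd_area_um2 = NA_real_))
        a <- sizes * pixelSize^2
        data.frame(timepoint = timepoints[i], n_cells = length(a),
                   mean_area_um2 = mean(a),
                   sd_area_um2 = if (length(a) > 1L) stats::sd(a) else 0)
    })
    do.call(rbind, rows)
}

#' Detect nuclei by scale-space blob detection
#'
#' Scale-normalized Laplacian-of-Gaussian filtering at the given blob
#' scale, followed by non-maximum suppression at that scale. A classical
#' detector standing in for trained-network nucleus detection; adequate for
#' well-separated stained nuclei, and two nuclei closer than the blob scale
#' merge into one detection (documented limitation).
#'
#' @param img 2D nuclear-channel matrix
#' @param scale blob radius in px
#' @param threshold minimal LoG response (image-intensity units); raise to
#'   suppress weak detections
#' @return data.frame of centroids (row, col) with responses; 0 rows is a
#'   valid result
#' @export
detectNuclei <- function(img, scale = 6, threshold = 10) {
    stopifnot(scale > 0)
    sigma <- scale / sqrt(2)
    half <- ceiling(3 * sigma)
    xs <- -half:half
    g <- exp(-xs^2 / (2 * sigma^2))
    G <- outer(g, g)
    G <- G / sum(G)
    r2 <- outer(xs^2, xs^2, "+")
    # scale-normalized negative LoG kernel (bright blobs -> positive peak)
    LoG <- -sigma^2 * ((r2 - 2 * sigma^2) / sigma^4) * G
    resp <- as.matrix(EBImage::filter2(img, LoG, boundary = "replicate"))
    # local maxima within a 3x3 neighbourhood
    isMax <- resp >= threshold
    for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                    c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
        isMax <- isMax & resp >= shiftMat(resp, sh[1L], sh[2L], -Inf)
    }
    idx <- which(isMax)
    if (length(idx) == 0L)
        return(data.frame(row = numeric(0), col = numeric(0),
                          response = numeric(0)))
    rc <- arrayInd(idx, dim(img))
    keep <- nonMaxSuppress(rc, resp[idx], radius = scale)
    rc <- rc[keep, , drop = FALSE]
    # subpixel refinement: 1D quadratic fit of the response per axis
    sub <- function(r, c, axis) {
        if (axis == 1L) {
            if (r <= 1L || r >= nrow(img)) return(0)
            v <- resp[(r - 1L):(r + 1L), c]
        } else {
            if (c <= 1L || c >= ncol(img)) return(0)
            v <- resp[r, (c - 1L):(c + 1L)]
        }
        den <- v[1L] - 2 * v[2L] + v[3L]
        if (den >= 0) return(0)
        max(min(0.5 * (v[1L] - v[3L]) / den, 0.5), -0.5)
    }
    dr <- vapply(seq_len(nrow(rc)),
                 function(i) sub(rc[i, 1L], rc[i, 2L], 1L), 0)
    dc <- vapply(seq_len(nrow(rc)),
                 function(i) sub(rc[i, 1L], rc[i, 2L], 2L), 0)
    data.frame(row = rc[, 1L] + dr, col = rc[, 2L] + dc,
               response = resp[cbind(rc[, 1L], rc[, 2L])])
}

#' Percent change in adherent cell number
#'
#' @param nReference cell count in the reference condition (> 0)
#' @param nCondition cell count in the test condition
#' @return percent change, 100 * (nCondition - nReference) / nReference
#' @examples adhesionChange(100, 60) # -40
#' @export
adhesionChange <- function(nReference, nCondition) {
    if (!is.finite(nReference) || nReference <= 0)
        stop("reference count must be positive")
    100 * (nCondition - nReference) / nReference
}

#' Link per-frame detections into tracks (greedy nearest neighbour)
#'
#' Frame-to-frame greedy nearest-neighbour assignment under a maximum
#' displacement, with gap closing up to \code{maxGap} missed frames.
#' Mean speed is total path length over total track duration; net
#' displacement is also emitted.
#'
#' @param detections data.frame with columns \code{frame, row, col}
#'   (pixel coordinates)
#' @param pixelSize µm per pixel
#' @param maxDisplacement maximal link distance in µm (per frame step)
#' @param maxGap maximal number of missed frames to bridge
#' @param frameInterval minutes between consecutive frames (> 0)
#' @return list with \code{tracks} (ResultTable: track_id, n_points,
#'   path_length_um, net_displacement_um, duration_min, mean_speed_um_min)
#'   and \code{points} (per-point assignment)
#' @export
linkTracks <- function(detections, pixelSize, maxDisplacement = 30,
                       maxGap = 1L, frameInterval = 20) {
    if (!is.finite(frameInterval) || frameInterval <= 0)
        stop("frame interval must be positive")
    stopifnot(all(c("frame", "row", "col") %in% names(detections)))
    frames <- sort(unique(detections$frame))
    if (length(frames) < 2L) stop("need detections from at least 2 frames")
    maxDispPx <- maxDisplacement / pixelSize
    ends <- data.frame(track = integer(0), frame = numeric(0),
                       row = numeric(0), col = numeric(0))
    pts <- list()
    nTracks <- 0L
    for (f in frames) {
        det <- detections[detections$frame == f, , drop = FALSE]
        if (nrow(det) == 0L) next
        live <- which(ends$frame >= f - 1L - maxGap & ends$frame < f)
        assigned <- rep(NA_integer_, nrow(det))
        if (length(live)) {
            dmat <- outer(ends$row[live], det$row, "-")^2 +
                    outer(ends$col[live], det$col, "-")^2
            cand <- which(dmat <= maxDispPx^2, arr.ind = TRUE)
            if (nrow(cand)) {
                ord <- order(dmat[cand])
                usedT <- logical(length(live)); usedD <- logical(nrow(det))
                for (k in ord) {
                    ti <- cand[k, 1L]; di <- cand[k, 2L]
                    if (usedT[ti] || usedD[di]) next
                    usedT[ti] <- TRUE; usedD[di] <- TRUE
                    assigned[di] <- ends$track[live[ti]]
                }
            }
        }
        for (di in seq_len(nrow(det))) {
            if (is.na(assigned[di])) {
                nTracks <- nTracks + 1L
                assigned[di] <- nTracks
                ends <- rbind(ends, data.frame(track = nTracks, frame = f,
                                               row = det$row[di],
                                               col = det$col[di]))
            } else {
                i <- which(ends$track == assigned[di])
                ends$frame[i] <- f
                ends$row[i] <- det$row[di]
                ends$col[i] <- det$col[di]
            }
        }
        pts[[length(pts) + 1L]] <- data.frame(
            track_id = assigned, frame = f, row = det$row, col = det$col)
    }
    points <- do.call(rbind, pts)
    points <- points[order(points$track_id, points$frame), ]
    tr <- lapply(split(points, points$track_id), function(p) {
        n <- nrow(p)
        path <- if (n > 1L)
            sum(sqrt(diff(p$row)^2 + diff(p$col)^2)) * pixelSize else 0
        dur <- (max(p$frame) - min(p$frame)) * frameInterval
        data.frame(track_id = p$track_id[1L], n_points = n,
                   path_length_um = path,
                   net_displacement_um = sqrt((p$row[n] - p$row[1L])^2 +
                       (p$col[n] - p$col[1L])^2) * pixelSize,
                   duration_min = dur,
                   mean_speed_um_min = if (dur > 0) path / dur else NA_real_)
    })
    tracks <- resultTable(do.call(rbind, tr), provenance = list(
        max_displacement_um = maxDisplacement, max_gap = maxGap,
        frame_interval_min = frameInterval, pixel_size_um = pixelSize))
    list(tracks = tracks, points = points)
}

#' Detect filopodia and measure their geodesic length
#'
#' The cell body is the morphological opening of the cell mask at the given
#' radius; protrusions are mask minus body. Each skeletonized protrusion
#' component touching the body is one filopodium; its length is the
#' diagonal-corrected geodesic skeleton distance from the base (skeleton
#' pixel nearest the body) to the farthest tip. Filopodia shorter than
#' \code{minLength} are discarded.
#'
#' @param cellLab integer cell label map (one or more cells)
#' @param openingRadius body opening radius in µm
#' @param minLength minimal filopodium length in µm
#' @param pixelSize µm per pixel
#' @return list with \code{filopodia} (ResultTable: cell_id, base/tip,
#'   length_um) and \code{perCell} (cell_id, n_filopodia, mean_length_um)
#' @export
detectFilopodia <- function(cellLab, openingRadius = 2, minLength = 1,
                            pixelSize) {
    stopifnot(pixelSize > 0, openingRadius > 0, minLength >= 0)
    ids <- sort(unique(cellLab[cellLab > 0L]))
    rPx <- max(1L, round(openingRadius / pixelSize))
    brush <- discBrush(rPx)
    filo <- list()
    per <- list()
    dimIm <- dim(cellLab)
    for (id in ids) {
        mask <- cellLab == id
        body <- EBImage::opening(mask, brush) > 0
        if (!any(body))
            stop("opening radius larger than cell ", id)
        prot <- mask & !body
        plab <- label8(prot)
        bodyDil <- EBImage::dilate(body, discBrush(1)) > 0
        found <- list()
        for (pid in seq_len(max(plab))) {
            idx <- which(plab == pid)
            if (!any(bodyDil[idx])) next # detached speck, not a protrusion
            bb <- bboxOf(idx, dimIm, pad = 2L)
            sub <- plab[bb$r, bb$c] == pid
            skel <- thinMask(sub)
            sIdx <- which(skel)
            if (length(sIdx) == 0L) next
            # base: skeleton pixel nearest the body
            bodySub <- body[bb$r, bb$c]
            dBody <- as.matrix(EBImage::distmap(!bodySub))
            src <- which.min(dBody[sIdx])
            gd <- skeletonGeodesic(sIdx, dim(sub), src)
            tip <- which.max(ifelse(is.finite(gd), gd, -Inf))
            lenUm <- (gd[tip] + dBody[sIdx][src]) * pixelSize
            if (!is.finite(lenUm) || lenUm < minLength) next
            rcB <- arrayInd(sIdx[src], dim(sub))
            rcT <- arrayInd(sIdx[tip], dim(sub))
            found[[length(found) + 1L]] <- data.frame(
                cell_id = id,
                base_row = bb$r[1L] + rcB[1L] - 1L,
                base_col = bb$c[1L] + rcB[2L] - 1L,
                tip_row = bb$r[1L] + rcT[1L] - 1L,
                tip_col = bb$c[1L] + rcT[2L] - 1L,
                length_um = lenUm)
        }
        fdf <- if (length(found)) do.call(rbind, found) else NULL
        filo[[length(filo) + 1L]] <- fdf
        per[[length(per) + 1L]] <- data.frame(
            cell_id = id,
            n_filopodia = if (is.null(fdf)) 0L else nrow(fdf),
            mean_length_um = if (is.null(fdf)) NA_real_ else mean(fdf$length_um))
    }
    fAll <- do.call(rbind, filo)
    if (is.null(fAll))
        fAll <- data.frame(cell_id = integer(0), base_row = integer(0),
                           base_col = integer(0), tip_row = integer(0),
                           tip_col = integer(0), length_um = numeric(0))
    list(filopodia = resultTable(fAll, provenance = list(
             opening_radius_um = openingRadius, min_length_um = minLength,
             pixel_size_um = pixelSize)),
         perCell = do.call(rbind, per))
}
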