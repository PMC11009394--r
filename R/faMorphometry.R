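# Focal-contact segmentation and morphometry.
#
# The segmentation chain mirrors a gradient-gated adaptive-threshold
# design: (1) pixels above a local mean + k*sd threshold become foreground;
# (2) candidate components are retained only if the mean gradient magnitude
# on their boundary exceeds a quantile of the scene-wide gradient
# distribution and their physical area falls inside a plausibility gate;
# (3) a centre/periphery intensity-ratio filter removes unspecific flat
# blobs; (4) slightly connected contacts are split along distance-transform
# watershed lines seeded at deep internal maxima.

#' Segmentation parameters for focal contacts
#'
#' @param window odd local-threshold window size in px
#' @param k sd multiple added to the local mean
#' @param gradientQuantile scene-gradient quantile a component's mean
#'   boundary gradient must exceed
#' @param minArea,maxArea physical area gates in µm²
#' @param ratioThreshold minimum centre/periphery intensity ratio (rho)
#' @param peripheryWidth width of the periphery ring in px
#' @param centerFraction innermost fraction of pixels forming the centre
#' @param splitDepth h-maxima depth for splitting, as a fraction of the
#'   component's maximal internal distance
#' @return validated list of class \code{FcSegmentationParams}
#' @export
fcSegmentationParams <- function(window = 31L, k = 1.0,
                                 gradientQuantile = 0.95,
                                 minArea = 0.1, maxArea = 20,
                                 ratioThreshold = 1.2,
                                 peripheryWidth = 3L,
                                 centerFraction = 0.25,
                                 splitDepth = 0.2) {
    window <- as.integer(window)
    stopifnot(window >= 3L, window %% 2L == 1L,
              centerFraction > 0, centerFraction < 1,
              ratioThreshold >= 1, minArea < maxArea, minArea >= 0,
              gradientQuantile >= 0, gradientQuantile <= 1,
              peripheryWidth >= 1, splitDepth > 0, splitDepth < 1)
    structure(list(window = window, k = k,
                   gradientQuantile = gradientQuantile,
                   minArea = minArea, maxArea = maxArea,
                   ratioThreshold = ratioThreshold,
                   peripheryWidth = as.integer(peripheryWidth),
                   centerFraction = centerFraction,
                   splitDepth = splitDepth),
              class = "FcSegmentationParams")
}

#' Segment focal contacts by a gradient-gated local threshold
#'
#' @param img 2D intensity matrix (one channel of an [ImageScene-class])
#' @param params a [fcSegmentationParams()]
#' @param pixelSize µm per pixel (for the physical area gates)
#' @return integer label map (8-connected components)
#' @export
segmentFocalContacts <- function(img, params = fcSegmentationParams(),
                                 pixelSize) {
    stopifnot(inherits(params, "FcSegmentationParams"), pixelSize > 0)
    if (any(dim(img) < params$window))
        stop("image smaller than the local-threshold window")
    if (diff(range(img)) == 0)
        return(matrix(0L, nrow(img), ncol(img)))
    st <- boxStats(img, params$window)
    fg <- img > st$mean + params$k * st$sd
    lab <- label8(fg)
    if (max(lab) == 0L) return(lab)
    grad <- gradientMagnitude(img)
    gq <- stats::quantile(grad, params$gradientQuantile, names = FALSE)
    bnd <- boundaryPixels(lab)
    gMean <- labelMeans(grad, lab, sel = bnd)
    sizes <- tabulate(lab[lab > 0L])
    areas <- sizes * pixelSize^2
    ids <- seq_along(sizes)
    keep <- ids[areas >= params$minArea & areas <= params$maxArea &
                ids %in% as.integer(names(gMean)) &
                gMean[as.character(ids)] > gq]
    relabelSequential(lab, keep = keep)
}

# Centre/periphery geometry of one component (indices within the full
# image). Returns means over the innermost `centerFraction` of pixels (by
# distance transform) and over a ring of `width` px outside the component
# (excluding pixels of any labelled component).
centerPeripheryMeans <- function(img, lab, id, params) {
    idx <- which(lab == id)
    dimIm <- dim(img)
    bb <- bboxOf(idx, dimIm, pad = params$peripheryWidth + 1L)
    sub <- lab[bb$r, bb$c]
    comp <- sub == id
    d <- as.matrix(EBImage::distmap(comp))
    dv <- d[comp]
    cut <- stats::quantile(dv, 1 - params$centerFraction, names = FALSE)
    center <- comp & d >= cut
    ring <- (EBImage::dilate(comp, discBrush(params$peripheryWidth)) > 0) &
        !comp & sub == 0L
    # does the nominal ring extend beyond the image?
    rc <- arrayInd(idx, dimIm)
    clipped <- min(rc[, 1L]) - params$peripheryWidth < 1 ||
        max(rc[, 1L]) + params$peripheryWidth > dimIm[1L] ||
        min(rc[, 2L]) - params$peripheryWidth < 1 ||
        max(rc[, 2L]) + params$peripheryWidth > dimIm[2L]
    imgSub <- img[bb$r, bb$c]
    list(center = mean(imgSub[center]),
         periphery = if (any(ring)) mean(imgSub[ring]) else NA_real_,
         ringEmpty = !any(ring), clipped = clipped)
}

#' Remove unspecific components by their centre/periphery intensity ratio
#'
#' For each component the centre is the innermost \code{centerFraction} of
#' its pixels by distance transform and the periphery is a ring of
#' \code{peripheryWidth} px outside it. Components whose centre/periphery
#' mean-intensity ratio falls below \code{ratioThreshold} are removed;
#' components whose ring lies entirely outside the image are retained with
#' a warning.
#'
#' @inheritParams segmentFocalContacts
#' @param lab label map from [segmentFocalContacts()]
#' @return filtered label map
#' @export
refineByCenterPeriphery <- function(img, lab, params = fcSegmentationParams()) {
    ids <- sort(unique(lab[lab > 0L]))
    if (length(ids) == 0L) return(lab)
    keep <- logical(length(ids))
    for (i in seq_along(ids)) {
        cp <- centerPeripheryMeans(img, lab, ids[i], params)
        if (cp$ringEmpty) {
            warning("component ", ids[i],
                    ": periphery ring entirely outside the image; retained")
            keep[i] <- TRUE
        } else {
            keep[i] <- isTRUE(cp$center / cp$periphery >= params$ratioThreshold)
        }
    }
    relabelSequential(lab, keep = ids[keep])
}

#' Split slightly connected contacts along distance-transform watersheds
#'
#' Components with two or more internal distance maxima deeper than
#' \code{splitDepth} times the component's maximal internal distance are
#' split along the watershed lines of the distance transform. The total
#' foreground pixel count is conserved exactly; children smaller than
#' \code{minArea} are re-merged with the sibling they touch most.
#'
#' @param lab integer label map
#' @param params a [fcSegmentationParams()]
#' @param pixelSize µm per pixel
#' @return relabelled map with touching contacts separated
#' @export
separateTouching <- function(lab, params = fcSegmentationParams(),
                             pixelSize) {
    ids <- sort(unique(lab[lab > 0L]))
    if (length(ids) == 0L) return(lab)
    out <- matrix(0L, nrow(lab), ncol(lab))
    nextId <- 0L
    dimIm <- dim(lab)
    minPx <- params$minArea / pixelSize^2
    for (id in ids) {
        idx <- which(lab == id)
        bb <- bboxOf(idx, dimIm, pad = 1L)
        comp <- lab[bb$r, bb$c] == id
        d <- as.matrix(EBImage::distmap(comp))
        # maxima exactly h*max deep still count as separate (strict split)
        tol <- params$splitDepth * max(d) - 1e-6
        w <- as.matrix(EBImage::watershed(EBImage::as.Image(d),
                                          tolerance = tol, ext = 1L))
        w[!comp] <- 0L
        # watershed may leave unlabelled ridge pixels; give them to the
        # nearest child so pixel count is conserved exactly
        miss <- comp & w == 0L
        while (any(miss)) {
            grown <- w
            for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                            c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
                nb <- shiftMat(w, sh[1L], sh[2L], 0L)
                fill <- miss & grown == 0L & nb > 0L
                grown[fill] <- nb[fill]
            }
            if (all(grown == w)) { grown[miss] <- 1L } # degenerate fallback
            w <- grown
            miss <- comp & w == 0L
        }
        kids <- sort(unique(w[w > 0L]))
        if (length(kids) > 1L) {
            # re-merge children below the minimum area into the sibling
            # they share the longest border with
            repeat {
                sizes <- tabulate(w[w > 0L], nbins = max(w))
                small <- which(sizes > 0L & sizes < minPx)
                if (length(small) == 0L || sum(sizes > 0L) <= 1L) break
                s <- small[which.min(sizes[small])]
                touch <- integer(0)
                for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                                c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
                    nb <- shiftMat(w, sh[1L], sh[2L], 0L)
                    touch <- c(touch, nb[w == s & nb > 0L & nb != s])
                }
                if (length(touch) == 0L) break
                tgt <- as.integer(names(which.max(table(touch))))
                w[w == s] <- tgt
            }
            kids <- sort(unique(w[w > 0L]))
        }
        for (kid in kids) {
            nextId <- nextId + 1L
            sel <- w == kid
            outSub <- out[bb$r, bb$c]
            outSub[sel] <- nextId
            out[bb$r, bb$c] <- outSub
        }
    }
    storage.mode(out) <- "integer"
    out
}

#' Measure shape and fluorescence of segmented contacts
#'
#' One record per component: physical area (pixel count × pixel size²),
#' axis lengths / eccentricity / orientation from second central moments,
#' mean, maximal and integrated intensity, and the centre/periphery
#' intensity measurements used by the specificity filter.
#'
#' @inheritParams segmentFocalContacts
#' @param lab final label map (after refinement and splitting)
#' @return a [resultTable()] of focal contacts (possibly 0 rows)
#' @export
measureFocalContacts <- function(img, lab, pixelSize,
                                 params = fcSegmentationParams()) {
    ids <- sort(unique(lab[lab > 0L]))
    cols <- c("id", "row", "col", "area_um2", "major_um", "minor_um",
              "eccentricity", "orientation_rad", "mean_intensity",
              "max_intensity", "integrated_intensity", "center_mean",
              "periphery_mean", "center_periphery_ratio", "cell_id",
              "radial_position")
    if (length(ids) == 0L) {
        df <- as.data.frame(stats::setNames(
            rep(list(numeric(0)), length(cols)), cols))
        return(resultTable(df))
    }
    dimIm <- dim(img)
    rec <- vector("list", length(ids))
    for (i in seq_along(ids)) {
        idx <- which(lab == ids[i])
        rc <- arrayInd(idx, dimIm)
        n <- length(idx)
        mr <- mean(rc[, 1L]); mc <- mean(rc[, 2L])
        dr <- rc[, 1L] - mr; dc <- rc[, 2L] - mc
        # second central moments with the 1/12 px self-variance term
        mu20 <- mean(dc * dc) + 1 / 12
        mu02 <- mean(dr * dr) + 1 / 12
        mu11 <- mean(dc * dr)
        tr <- mu20 + mu02
        det <- sqrt(pmax((mu20 - mu02)^2 + 4 * mu11^2, 0))
        l1 <- (tr + det) / 2; l2 <- (tr - det) / 2
        vals <- img[idx]
        cp <- centerPeripheryMeans(img, lab, ids[i], params)
        rec[[i]] <- data.frame(
            id = ids[i], row = mr, col = mc,
            area_um2 = n * pixelSize^2,
            major_um = 4 * sqrt(pmax(l1, 0)) * pixelSize,
            minor_um = 4 * sqrt(pmax(l2, 0)) * pixelSize,
            eccentricity = if (l1 > 0) sqrt(pmax(1 - l2 / l1, 0)) else 0,
            orientation_rad = 0.5 * atan2(2 * mu11, mu20 - mu02),
            mean_intensity = mean(vals),
            max_intensity = max(vals),
            integrated_intensity = sum(vals),
            center_mean = cp$center,
            periphery_mean = cp$periphery,
            center_periphery_ratio = if (is.finite(cp$periphery) &&
                cp$periphery > 0) cp$center / cp$periphery else NA_real_,
            cell_id = NA_integer_,
            radial_position = NA_real_)
    }
    resultTable(do.call(rbind, rec),
                provenance = list(pixel_size_um = pixelSize))
}

#' Assign contacts to cells and compute their radial position
#'
#' \code{cell_id} is the cell label under the contact centroid.
#' \code{radial_position} is the distance from the cell centroid to the
#' contact centroid divided by the distance from the cell centroid to the
#' cell boundary along the same ray, clipped to [0, 1]. Contacts whose
#' centroid lies on background are flagged and retained with undefined
#' position.
#'
#' @param contacts table from [measureFocalContacts()]
#' @param cellLab integer cell label map (see [segmentCellFromSeeds()])
#' @return the table with \code{cell_id}, \code{radial_position} and
#'   \code{outside_cell} filled in
#' @export
localizeInCell <- function(contacts, cellLab) {
    if (nrow(contacts) == 0L) {
        contacts$outside_cell <- logical(0)
        return(contacts)
    }
    dimIm <- dim(cellLab)
    ids <- sort(unique(cellLab[cellLab > 0L]))
    cents <- lapply(ids, function(id) {
        rc <- arrayInd(which(cellLab == id), dimIm)
        c(mean(rc[, 1L]), mean(rc[, 2L]))
    })
    names(cents) <- ids
    contacts$outside_cell <- FALSE
    for (i in seq_len(nrow(contacts))) {
        pr <- round(contacts$row[i]); pc <- round(contacts$col[i])
        pr <- min(max(pr, 1L), dimIm[1L]); pc <- min(max(pc, 1L), dimIm[2L])
        cid <- cellLab[pr, pc]
        if (cid == 0L) {
            contacts$outside_cell[i] <- TRUE
            next
        }
        contacts$cell_id[i] <- cid
        ctr <- cents[[as.character(cid)]]
        v <- c(contacts$row[i], contacts$col[i]) - ctr
        dContact <- sqrt(sum(v^2))
        if (dContact < 1e-9) {
            contacts$radial_position[i] <- 0
            next
        }
        u <- v / dContact
        # march along the ray until leaving the cell
        t <- dContact
        repeat {
            t <- t + 0.25
            p <- ctr + t * u
            rr <- round(p[1L]); cc <- round(p[2L])
            if (rr < 1 || rr > dimIm[1L] || cc < 1 || cc > dimIm[2L] ||
                cellLab[rr, cc] != cid) break
        }
        contacts$radial_position[i] <- min(dContact / (t - 0.125), 1)
    }
    contacts
}

#' Full focal-contact quantification pipeline
#'
#' Chains [segmentFocalContacts()], [refineByCenterPeriphery()],
#' [separateTouching()] and [measureFocalContacts()]; with cell labels (or
#' seeds) also [localizeInCell()].
#'
#' @param scene an [ImageScene-class]
#' @param channel channel to quantify
#' @param params a [fcSegmentationParams()]
#' @param cellLab optional cell label map for within-cell localization
#' @return list with \code{contacts} (ResultTable) and \code{labels}
#' @export
quantifyFocalAdhesions <- function(scene, channel = 1L,
                                   params = fcSegmentationParams(),
                                   cellLab = NULL) {
    img <- getChannel(scene, channel)
    ps <- pixelSize(scene)
    lab <- segmentFocalContacts(img, params, ps)
    lab <- refineByCenterPeriphery(img, lab, params)
    lab <- separateTouching(lab, params, ps)
    contacts <- measureFocalContacts(img, lab, ps, params)
    if (!is.null(cellLab)) contacts <- localizeInCell(contacts, cellLab)
    list(contacts = contacts, labels = lab)
}
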