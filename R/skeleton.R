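# Morphological thinning and skeleton metrics.
#
# Thinning follows the two-subiteration scheme of Guo & Hall; it reduces a
# binary mask to an 8-connected one-pixel-wide skeleton while preserving
# topology and, importantly for length measurement, collapses staircase
# corners into diagonal steps.

#' Thin a binary mask to a one-pixel skeleton
#'
#' Iterative two-subcycle thinning producing an 8-connected centreline.
#' Used as the length-measurement backbone for slit-diaphragm networks and
#' filopodia.
#'
#' @param mask logical or 0/1 matrix
#' @param maxIter iteration cap (safety, rarely reached)
#' @return logical matrix of skeleton pixels (subset of \code{mask})
#' @export
thinMask <- function(mask, maxIter = 1000L) {
    m <- mask > 0
    if (!any(m)) return(m)
    for (it in seq_len(maxIter)) {
        changed <- FALSE
        for (sub in 1:2) {
            p2 <- shiftMat(m, 1, 0, FALSE);  p3 <- shiftMat(m, 1, -1, FALSE)
            p4 <- shiftMat(m, 0, -1, FALSE); p5 <- shiftMat(m, -1, -1, FALSE)
            p6 <- shiftMat(m, -1, 0, FALSE); p7 <- shiftMat(m, -1, 1, FALSE)
            p8 <- shiftMat(m, 0, 1, FALSE);  p9 <- shiftMat(m, 1, 1, FALSE)
            C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
                 (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
            N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
            N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
            N <- pmin(N1, N2)
            mcond <- if (sub == 1L) ((p6 | p7 | !p9) & p8)
                     else ((p2 | p3 | !p5) & p4)
            del <- m & C == 1 & N >= 2 & N <= 3 & !mcond
            if (any(del)) {
                m[del] <- FALSE
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    m
}

#' Physical length of a skeleton
#'
#' Sums over adjacent skeleton-pixel pairs: 1 pixel step for orthogonal
#' neighbours, sqrt(2) for diagonal neighbours, times the pixel size. A
#' plain pixel count would underestimate diagonal curves by up to 29%.
#'
#' With \code{smooth > 0} (default 3 passes) corner-cutting smoothing is
#' applied to chain pixels (degree <= 2) before summing Euclidean segment
#' lengths. On straight orthogonal or diagonal chains this reproduces the
#' raw step metric exactly; on oblique staircase chains it removes most of
#' the systematic overestimate of digitized curve length (up to ~8% at
#' 22.5° for the raw metric, +5.4% on a rasterized circle).
#'
#' @param skeleton logical/binary matrix (ideally from [thinMask()])
#' @param pixelSize micrometres per pixel
#' @param smooth number of corner-cutting passes (0 = raw step metric)
#' @return length in micrometres (0 for an empty skeleton)
#' @export
skeletonPathLength <- function(skeleton, pixelSize, smooth = 3L) {
    s <- skeleton > 0
    if (!any(s)) return(0)
    smooth <- as.integer(smooth)
    if (smooth <= 0L) {
        nOrth <- sum(s & shiftMat(s, 1, 0, FALSE)) +
                 sum(s & shiftMat(s, 0, 1, FALSE))
        nDiag <- sum(s & shiftMat(s, 1, 1, FALSE)) +
                 sum(s & shiftMat(s, 1, -1, FALSE))
        return((nOrth + sqrt(2) * nDiag) * pixelSize)
    }
    dimIm <- dim(s)
    idx <- which(s)
    id <- matrix(0L, dimIm[1L], dimIm[2L])
    id[idx] <- seq_along(idx)
    # adjacency pairs, each counted once
    pairs <- NULL
    for (sh in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
        nb <- shiftMat(id, sh[1L], sh[2L], 0L)
        sel <- id > 0L & nb > 0L
        if (any(sel)) pairs <- rbind(pairs, cbind(id[sel], nb[sel]))
    }
    if (is.null(pairs)) return(0)
    deg <- tabulate(c(pairs[, 1L], pairs[, 2L]), nbins = length(idx))
    rc <- arrayInd(idx, dimIm)
    pos <- rc * 1.0
    # corner cutting on interior chain pixels only
    two <- which(deg == 2L)
    if (length(two)) {
        for (p in seq_len(smooth)) {
            nbSum <- matrix(0, length(idx), 2L)
            for (k in seq_len(nrow(pairs))) {
                a <- pairs[k, 1L]; b <- pairs[k, 2L]
                nbSum[a, ] <- nbSum[a, ] + pos[b, ]
                nbSum[b, ] <- nbSum[b, ] + pos[a, ]
            }
            pos[two, ] <- 0.5 * pos[two, ] + 0.25 * nbSum[two, ]
        }
    }
    seg <- sqrt((pos[pairs[, 1L], 1L] - pos[pairs[, 2L], 1L])^2 +
                (pos[pairs[, 1L], 2L] - pos[pairs[, 2L], 2L])^2)
    sum(seg) * pixelSize
}

# Geodesic distances (in px units, diagonal-corrected) from a source
# skeleton pixel to every skeleton pixel; Dijkstra over the 8-neighbour
# graph. idx: linear indices of skeleton pixels; src: index into idx.
skeletonGeodesic <- function(idx, dimIm, src) {
    rc <- arrayInd(idx, dimIm)
    n <- length(idx)
    key <- rc[, 1L] + rc[, 2L] * (dimIm[1L] + 2L)
    lookup <- integer(0)
    lookup[as.character(key)] <- seq_len(n) # small n; env would also do
    nbr <- expand.grid(dr = -1:1, dc = -1:1)
    nbr <- nbr[!(nbr$dr == 0 & nbr$dc == 0), ]
    dist <- rep(Inf, n)
    dist[src] <- 0
    done <- rep(FALSE, n)
    for (step in seq_len(n)) {
        u <- which.min(ifelse(done, Inf, dist))
        if (!is.finite(dist[u])) break
        done[u] <- TRUE
        for (k in seq_len(nrow(nbr))) {
            vk <- (rc[u, 1L] + nbr$dr[k]) + (rc[u, 2L] + nbr$dc[k]) *
                  (dimIm[1L] + 2L)
            v <- lookup[as.character(vk)]
            if (is.na(v) || done[v]) next
            w <- if (nbr$dr[k] != 0 && nbr$dc[k] != 0) sqrt(2) else 1
            if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
        }
    }
    dist
}
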