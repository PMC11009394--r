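# Internal pixel-level helpers shared by the imaging modules.

# Shift a matrix by (dr, dc), padding with `fill`.
shiftMat <- function(m, dr, dc, fill = 0) {
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(fill, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
}

# Local mean and sd in a w x w window (replicate boundary).
boxStats <- function(img, w) {
    kern <- matrix(1 / (w * w), w, w)
    mu <- EBImage::filter2(img, kern, boundary = "replicate")
    mu2 <- EBImage::filter2(img * img, kern, boundary = "replicate")
    list(mean = mu, sd = sqrt(pmax(mu2 - mu * mu, 0)))
}

# Sobel gradient magnitude (Euclidean norm of the two directional responses).
gradientMagnitude <- function(img) {
    kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
    gx <- EBImage::filter2(img, kx / 4, boundary = "replicate")
    gy <- EBImage::filter2(img, t(kx) / 4, boundary = "replicate")
    sqrt(gx * gx + gy * gy)
}

# 8-connected labeling: EBImage::bwlabel (4-connected) plus union-find
# merging of diagonally adjacent labels.
label8 <- function(mask) {
    mask <- mask > 0
    if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
    lab <- EBImage::bwlabel(mask)
    storage.mode(lab) <- "integer"
    nr <- nrow(lab); nc <- ncol(lab)
    pairs <- NULL
    for (sh in list(c(1L, 1L), c(1L, -1L))) {
        a <- lab[seq_len(nr - 1L), , drop = FALSE]
        b <- lab[-1L, , drop = FALSE]
        if (sh[2L] == 1L) {
            a <- a[, seq_len(nc - 1L), drop = FALSE]
            b <- b[, -1L, drop = FALSE]
        } else {
            a <- a[, -1L, drop = FALSE]
            b <- b[, seq_len(nc - 1L), drop = FALSE]
        }
        keep <- a > 0L & b > 0L & a != b
        if (any(keep)) pairs <- rbind(pairs, cbind(a[keep], b[keep]))
    }
    n <- max(lab)
    parent <- seq_len(n)
    findRoot <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    if (!is.null(pairs)) {
        pairs <- unique(pairs)
        for (k in seq_len(nrow(pairs))) {
            ra <- findRoot(pairs[k, 1L]); rb <- findRoot(pairs[k, 2L])
            if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
    }
    root <- vapply(seq_len(n), findRoot, 1L)
    relab <- match(root, sort(unique(root)))
    out <- lab
    out[lab > 0L] <- relab[lab[lab > 0L]]
    storage.mode(out) <- "integer"
    out
}

# Drop labels, keep the rest, renumber 1..k preserving order.
relabelSequential <- function(lab, keep = NULL) {
    storage.mode(lab) <- "integer"
    present <- sort(unique(lab[lab > 0L]))
    if (!is.null(keep)) present <- present[present %in% keep]
    if (length(present) == 0L) return(matrix(0L, nrow(lab), ncol(lab)))
    map <- integer(max(lab))
    map[present] <- seq_along(present)
    out <- lab
    out[lab > 0L] <- map[lab[lab > 0L]]
    storage.mode(out) <- "integer"
    out
}

# Row/col index list per label.
labelIndices <- function(lab) {
    idx <- which(lab > 0L)
    if (length(idx) == 0L) return(list())
    split(idx, lab[idx])
}

# Bounding box of linear indices, padded, clipped to the image.
bboxOf <- function(idx, dimIm, pad = 0L) {
    rc <- arrayInd(idx, dimIm)
    r0 <- max(1L, min(rc[, 1L]) - pad); r1 <- min(dimIm[1L], max(rc[, 1L]) + pad)
    c0 <- max(1L, min(rc[, 2L]) - pad); c1 <- min(dimIm[2L], max(rc[, 2L]) + pad)
    list(r = r0:r1, c = c0:c1)
}

# Interior 4-neighbour test: TRUE where all 4 orthogonal neighbours share
# the pixel's label (label map version).
boundaryPixels <- function(lab) {
    fg <- lab > 0L
    same <- function(dr, dc) {
        s <- shiftMat(lab, dr, dc, fill = -1L)
        s == lab
    }
    interior <- fg & same(1, 0) & same(-1, 0) & same(0, 1) & same(0, -1)
    fg & !interior
}

# Disc brush of pixel radius r (odd-sized EBImage brush).
discBrush <- function(r) {
    r <- max(1L, as.integer(round(r)))
    EBImage::makeBrush(2L * r + 1L, shape = "disc")
}

# Stamp discs of diameter `width` px along a polyline (points in px coords,
# columns r, c), marking TRUE in a logical matrix.
rasterizePolyline <- function(pts, dimIm, width = 1) {
    mask <- matrix(FALSE, dimIm[1L], dimIm[2L])
    if (nrow(pts) == 0L) return(mask)
    # densify so consecutive samples are < 0.5 px apart
    dense <- pts
    if (nrow(pts) > 1L) {
        seg <- sqrt(diff(pts[, 1L])^2 + diff(pts[, 2L])^2)
        nsub <- pmax(1L, ceiling(seg / 0.5))
        dense <- do.call(rbind, lapply(seq_along(seg), function(i) {
            t <- seq(0, 1, length.out = nsub[i] + 1L)[-(nsub[i] + 1L)]
            cbind(pts[i, 1L] + t * (pts[i + 1L, 1L] - pts[i, 1L]),
                  pts[i, 2L] + t * (pts[i + 1L, 2L] - pts[i, 2L]))
        }))
        dense <- rbind(dense, pts[nrow(pts), , drop = FALSE])
    }
    rr <- round(dense[, 1L]); cc <- round(dense[, 2L])
    ok <- rr >= 1 & rr <= dimIm[1L] & cc >= 1 & cc <= dimIm[2L]
    mask[cbind(rr[ok], cc[ok])] <- TRUE
    if (width > 1) {
        mask <- EBImage::dilate(mask, discBrush((width - 1) / 2)) > 0
    }
    mask
}

# Even-odd rasterization of a polygon given vertices (r, c) in px coords.
rasterizePolygon <- function(vertices, dimIm) {
    vr <- vertices[, 1L]; vc <- vertices[, 2L]
    n <- length(vr)
    mask <- matrix(FALSE, dimIm[1L], dimIm[2L])
    for (row in seq_len(dimIm[1L])) {
        # horizontal scanline at y = row; find crossings along columns
        xs <- numeric(0)
        j <- n
        for (i in seq_len(n)) {
            if ((vr[i] > row) != (vr[j] > row)) {
                xs <- c(xs, vc[i] + (row - vr[i]) / (vr[j] - vr[i]) *
                            (vc[j] - vc[i]))
            }
            j <- i
        }
        if (length(xs) >= 2L) {
            xs <- sort(xs)
            for (k in seq(1L, length(xs) - 1L, by = 2L)) {
                c0 <- max(1L, ceiling(xs[k])); c1 <- min(dimIm[2L], floor(xs[k + 1L]))
                if (c0 <= c1) mask[row, c0:c1] <- TRUE
            }
        }
    }
    mask
}

# Greedy non-maximum suppression: keep strongest points, drop any within
# `radius` of an accepted one. pts: matrix (r, c), resp: responses.
nonMaxSuppress <- function(pts, resp, radius) {
    if (nrow(pts) == 0L) return(integer(0))
    ord <- order(resp, decreasing = TRUE)
    keep <- integer(0)
    for (i in ord) {
        if (length(keep) == 0L) { keep <- i; next }
        d2 <- (pts[keep, 1L] - pts[i, 1L])^2 + (pts[keep, 2L] - pts[i, 2L])^2
        if (all(d2 > radius^2)) keep <- c(keep, i)
    }
    sort(keep)
}

# Per-label mean of `values` at pixels selected by `sel` (logical) in lab.
labelMeans <- function(values, lab, sel = NULL) {
    idx <- if (is.null(sel)) which(lab > 0L) else which(sel & lab > 0L)
    if (length(idx) == 0L) return(numeric(0))
    tapply(values[idx], lab[idx], mean)
}

# Restore RNG state on exit so seeded generators do not disturb callers.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(eval.parent(substitute(expr)))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}
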