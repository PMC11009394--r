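# Shared fixtures and scoring helpers, all built in code.

# Intersection-over-union of two binary masks.
iou <- function(a, b) {
    a <- a > 0; b <- b > 0
    u <- sum(a | b)
    if (u == 0) return(NA_real_)
    sum(a & b) / u
}

# Detection precision/recall: a detection matches a truth object when the
# centroids are within `radius` px.
matchScores <- function(detRow, detCol, truRow, truCol, radius = 3) {
    if (length(detRow) == 0L)
        return(list(precision = NA_real_, recall = 0))
    d2 <- outer(detRow, truRow, "-")^2 + outer(detCol, truCol, "-")^2
    list(precision = mean(apply(d2, 1, function(x) any(x <= radius^2))),
         recall = mean(apply(d2, 2, function(x) any(x <= radius^2))))
}

# Binary disc mask.
discMask <- function(n, ctrRow, ctrCol, radius) {
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    (rows - ctrRow)^2 + (cols - ctrCol)^2 <= radius^2
}

# 2x bilinear upsampling of a matrix (finer sampling of the same field,
# as a higher-magnification acquisition would give).
upsample2 <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    xi <- pmin(pmax(seq(0.75, nr + 0.25, by = 0.5), 1), nr)
    yi <- pmin(pmax(seq(0.75, nc + 0.25, by = 0.5), 1), nc)
    x0 <- floor(xi); x1 <- pmin(x0 + 1, nr); fx <- xi - x0
    y0 <- floor(yi); y1 <- pmin(y0 + 1, nc); fy <- yi - y0
    FX <- matrix(fx, length(xi), length(yi))
    FY <- matrix(fy, length(xi), length(yi), byrow = TRUE)
    m[x0, y0] * (1 - FX) * (1 - FY) + m[x1, y0] * FX * (1 - FY) +
        m[x0, y1] * (1 - FX) * FY + m[x1, y1] * FX * FY
}
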