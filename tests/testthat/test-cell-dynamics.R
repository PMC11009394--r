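test_that("seeded segmentation recovers single and touching cells", {
    n <- 120L
    img <- 20 + 180 * discMask(n, 60, 60, 35)
    lab <- segmentCellFromSeeds(img, data.frame(cell_id = 1, row = 60,
                                                col = 60))
    expect_gte(iou(lab == 1, discMask(n, 60, 60, 35)), 0.95)
    # two touching cells, nearest-seed oracle
    set.seed(42)
    m1 <- discMask(200, 100, 70, 35); m2 <- discMask(200, 100, 130, 35)
    img2 <- pmax(20 + 180 * (m1 | m2) + rnorm(200 * 200, sd = 10), 0)
    dim(img2) <- c(200L, 200L)
    lab2 <- segmentCellFromSeeds(img2, data.frame(cell_id = 1:2,
                                                  row = c(100, 100),
                                                  col = c(70, 130)))
    rows <- matrix(seq_len(200), 200, 200)
    cols <- matrix(seq_len(200), 200, 200, byrow = TRUE)
    d1 <- (rows - 100)^2 + (cols - 70)^2
    d2 <- (rows - 100)^2 + (cols - 130)^2
    oracle <- ifelse(d1 < d2, 1L, 2L) * (m1 | m2)
    expect_gte(iou(lab2 == 1, oracle == 1), 0.9)
    expect_gte(iou(lab2 == 2, oracle == 2), 0.9)
    expect_error(segmentCellFromSeeds(img, data.frame(cell_id = 1,
                                                      row = 2, col = 2)),
                 "background")
    expect_error(segmentCellFromSeeds(img, data.frame()[0, ]),
                 "seed")
})

test_that("spreading areas convert to physical units", {
    m <- matrix(0L, 60, 60)
    m[6:55, 6:55] <- 1L # 2500 px
    sp <- measureSpreading(list(m), pixelSize = 0.2)
    expect_equal(sp$mean_area_um2, 100)
    # identical masks -> flat series, zero dispersion
    sp3 <- measureSpreading(list(m, m, m), pixelSize = 0.2)
    expect_equal(unique(sp3$mean_area_um2), 100)
    expect_true(all(sp3$sd_area_um2 == 0))
    # empty timepoint recorded as missing
    sp2 <- measureSpreading(list(m, matrix(0L, 60, 60)), pixelSize = 0.2)
    expect_true(is.na(sp2$mean_area_um2[2]))
    expect_equal(sp2$n_cells[2], 0L)
})

test_that("a planted logistic growth curve is recovered", {
    # planted per-timepoint disc radii following a logistic area curve
    hours <- 1:8
    areaT <- 400 / (1 + exp(-(hours - 4))) + 100 # µm²
    ps <- 0.5
    maps <- lapply(areaT, function(a) {
        r <- sqrt(a / pi) / ps
        m <- matrix(0L, 120, 120)
        m[discMask(120L, 60, 60, r)] <- 1L
        m
    })
    sp <- measureSpreading(maps, ps, timepoints = hours)
    expect_true(all(abs(sp$mean_area_um2 / areaT - 1) < 0.05))
})

test_that("blob detection finds well-separated nuclei", {
    expect_equal(nrow(detectNuclei(matrix(0, 64, 64))), 0L)
    sim <- synthNucleiTimelapse(nCells = 30L, nFrames = 2L, seed = 3)
    img <- getChannel(sim$scene, 1L, frame = 1L)
    det <- detectNuclei(img, scale = 6, threshold = 20)
    tr <- truthObjects(sim$truth)
    tr1 <- tr[tr$frame == 1L, ]
    expect_equal(nrow(det), 30L)
    d2 <- outer(det$row, tr1$row, "-")^2 + outer(det$col, tr1$col, "-")^2
    expect_lt(sqrt(max(apply(d2, 2, min))), 2)
})

test_that("nuclei closer than the blob scale merge into one detection", {
    n <- 64L
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    spot <- function(r0, c0) 200 * exp(-((rows - r0)^2 + (cols - c0)^2) /
                                       (2 * 3^2))
    img <- spot(32, 30) + spot(32, 34) # 4 px apart at blob scale 6
    expect_equal(nrow(detectNuclei(img, scale = 6, threshold = 20)), 1L)
})

test_that("detection count is monotone in the threshold", {
    sim <- synthNucleiTimelapse(nCells = 20L, nFrames = 2L, seed = 8)
    img <- getChannel(sim$scene, 1L, frame = 1L)
    counts <- vapply(c(5, 10, 20, 50, 120),
                     function(th) nrow(detectNuclei(img, 6, th)), 0L)
    expect_true(all(diff(counts) <= 0L))
})

test_that("adhesion change is a guarded percent difference", {
    expect_equal(adhesionChange(100, 60), -40)
    expect_equal(adhesionChange(50, 50), 0)
    expect_error(adhesionChange(0, 10), "positive")
})

test_that("stationary and drifting detections track exactly", {
    det <- do.call(rbind, lapply(1:10, function(f)
        data.frame(frame = f, row = c(10, 40, 80), col = c(15, 50, 90))))
    lt <- linkTracks(det, pixelSize = 0.65, frameInterval = 20)
    expect_equal(nrow(lt$tracks), 3L)
    expect_true(all(lt$tracks$mean_speed_um_min == 0))
    # uniform drift 2 µm/frame at 20 min/frame -> 0.1 µm/min exactly
    ps <- 0.5
    drift <- do.call(rbind, lapply(1:8, function(f)
        data.frame(frame = f, row = c(10, 60) + (f - 1) * 2 / ps,
                   col = c(15, 80))))
    lt2 <- linkTracks(drift, pixelSize = ps, frameInterval = 20)
    expect_equal(nrow(lt2$tracks), 2L)
    expect_equal(lt2$tracks$mean_speed_um_min, c(0.1, 0.1),
                 tolerance = 1e-12)
    expect_error(linkTracks(det, 0.65, frameInterval = 0), "positive")
})

test_that("random-walk tracking recovers truth speeds and identities", {
    sim <- synthNucleiTimelapse(nCells = 12L, stepSdUm = 1.2,
                                nFrames = 10L, frameIntervalMin = 20,
                                minSeparationPx = 30,
                                imageSize = c(500L, 500L), seed = 5)
    dets <- do.call(rbind, lapply(seq_len(10L), function(t) {
        d <- detectNuclei(getChannel(sim$scene, 1L, frame = t),
                          scale = 6, threshold = 20)
        cbind(frame = t, d)
    }))
    lt <- linkTracks(dets, pixelSize = 0.65, maxDisplacement = 30,
                     frameInterval = 20)
    expect_equal(nrow(lt$tracks), 12L)
    expect_true(all(lt$tracks$n_points == 10L)) # zero identity switches
    # per-track speed vs truth (true step << max displacement / 2)
    tru <- truthScalars(sim$truth)$mean_speed_um_min
    truPos <- truthObjects(sim$truth)
    first <- truPos[truPos$frame == 1L, ]
    est <- lt$tracks$mean_speed_um_min
    pts1 <- lt$points[lt$points$frame == 1L, ]
    map <- vapply(seq_len(nrow(first)), function(i)
        pts1$track_id[which.min((pts1$row - first$row[i])^2 +
                                (pts1$col - first$col[i])^2)], 0L)
    expect_true(all(abs(est[match(map, lt$tracks$track_id)] / tru - 1)
                    < 0.10))
})

test_that("filopodia are detected with geodesic lengths", {
    bare <- synthFilopodiaScene(nFilopodia = 0L, seed = 1)
    r0 <- detectFilopodia(truthLabels(bare$truth), pixelSize = 0.2)
    expect_equal(r0$perCell$n_filopodia, 0L)
    sim <- synthFilopodiaScene(lengths = c(5, 6, 7, 8, 9), seed = 2)
    res <- detectFilopodia(truthLabels(sim$truth), pixelSize = 0.2)
    expect_equal(res$perCell$n_filopodia, 5L)
    expect_lt(abs(res$perCell$mean_length_um / 7 - 1), 0.10)
    expect_error(detectFilopodia(truthLabels(sim$truth),
                                 openingRadius = 100, pixelSize = 0.2),
                 "opening radius")
})

test_that("filopodium lengths are invariant to 90 degree rotation", {
    sim <- synthFilopodiaScene(lengths = c(4, 6, 8, 10), seed = 7)
    lab <- truthLabels(sim$truth)
    res <- detectFilopodia(lab, pixelSize = 0.2)
    rot <- t(lab)[, rev(seq_len(nrow(lab)))] # 90° rotation
    resR <- detectFilopodia(rot, pixelSize = 0.2)
    expect_equal(resR$perCell$n_filopodia, res$perCell$n_filopodia)
    expect_lt(abs(resR$perCell$mean_length_um /
                  res$perCell$mean_length_um - 1), 0.05)
})
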