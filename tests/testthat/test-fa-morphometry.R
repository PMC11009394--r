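test_that("noiseless planted contacts are segmented with high overlap", {
    sim <- synthFaScene(faSceneSpec(nFa = 10L, imageSize = c(256L, 256L),
                                    gaussianSd = 0, poissonGain = 0,
                                    seed = 6))
    img <- getChannel(sim$scene, 1L)
    lab <- segmentFocalContacts(img, fcSegmentationParams(),
                                pixelSize(sim$scene))
    expect_equal(max(lab), 10L)
    # oracle: global threshold at background + half amplitude on the
    # noiseless image reproduces the object supports
    oracle <- label8(img > 100 + 100)
    tl <- truthLabels(sim$truth)
    for (id in seq_len(10L)) {
        tmask <- tl == id
        hit <- unique(lab[tmask]); hit <- hit[hit > 0]
        expect_length(hit, 1L)
        expect_gte(iou(lab == hit, tmask), 0.7)
        ohit <- unique(oracle[tmask]); ohit <- ohit[ohit > 0]
        expect_gte(iou(lab == hit, oracle == ohit[1L]), 0.7)
    }
})

test_that("constant images yield no contacts", {
    img <- matrix(5, 64, 64)
    lab <- segmentFocalContacts(img, fcSegmentationParams(), 0.1)
    expect_equal(max(lab), 0L)
    expect_error(segmentFocalContacts(matrix(1, 8, 8),
                                      fcSegmentationParams(), 0.1),
                 "smaller than")
})

test_that("detection precision and recall reach 0.9 at SNR 10", {
    sim <- synthFaScene(faSceneSpec(nFa = 50L, seed = 1)) # SNR 10 default
    res <- quantifyFocalAdhesions(sim$scene)
    tr <- truthObjects(sim$truth)
    sc <- matchScores(res$contacts$row, res$contacts$col, tr$row, tr$col)
    expect_gte(sc$precision, 0.9)
    expect_gte(sc$recall, 0.9)
})

test_that("flat discs on equal background fail the specificity filter", {
    img <- matrix(100, 64, 64)
    lab <- matrix(0L, 64, 64)
    lab[discMask(64, 32, 32, 8)] <- 1L
    out <- refineByCenterPeriphery(img, lab, fcSegmentationParams())
    expect_equal(max(out), 0L)
    # empty label map passes through
    empty <- matrix(0L, 64, 64)
    expect_identical(refineByCenterPeriphery(img, empty,
                                             fcSegmentationParams()),
                     empty)
})

test_that("centre/periphery ratio matches numeric profile integration", {
    # Gaussian contact: peak 200 over background 50, sd 3 px, component =
    # the 2-sd disc
    n <- 81L; ctr <- 41; sdpx <- 3
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    r2 <- (rows - ctr)^2 + (cols - ctr)^2
    img <- 50 + 200 * exp(-r2 / (2 * sdpx^2))
    lab <- matrix(0L, n, n)
    lab[r2 <= (2 * sdpx)^2] <- 1L
    p <- fcSegmentationParams(ratioThreshold = 1.2)
    tab <- measureFocalContacts(img, lab, 0.1, p)
    # oracle: numeric integration of the continuous profile; for a disc the
    # innermost 25% of pixels by distance is the half-radius disc, the
    # periphery the 3-px ring outside the 2-sd disc
    fine <- seq(0, 2 * sdpx, by = 0.01)
    profile <- function(r) 50 + 200 * exp(-r^2 / (2 * sdpx^2))
    wc <- fine[fine <= sdpx] # half of 2-sd radius
    centerOracle <- sum(profile(wc) * wc) / sum(wc)
    ringR <- seq(2 * sdpx, 2 * sdpx + 3, by = 0.01)
    periOracle <- sum(profile(ringR) * ringR) / sum(ringR)
    expect_equal(tab$center_periphery_ratio, centerOracle / periOracle,
                 tolerance = 0.05)
    out <- refineByCenterPeriphery(img, lab, p)
    expect_equal(max(out), 1L) # retained at rho = 1.2
})

test_that("touching discs split along the nearest-centre partition", {
    n <- 40L
    m <- discMask(n, 20, 16, 5) | discMask(n, 20, 24, 5)
    lab <- matrix(0L, n, n)
    lab[m] <- 1L
    expect_equal(max(label8(m)), 1L) # genuinely merged
    out <- separateTouching(lab, fcSegmentationParams(), 0.1)
    expect_equal(max(out), 2L)
    expect_equal(sum(out > 0), sum(m)) # exact conservation
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    nearest <- ifelse((cols - 16)^2 <= (cols - 24)^2, 1L, 2L) * m
    for (k in 1:2) {
        # identify matching child by majority overlap
        child <- which.max(c(sum(out == 1 & nearest == k),
                             sum(out == 2 & nearest == k)))
        expect_lt(abs(sum(out == child) / sum(nearest == k) - 1), 0.1)
    }
})

test_that("convex components are not split and pixels are conserved", {
    n <- 40L
    lab <- matrix(0L, n, n)
    lab[discMask(n, 20, 20, 8)] <- 1L
    out <- separateTouching(lab, fcSegmentationParams(), 0.1)
    expect_equal(max(out), 1L)
    expect_equal(sum(out > 0), sum(lab > 0))
    # idempotence on its own output
    sim <- synthFaScene(faSceneSpec(nFa = 40L, touchingFraction = 0.3,
                                    imageSize = c(384L, 384L), seed = 8))
    lab1 <- segmentFocalContacts(getChannel(sim$scene, 1L),
                                 fcSegmentationParams(), 0.1)
    split1 <- separateTouching(lab1, fcSegmentationParams(), 0.1)
    split2 <- separateTouching(split1, fcSegmentationParams(), 0.1)
    expect_equal(max(split2), max(split1))
    expect_equal(sum(split2 > 0), sum(lab1 > 0))
})

test_that("measurements report physical units and moments correctly", {
    lab <- matrix(0L, 30, 30)
    lab[11:20, 11:20] <- 1L # 100 px
    img <- matrix(7, 30, 30)
    tab <- measureFocalContacts(img, lab, 0.1)
    expect_equal(tab$area_um2, 1.00)
    expect_equal(tab$mean_intensity, 7)
    expect_equal(tab$integrated_intensity, 700)
    # axis-aligned 20 x 5 rectangle: orientation 0, major > minor
    lab2 <- matrix(0L, 40, 60)
    lab2[18:22, 11:30] <- 1L
    tab2 <- measureFocalContacts(matrix(1, 40, 60), lab2, 0.1)
    expect_lt(abs(tab2$orientation_rad), 0.05)
    expect_gt(tab2$major_um, tab2$minor_um)
    # empty labels -> empty table
    expect_equal(nrow(measureFocalContacts(img, lab * 0L, 0.1)), 0L)
})

test_that("full pipeline recovers the planted mean area within 10%", {
    sim <- synthFaScene(faSceneSpec(seed = 13))
    res <- quantifyFocalAdhesions(sim$scene)
    est <- mean(res$contacts$area_um2)
    tru <- mean(truthObjects(sim$truth)$area_um2)
    expect_lt(abs(est / tru - 1), 0.10)
})

test_that("contacts are localized within their cell", {
    n <- 100L
    cellLab <- matrix(0L, n, n)
    cellLab[discMask(n, 50, 50, 40)] <- 1L
    contacts <- data.frame(
        id = 1:3, row = c(50, 50, 5), col = c(50, 89.6, 5),
        cell_id = NA_integer_, radial_position = NA_real_)
    out <- localizeInCell(contacts, cellLab)
    expect_equal(out$cell_id[1], 1L)
    expect_equal(out$radial_position[1], 0)
    expect_equal(out$radial_position[2], 1, tolerance = 0.05)
    expect_true(out$outside_cell[3])
    expect_true(is.na(out$radial_position[3]))
})

test_that("raising the specificity threshold never adds contacts", {
    sim <- synthFaScene(faSceneSpec(nFa = 30L, imageSize = c(320L, 320L),
                                    seed = 9))
    img <- getChannel(sim$scene, 1L)
    lab <- segmentFocalContacts(img, fcSegmentationParams(), 0.1)
    counts <- vapply(c(1, 1.2, 1.5, 2, 3), function(rho) {
        max(refineByCenterPeriphery(img, lab,
            fcSegmentationParams(ratioThreshold = rho)))
    }, 0L)
    expect_true(all(diff(counts) <= 0L))
})

test_that("reported areas are stable under 2x upsampling", {
    sim <- synthFaScene(faSceneSpec(nFa = 25L, imageSize = c(256L, 256L),
                                    seed = 10))
    res1 <- quantifyFocalAdhesions(sim$scene)
    up <- ImageScene(list(fa = upsample2(getChannel(sim$scene, 1L))),
                     pixelSize = pixelSize(sim$scene) / 2)
    # pixel-denominated parameters scale with the finer sampling
    res2 <- quantifyFocalAdhesions(up, params = fcSegmentationParams(
        window = 61L, peripheryWidth = 6L))
    expect_lt(abs(mean(res2$contacts$area_um2) /
                  mean(res1$contacts$area_um2) - 1), 0.05)
})
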