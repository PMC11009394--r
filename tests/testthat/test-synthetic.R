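test_that("generators are deterministic given the seed", {
    a <- synthFaScene(faSceneSpec(nFa = 20L, seed = 5))
    b <- synthFaScene(faSceneSpec(nFa = 20L, seed = 5))
    expect_identical(getChannel(a$scene, 1L), getChannel(b$scene, 1L))
    expect_identical(truthObjects(a$truth), truthObjects(b$truth))
    s1 <- synthSlitScene(slitSceneSpec(capillaryRadiusUm = 2.5, seed = 9))
    s2 <- synthSlitScene(slitSceneSpec(capillaryRadiusUm = 2.5, seed = 9))
    expect_identical(getChannel(s1$scene, 1L), getChannel(s2$scene, 1L))
    p1 <- synthProteomeTable(nProteins = 300L, nUp = 10L, nDown = 20L,
                             seed = 3)
    p2 <- synthProteomeTable(nProteins = 300L, nUp = 10L, nDown = 20L,
                             seed = 3)
    expect_identical(as.data.frame(p1$table), as.data.frame(p2$table))
})

test_that("empty focal-contact scene is background only", {
    sim <- synthFaScene(faSceneSpec(nFa = 0L, imageSize = c(128L, 128L),
                                    seed = 1))
    expect_equal(nrow(truthObjects(sim$truth)), 0L)
    expect_true(all(truthLabels(sim$truth) == 0L))
})

test_that("planted contact areas sample the requested mean", {
    sim <- synthFaScene(faSceneSpec(seed = 2)) # nFa = 200, mean 1.32 µm²
    a <- truthObjects(sim$truth)$area_um2
    expect_length(a, 200L)
    sem <- sd(a) / sqrt(length(a))
    expect_lt(abs(mean(a) - 1.32), 2 * sem + 1e-9)
})

test_that("slit scenes plant the target density to within 2 percent", {
    sim <- synthSlitScene(slitSceneSpec(targetFsd = 4.57, seed = 3))
    tr <- truthScalars(sim$truth)
    expect_lt(abs(tr$true_fsd / 4.57 - 1), 0.02)
    # L = FSD * A at the scene's own mask area
    expect_equal(tr$true_length_um, tr$true_fsd * tr$capillary_area_um2,
                 tolerance = 1e-9)
})

test_that("doubling the target FSD doubles the planted length", {
    lo <- truthScalars(synthSlitScene(
        slitSceneSpec(targetFsd = 2.2, seed = 4))$truth)
    hi <- truthScalars(synthSlitScene(
        slitSceneSpec(targetFsd = 4.4, seed = 4))$truth)
    ratio <- hi$true_length_um / lo$true_length_um *
        lo$capillary_area_um2 / hi$capillary_area_um2
    expect_lt(abs(ratio - 2), 0.08) # ±4% on the doubling
})

test_that("zero target FSD gives a blank capillary", {
    sim <- synthSlitScene(slitSceneSpec(targetFsd = 0,
                                        capillaryRadiusUm = 2, seed = 1))
    expect_equal(truthScalars(sim$truth)$true_length_um, 0)
    expect_false(any(truthLabels(sim$truth) == 2L))
    expect_true(any(truthLabels(sim$truth) == 1L))
})

test_that("unreachable slit densities error", {
    expect_error(synthSlitScene(slitSceneSpec(targetFsd = 40,
                                              capillaryRadiusUm = 2)),
                 "unreachable")
})

test_that("filopodia generator plants exact lengths and counts", {
    sim <- synthFilopodiaScene(lengths = c(5, 6, 7, 8, 9), seed = 2)
    tr <- truthObjects(sim$truth)
    expect_equal(nrow(tr), 5L)
    expect_equal(mean(tr$length_um), 7)
    bare <- synthFilopodiaScene(nFilopodia = 0L, seed = 1)
    expect_equal(nrow(truthObjects(bare$truth)), 0L)
    # mask is a single smooth component
    expect_equal(max(truthLabels(bare$truth)), 1L)
})

test_that("knockout-style filopodia specs carry exact planted ratios", {
    ctrl <- synthFilopodiaScene(nFilopodia = 20L, lengthMeanUm = 7,
                                seed = 11)
    lens <- truthObjects(ctrl$truth)$length_um
    ko <- synthFilopodiaScene(lengths = 0.53 * lens[1:13], seed = 12)
    expect_equal(nrow(truthObjects(ko$truth)) / 20, 0.65)
    expect_equal(mean(truthObjects(ko$truth)$length_um) /
                     mean(lens[1:13]), 0.53)
})

test_that("nuclei time-lapse truth speeds follow the motion model", {
    still <- synthNucleiTimelapse(nCells = 5L, nFrames = 4L, seed = 1,
                                  imageSize = c(200L, 200L))
    expect_true(all(truthScalars(still$truth)$mean_speed_um_min == 0))
    drift <- synthNucleiTimelapse(nCells = 5L,
                                  driftUmPerFrame = c(0, 2),
                                  nFrames = 6L, frameIntervalMin = 20,
                                  imageSize = c(300L, 300L), seed = 2)
    expect_equal(truthScalars(drift$truth)$mean_speed_um_min,
                 rep(0.1, 5), tolerance = 1e-12)
})

test_that("random-walk truth speeds match the Rayleigh-step expectation", {
    s <- 1.5 # µm per-axis step sd
    rw <- synthNucleiTimelapse(nCells = 40L, stepSdUm = s, nFrames = 15L,
                               frameIntervalMin = 20,
                               imageSize = c(600L, 600L), seed = 3)
    speeds <- truthScalars(rw$truth)$mean_speed_um_min
    # independent Monte-Carlo oracle for E|step| of a 2D Gaussian walk
    set.seed(99)
    mc <- sqrt(rnorm(20000, sd = s)^2 + rnorm(20000, sd = s)^2)
    expected <- mean(mc) / 20
    sem <- sd(speeds) / sqrt(length(speeds))
    expect_lt(abs(mean(speeds) - expected), 3 * sem)
})

test_that("proteome tables plant exact pass/fail structure", {
    sim <- synthProteomeTable(nProteins = 1000L, nUp = 71L, nDown = 105L,
                              seed = 4)
    tab <- sim$table
    up <- tab$fold_change >= 1.5 & tab$p_value <= 0.05
    down <- tab$fold_change <= 1 / 1.5 & tab$p_value <= 0.05
    expect_equal(sum(up), 71L)
    expect_equal(sum(down), 105L)
    none <- synthProteomeTable(nProteins = 200L, nUp = 0L, nDown = 0L,
                               seed = 5)
    t2 <- none$table
    expect_equal(sum(t2$fold_change >= 1.5 & t2$p_value <= 0.05), 0L)
    expect_equal(sum(t2$fold_change <= 1 / 1.5 & t2$p_value <= 0.05), 0L)
    expect_error(synthProteomeTable(nProteins = 10L, nUp = 6L, nDown = 5L),
                 "contradictory")
})
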